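#' Default meteorological season definition
#'
#' Meteorological seasons with the prior December folded into the following
#' year's winter: winter = Dec(Y-1), Jan(Y), Feb(Y); spring = MAM;
#' summer = JJA; fall = SON.
#'
#' @return A named list mapping season name to month numbers (12 denotes the
#'   previous calendar year's December).
#' @export
default_seasons <- function() {
  list(winter = c(12L, 1L, 2L), spring = 3:5, summer = 6:8, fall = 9:11)
}

season_lookup <- function(seasons) {
  purrr::imap_dfr(seasons, ~ tibble(season = .y, month = as.integer(.x)))
}

#' Seasonal means of monthly climate variables
#'
#' Aggregates monthly records to unweighted seasonal means per cell-year.
#' December is assigned to the following year's winter. Cell-year-seasons
#' with any missing month are omitted (their count is reported via a
#' message).
#'
#' @param monthly A long monthly table: `cell_id, year, month` plus numeric
#'   variable columns.
#' @param seasons A season definition, see [default_seasons()].
#' @return A tibble `cell_id, year, season` plus the seasonal means of every
#'   variable column.
#' @export
seasonal_aggregate <- function(monthly, seasons = default_seasons()) {
  vars <- setdiff(names(monthly), c("cell_id", "year", "month"))
  lk <- season_lookup(seasons)
  expected <- stats::setNames(vapply(seasons, length, integer(1)), names(seasons))
  out <- monthly |>
    inner_join(lk, by = "month", relationship = "many-to-many") |>
    mutate(season_year = .data$year + (.data$month == 12L &
                                         .data$season == "winter")) |>
    group_by(.data$cell_id, year = .data$season_year, .data$season) |>
    summarise(n_months = n(),
              across(all_of(vars), mean),
              .groups = "drop")
  incomplete <- out$n_months < expected[out$season]
  if (any(incomplete)) {
    inform(sprintf("Omitted %d incomplete cell-year-season(s).",
                   sum(incomplete)))
  }
  out |>
    filter(!incomplete) |>
    select(-"n_months") |>
    arrange(.data$cell_id, .data$year, .data$season)
}

#' Extreme-hot-day thresholds per cell and calendar month
#'
#' For each cell and calendar month, the threshold is the empirical 90th
#' percentile (linear-interpolation quantile) of all daily maximum
#' temperatures pooled across the reference years.
#'
#' @param daily A daily weather table (`cell_id, date, tmax_c`, ...).
#' @param reference_years Integer vector of pooled reference years.
#' @return A tibble `cell_id, month, threshold_c`.
#' @export
derive_hot_thresholds <- function(daily, reference_years) {
  pooled <- daily |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           month = as.integer(format(.data$date, "%m"))) |>
    filter(.data$year %in% reference_years) |>
    group_by(.data$cell_id, .data$month) |>
    summarise(n_days = n(),
              threshold_c = quantile(.data$tmax_c, 0.9, type = 7,
                                     names = FALSE),
              .groups = "drop")
  if (any(pooled$n_days < 30)) {
    bad <- pooled |> filter(.data$n_days < 30)
    abort(sprintf(
      "Fewer than 30 pooled days for %d cell-month(s), e.g. %s month %d.",
      nrow(bad), bad$cell_id[1], bad$month[1]
    ), class = "yieldgap_insufficient_data")
  }
  pooled |> select("cell_id", "month", "threshold_c")
}

#' Count extreme hot days per cell, year and month
#'
#' A day is hot when its maximum temperature strictly exceeds the cell's
#' threshold for that calendar month.
#'
#' @param daily A daily weather table (`cell_id, date, tmax_c`, ...).
#' @param thresholds Output of [derive_hot_thresholds()].
#' @return A tibble `cell_id, year, month, hotdays`.
#' @export
count_hot_days <- function(daily, thresholds) {
  d <- daily |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           month = as.integer(format(.data$date, "%m"))) |>
    left_join(thresholds, by = c("cell_id", "month"))
  if (anyNA(d$threshold_c)) {
    bad <- d |> filter(is.na(.data$threshold_c)) |>
      distinct(.data$cell_id, .data$month)
    abort(sprintf("No hot-day threshold for cell %s month %d.",
                  bad$cell_id[1], bad$month[1]),
          class = "yieldgap_config_error")
  }
  d |>
    group_by(.data$cell_id, .data$year, .data$month) |>
    summarise(hotdays = sum(.data$tmax_c > .data$threshold_c), .groups = "drop")
}

#' Long-term (reference-decade) climatology per cell
#'
#' Per-cell means over the reference years at seasonal and annual
#' granularity, for every variable column of the monthly table.
#'
#' @param monthly A long monthly table: `cell_id, year, month` plus numeric
#'   variable columns.
#' @param reference_years Integer vector of reference years.
#' @param seasons Season definition, see [default_seasons()].
#' @param min_years Minimum reference years required per cell (default 8).
#' @return A wide tibble keyed by `cell_id` with columns
#'   `ltm_{var}_{season}` and `ltm_{var}_annual`.
#' @export
long_term_climatology <- function(monthly, reference_years,
                                  seasons = default_seasons(),
                                  min_years = 8) {
  vars <- setdiff(names(monthly), c("cell_id", "year", "month"))
  ref <- monthly |> filter(.data$year %in% reference_years)
  cover <- ref |> group_by(.data$cell_id) |>
    summarise(n_years = dplyr::n_distinct(.data$year), .groups = "drop")
  sparse <- cover |> filter(.data$n_years < min_years)
  if (nrow(sparse)) {
    abort(sprintf("Cell(s) with < %d reference years: %s.", min_years,
                  paste(sparse$cell_id, collapse = ", ")),
          class = "yieldgap_insufficient_data")
  }
  seasonal <- seasonal_aggregate(ref, seasons) |>
    # climatology of the winter labelled with the first reference year uses a
    # December outside the span; keep within-span season-years only
    filter(.data$year %in% reference_years) |>
    group_by(.data$cell_id, period = .data$season) |>
    summarise(across(all_of(vars), mean), .groups = "drop")
  annual <- ref |>
    group_by(.data$cell_id) |>
    summarise(across(all_of(vars), mean), .groups = "drop") |>
    mutate(period = "annual")
  bind_rows(seasonal, annual) |>
    tidyr::pivot_longer(all_of(vars), names_to = "var") |>
    mutate(name = paste0("ltm_", .data$var, "_", .data$period)) |>
    select("cell_id", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value") |>
    arrange(.data$cell_id)
}

#' Assign each orchard to its nearest climate cell
#'
#' Nearest-neighbour match on coordinates (squared degree distance); ties
#' are broken by the lowest `cell_id`.
#'
#' @param plots Plot table carrying `orchard_id, latitude, longitude`.
#' @param cells Cell table `cell_id, latitude, longitude`.
#' @return `plots` with a `cell_id` column.
#' @export
assign_cells <- function(plots, cells) {
  cells <- cells |> arrange(.data$cell_id)
  orch <- plots |> distinct(.data$orchard_id, .data$latitude, .data$longitude)
  idx <- vapply(seq_len(nrow(orch)), function(i) {
    d2 <- (cells$latitude - orch$latitude[i])^2 +
      (cells$longitude - orch$longitude[i])^2
    which.min(d2)  # which.min takes the first (lowest cell_id) on ties
  }, integer(1))
  orch$cell_id <- cells$cell_id[idx]
  plots |>
    select(-any_of("cell_id")) |>
    left_join(orch[c("orchard_id", "cell_id")], by = "orchard_id")
}

# canonical variable order used throughout the feature table
climate_vars <- c("ppt", "tmax", "tmin", "tmean", "vpdmax", "srad", "dayl")
bio_vars <- c("latitude", "longitude", "cultivar_id", "age",
              "row_spacing_m", "tree_spacing_m", "light_interception")

feature_column_order <- function(seasons = default_seasons()) {
  periods <- c(sprintf("m%02d", 1:12), names(seasons))
  clim <- unlist(lapply(climate_vars, function(v)
    unlist(lapply(c("cur", "prev"), function(l) paste0(v, "_", periods, "_", l)))))
  hot <- unlist(lapply(c("cur", "prev"), function(l)
    paste0("hotdays_", sprintf("m%02d", 1:12), "_", l)))
  ltm <- unlist(lapply(climate_vars, function(v)
    paste0("ltm_", v, "_", c(names(seasons), "annual"))))
  c(bio_vars, clim, hot, ltm)
}

#' Assemble the plot-year feature table
#'
#' One row per plot-year, combining biological plot descriptors with monthly
#' and seasonal climate means for the current and previous year, monthly
#' extreme-hot-day counts at both lags, and per-cell long-term climatology.
#' Columns are named `{var}_{period}_{cur|prev}` (periods `m01..m12` and the
#' season names), `hotdays_m{MM}_{cur|prev}` and `ltm_{var}_{period}`, in a
#' deterministic order. Rows whose previous-year climate is unavailable
#' (e.g. the first survey year) are dropped with a reported count.
#'
#' @param plots A validated plot table (see [load_plots()]).
#' @param monthly Monthly climate table
#'   (`cell_id, year, month, ppt_mm, tmax_c, tmin_c, tmean_c, vpdmax_hpa`).
#' @param daily Daily weather table
#'   (`cell_id, date, tmax_c, srad_wm2, dayl_hours`).
#' @param cells Optional cell-coordinate table for the nearest-cell join;
#'   not needed when `plots` already carries `cell_id`.
#' @param seasons Season definition, see [default_seasons()].
#' @param reference_years Years pooled for hot-day thresholds and long-term
#'   climatology; defaults to the survey years present in `plots`.
#' @return A feature tibble keyed by `plot_id, orchard_id, year` with the
#'   target column `yield_kernel_lbs_acre` and all feature columns; no
#'   missing values.
#' @export
build_feature_table <- function(plots, monthly, daily, cells = NULL,
                                seasons = default_seasons(),
                                reference_years = NULL) {
  if (!"cell_id" %in% names(plots)) {
    if (is.null(cells)) {
      abort("`plots` has no `cell_id`; supply `cells` for the nearest-cell join.",
            class = "yieldgap_config_error")
    }
    plots <- assign_cells(plots, cells)
  }
  reference_years <- reference_years %||% sort(unique(plots$year))

  # daily -> monthly means of SRAD and daylight, then one long monthly table
  daily_m <- daily |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           month = as.integer(format(.data$date, "%m"))) |>
    group_by(.data$cell_id, .data$year, .data$month) |>
    summarise(srad = mean(.data$srad_wm2), dayl = mean(.data$dayl_hours),
              .groups = "drop")
  monthly_all <- monthly |>
    rename(ppt = "ppt_mm", tmax = "tmax_c", tmin = "tmin_c",
           tmean = "tmean_c", vpdmax = "vpdmax_hpa") |>
    inner_join(daily_m, by = c("cell_id", "year", "month"))

  monthly_wide <- monthly_all |>
    tidyr::pivot_longer(all_of(climate_vars), names_to = "var") |>
    mutate(name = paste0(.data$var, "_", sprintf("m%02d", .data$month))) |>
    select("cell_id", "year", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")

  seasonal_wide <- seasonal_aggregate(monthly_all, seasons) |>
    tidyr::pivot_longer(all_of(climate_vars), names_to = "var") |>
    mutate(name = paste0(.data$var, "_", .data$season)) |>
    select("cell_id", "year", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")

  thresholds <- derive_hot_thresholds(daily, reference_years)
  hot_wide <- count_hot_days(daily, thresholds) |>
    mutate(name = paste0("hotdays_", sprintf("m%02d", .data$month))) |>
    select("cell_id", "year", "name", value = "hotdays") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")

  cell_year <- monthly_wide |>
    inner_join(seasonal_wide, by = c("cell_id", "year")) |>
    inner_join(hot_wide, by = c("cell_id", "year"))
  cur <- cell_year |> rename_climate_lag("cur")
  prev <- cell_year |> mutate(year = .data$year + 1L) |> rename_climate_lag("prev")
  ltm <- long_term_climatology(
    monthly_all, reference_years, seasons = seasons,
    min_years = min(8L, length(reference_years)))

  out <- plots |>
    left_join(cur, by = c("cell_id", "year")) |>
    left_join(prev, by = c("cell_id", "year")) |>
    left_join(ltm, by = "cell_id")
  feat_cols <- setdiff(feature_column_order(seasons), bio_vars)
  keep <- complete.cases(out[feat_cols])
  if (any(!keep)) {
    inform(sprintf("Dropped %d plot-year row(s) with incomplete climate.",
                   sum(!keep)))
  }
  out <- out[keep, , drop = FALSE]
  ordered <- c("plot_id", "orchard_id", "cell_id", "year",
               "yield_kernel_lbs_acre", feature_column_order(seasons))
  out[, intersect(ordered, names(out))]
}

rename_climate_lag <- function(cell_year, lag) {
  keys <- c("cell_id", "year")
  vals <- setdiff(names(cell_year), keys)
  stats::setNames(cell_year, c(keys, paste0(vals, "_", lag)))
}

#' Manifest of feature-table columns and their recipes
#'
#' @param seasons Season definition, see [default_seasons()].
#' @return A tibble `column, recipe` describing every generated column.
#' @export
features_manifest <- function(seasons = default_seasons()) {
  cols <- feature_column_order(seasons)
  recipe <- vapply(cols, function(cl) {
    if (cl %in% bio_vars) return("biological plot descriptor")
    if (grepl("^ltm_", cl)) {
      return("per-cell mean over the reference years at the named period")
    }
    if (grepl("^hotdays_", cl)) {
      return(paste("count of days with daily Tmax above the cell's",
                   "90th-percentile threshold for that calendar month",
                   "(cur = plot year, prev = plot year - 1)"))
    }
    paste("mean of the variable over the named month/season",
          "(cur = plot year, prev = plot year - 1;",
          "winter includes the prior December)")
  }, character(1))
  tibble(column = cols, recipe = unname(recipe))
}
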