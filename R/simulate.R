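#' Configuration for the synthetic orchard/climate/yield generator
#'
#' Defines the study conditions the generator emulates: a multi-orchard,
#' multi-year survey of plot-level light interception (LI) and kernel yield
#' across a latitudinal climate gradient, with yields bounded above by a
#' linear frontier in LI and yield gaps driven by tree age, winter mean
#' temperature, summer maximum vapour-pressure deficit (VPDmax) and incoming
#' shortwave radiation (SRAD).
#'
#' @param n_orchards Number of orchards (default 33).
#' @param plots_per_orchard_year Plots sampled per orchard per year (default 24).
#' @param years Inclusive calendar span of the survey (default 2009:2018).
#' @param seed Master RNG seed for the generator.
#' @param frontier_slope True potential-yield slope, lbs/acre per LI
#'   percentage point (default 57.9).
#' @param li_max Asymptotic canopy light-interception fraction (default 0.80).
#' @param li_rate Per-year exponential canopy growth constant (default 0.35).
#' @param li_sd Gaussian measurement/plot noise on LI (fraction, default 0.04).
#' @param canopy_range Per-plot canopy-density multiplier range on `li_max`
#'   (spacing/pruning variation), default `c(0.70, 1.05)`.
#' @param srad_li_effect LI response to long-term spring SRAD
#'   (fraction per W m-2, default 1.5e-3).
#' @param mgmt_range Per-plot management gap-multiplier range (default
#'   `c(0.65, 1.0)`): even stress-free plots fall short of potential by
#'   unmodelled management factors.
#' @param gap_noise_sd Lognormal sigma of the residual gap noise (default 0.12).
#' @param gap_cap Upper clip for the gap multiplier (default 1.05), so a
#'   small fraction of plots lands slightly above the frontier.
#' @param age_threshold Age (years) at which the youth yield penalty
#'   vanishes (default 5).
#' @param age_effect Maximum fractional yield penalty for very young trees
#'   (concave ramp: losses concentrate in the youngest orchards and vanish
#'   at `age_threshold`)
#'   (default 0.25).
#' @param winter_t_threshold Winter mean-temperature hinge (degC, default 10):
#'   warmer winters reduce yield.
#' @param winter_effect Fractional yield loss per degC above the winter
#'   hinge (default 0.10).
#' @param vpd_threshold Summer mean daily VPDmax hinge (hPa, default 40).
#' @param vpd_effect Fractional yield loss per hPa above the VPD hinge
#'   (default 0.045).
#' @param srad_gap_effect Fractional yield response per W m-2 of April SRAD
#'   around `srad_ref` (default 6e-4).
#' @param srad_ref Reference SRAD level (W m-2, default 370).
#' @param gap_effects Logical; `FALSE` disables the management factor and all
#'   deterministic gap effects (every gap multiplier becomes 1), giving the
#'   degenerate on-frontier generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_orchards = 33,
                       plots_per_orchard_year = 24,
                       years = 2009:2018,
                       seed = 1,
                       frontier_slope = 57.9,
                       li_max = 0.80,
                       li_rate = 0.35,
                       li_sd = 0.04,
                       canopy_range = c(0.70, 1.05),
                       srad_li_effect = 1.5e-3,
                       mgmt_range = c(0.65, 1.0),
                       gap_noise_sd = 0.12,
                       gap_cap = 1.05,
                       age_threshold = 5,
                       age_effect = 0.25,
                       winter_t_threshold = 10,
                       winter_effect = 0.10,
                       vpd_threshold = 40,
                       vpd_effect = 0.045,
                       srad_gap_effect = 6e-4,
                       srad_ref = 370,
                       gap_effects = TRUE) {
  cfg <- as.list(environment())
  if (n_orchards < 1 || plots_per_orchard_year < 1 || length(years) < 1) {
    abort("Counts and year span must be positive.", class = "yieldgap_config_error")
  }
  if (li_max <= 0 || li_max > 1) {
    abort("`li_max` must lie in (0, 1].", class = "yieldgap_config_error")
  }
  if (gap_noise_sd < 0 || li_sd < 0) {
    abort("Noise standard deviations must be non-negative.",
          class = "yieldgap_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate orchard/plot skeletons (no LI or yield yet)
#'
#' Places orchards on a latitude gradient spanning roughly 35.0-39.5 degN
#' (warmer, drier conditions in the south), assigns each a climate cell, and
#' draws per-plot tree age (1-22 years), cultivar (one dominant class),
#' and row/tree spacing for every orchard-year.
#'
#' @param config A [sim_config()].
#' @return A plot-skeleton tibble (`plot_id`, `orchard_id`, `cell_id`, `year`,
#'   coordinates, `cultivar_id`, `planting_year`, `age`, spacings).
#' @export
simulate_orchards <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "orchards"))
  n <- config$n_orchards
  lat <- seq(35.0, 39.5, length.out = n) + runif(n, -0.04, 0.04)
  lon <- -119.0 - (lat - 35) / 4.5 * 2.7 + runif(n, -0.15, 0.15)
  orchards <- tibble(
    orchard_id = sprintf("O%02d", seq_len(n)),
    cell_id = sprintf("C%02d", seq_len(n)),
    latitude = round(lat, 4),
    longitude = round(lon, 4)
  )
  cultivar_ids <- c(2L, 5L, 7L, 17L, 18L, 21L, 25L)
  cultivar_p <- c(0.05, 0.06, 0.08, 0.08, 0.62, 0.06, 0.05)
  ages <- 1:22
  age_p <- stats::dnorm(ages, mean = 9, sd = 6)
  grid <- tidyr::expand_grid(
    orchards,
    year = config$years,
    plot_index = seq_len(config$plots_per_orchard_year)
  )
  m <- nrow(grid)
  grid |>
    mutate(
      age = sample(ages, m, replace = TRUE, prob = age_p),
      planting_year = .data$year - .data$age,
      cultivar_id = sample(cultivar_ids, m, replace = TRUE, prob = cultivar_p),
      row_spacing_m = sample(c(6.4, 6.7, 7.0, 7.3), m, replace = TRUE),
      tree_spacing_m = sample(c(4.3, 4.9, 5.5, 6.1), m, replace = TRUE),
      plot_id = sprintf("%s_Y%d_P%02d", .data$orchard_id, .data$year,
                        .data$plot_index)
    ) |>
    select("plot_id", "orchard_id", "cell_id", "year", "latitude",
           "longitude", "cultivar_id", "planting_year", "age",
           "row_spacing_m", "tree_spacing_m")
}

# seasonal climatology helpers: month on a cosine wave peaking in summer
.wave <- function(month, peak) cos(2 * pi * (month - peak) / 12)

#' Simulate gridded-style monthly climate and daily weather
#'
#' Per climate cell, draws monthly precipitation, Tmax/Tmin/Tmean and VPDmax
#' (PRISM-style) and daily Tmax, SRAD and daylight duration (Daymet-style)
#' from sinusoidal seasonal climatologies shifted by latitude (southern sites
#' warmer and drier with higher summer VPDmax), plus interannual and daily
#' noise. `tmin <= tmean <= tmax` holds in every cell-month by construction,
#' and daily Tmax is centred on the monthly value. Two years before the first
#' survey year are included so previous-year and prior-December features can
#' be built for every survey year but the first.
#'
#' @param config A [sim_config()].
#' @param orchards An orchard table (or plot skeleton) carrying
#'   `cell_id`, `latitude`, `longitude`.
#' @return A list with tibbles `monthly`
#'   (`cell_id, year, month, ppt_mm, tmax_c, tmin_c, tmean_c, vpdmax_hpa`)
#'   and `daily` (`cell_id, date, tmax_c, srad_wm2, dayl_hours`).
#' @export
simulate_climate <- function(config, orchards) {
  stopifnot(inherits(config, "sim_config"))
  cells <- orchards |>
    distinct(.data$cell_id, .data$latitude, .data$longitude) |>
    arrange(.data$cell_id)
  set.seed(derive_seed(config$seed, "climate"))
  clim_years <- (min(config$years) - 2):max(config$years)

  grid <- tidyr::expand_grid(cells, year = clim_years, month = 1:12)
  # one interannual anomaly per cell-year, shared by the temperature columns
  yr <- tidyr::expand_grid(cells["cell_id"], year = clim_years) |>
    mutate(
      t_anom = rnorm(n(), 0, 1.5),
      vpd_anom = rnorm(n(), 0, 3.0),
      srad_anom = rnorm(n(), 0, 8)
    )
  monthly <- grid |>
    left_join(yr, by = c("cell_id", "year")) |>
    mutate(
      tbar = 19.5 - 0.8 * (.data$latitude - 35),
      tmean_c = .data$tbar + 8.2 * .wave(.data$month, 7.2) + .data$t_anom +
        rnorm(n(), 0, 0.6),
      tmax_c = .data$tmean_c + 6.5 + 2.0 * .wave(.data$month, 7) +
        abs(rnorm(n(), 0, 0.8)),
      tmin_c = .data$tmean_c - 6.0 - 1.5 * .wave(.data$month, 7) -
        abs(rnorm(n(), 0, 0.8)),
      vpdmax_hpa = pmax(
        1, pmax(3, 26.5 - 1.0 * (.data$latitude - 35) +
                  18 * .wave(.data$month, 7.2)) +
          .data$vpd_anom + rnorm(n(), 0, 1.2)
      ),
      ppt_mm = pmax(0, 58 * .wave(.data$month, 1)) *
        (1 + 0.25 * (.data$latitude - 37)) * exp(rnorm(n(), 0, 0.5))
    ) |>
    mutate(across(c("ppt_mm", "tmax_c", "tmin_c", "tmean_c", "vpdmax_hpa"),
                  ~ round(.x, 3))) |>
    select("cell_id", "year", "month", "ppt_mm", "tmax_c", "tmin_c",
           "tmean_c", "vpdmax_hpa")

  dates <- seq(as.Date(sprintf("%d-01-01", min(clim_years))),
               as.Date(sprintf("%d-12-31", max(clim_years))), by = "day")
  daily <- tidyr::expand_grid(cells, date = dates) |>
    mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m")),
      doy = as.integer(format(.data$date, "%j"))
    ) |>
    left_join(monthly[c("cell_id", "year", "month", "tmax_c")],
              by = c("cell_id", "year", "month"), suffix = c("", "_m")) |>
    left_join(yr[c("cell_id", "year", "srad_anom")],
              by = c("cell_id", "year")) |>
    mutate(
      tmax_c = round(.data$tmax_c + rnorm(n(), 0, 3.2), 2),
      srad_wm2 = round(pmax(
        15, 320 + 205 * .wave(.data$month, 6.5) - 6 * (.data$latitude - 37) +
          .data$srad_anom + rnorm(n(), 0, 28)
      ), 1),
      dayl_hours = round(geosphere::daylength(.data$latitude, .data$doy), 3)
    ) |>
    select("cell_id", "date", "tmax_c", "srad_wm2", "dayl_hours")

  list(monthly = monthly, daily = daily)
}

# cell-year covariates the yield model needs: winter Tmean (Dec of the
# previous calendar year + Jan + Feb), summer mean VPDmax, April SRAD, and
# per-cell long-term spring SRAD over the survey years.
.sim_gap_covariates <- function(climate, years) {
  winter <- climate$monthly |>
    mutate(season_year = .data$year + (.data$month == 12)) |>
    filter(.data$month %in% c(12, 1, 2)) |>
    group_by(.data$cell_id, year = .data$season_year) |>
    summarise(winter_tmean = mean(.data$tmean_c), n_m = n(), .groups = "drop") |>
    filter(.data$n_m == 3) |>
    select(-"n_m")
  summer <- climate$monthly |>
    filter(.data$month %in% 6:8) |>
    group_by(.data$cell_id, .data$year) |>
    summarise(summer_vpdmax = mean(.data$vpdmax_hpa), .groups = "drop")
  daily <- climate$daily |>
    mutate(year = as.integer(format(.data$date, "%Y")),
           month = as.integer(format(.data$date, "%m")))
  april <- daily |>
    filter(.data$month == 4) |>
    group_by(.data$cell_id, .data$year) |>
    summarise(april_srad = mean(.data$srad_wm2), .groups = "drop")
  ltm_spring <- daily |>
    filter(.data$month %in% 3:5, .data$year %in% years) |>
    group_by(.data$cell_id) |>
    summarise(ltm_spring_srad = mean(.data$srad_wm2), .groups = "drop")
  winter |>
    inner_join(summer, by = c("cell_id", "year")) |>
    inner_join(april, by = c("cell_id", "year")) |>
    left_join(ltm_spring, by = "cell_id")
}

#' Simulate light interception and yields over a plot skeleton
#'
#' Light interception saturates in tree age
#' (`LI = v * li_max * (1 - exp(-li_rate * age))` with a per-plot canopy
#' multiplier `v`, a long-term spring-SRAD shift and Gaussian noise, clipped
#' to `[0.05, 0.90]`). Potential yield is linear through the origin in LI
#' percent. The realised yield is the potential times a gap multiplier
#' `g = u * g_age * g_winter * g_vpd * g_srad * exp(eps)` (hinge-shaped
#' stress terms at the configured thresholds, management factor `u`,
#' lognormal noise), clipped to `(0, gap_cap]`.
#'
#' @param skeleton Output of [simulate_orchards()].
#' @param climate Output of [simulate_climate()].
#' @param config The same [sim_config()].
#' @return A list: `plots` (full plot table with `light_interception` and
#'   `yield_kernel_lbs_acre`) and `truth` (a `sim_truth` list carrying the
#'   true frontier slope, effect parameters and per-plot gap multipliers).
#' @export
simulate_yields <- function(skeleton, climate, config) {
  stopifnot(inherits(config, "sim_config"))
  cov <- .sim_gap_covariates(climate, config$years)
  d <- skeleton |> left_join(cov, by = c("cell_id", "year"))
  if (anyNA(d$winter_tmean) || anyNA(d$summer_vpdmax)) {
    bad <- unique(d$orchard_id[!complete.cases(
      d[c("winter_tmean", "summer_vpdmax", "april_srad")])])
    abort(sprintf("Missing climate for orchard-year(s) in orchard(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "yieldgap_linkage_error")
  }
  set.seed(derive_seed(config$seed, "yields"))
  m <- nrow(d)
  v <- runif(m, config$canopy_range[1], config$canopy_range[2])
  u <- runif(m, config$mgmt_range[1], config$mgmt_range[2])
  eps <- rnorm(m, 0, config$gap_noise_sd)
  li_noise <- if (config$li_sd > 0) rnorm(m, 0, config$li_sd) else 0

  li_det <- v * config$li_max * (1 - exp(-config$li_rate * d$age)) +
    config$srad_li_effect * (d$ltm_spring_srad - config$srad_ref)
  # round LI before computing the potential so stored values reproduce the
  # frontier identity exactly under the degenerate configuration
  li <- round(pmin(0.90, pmax(0.05, li_det + li_noise)), 4)
  y_p <- config$frontier_slope * li * 100

  if (isTRUE(config$gap_effects)) {
    g_age <- 1 - config$age_effect *
      sqrt(pmax(0, config$age_threshold - d$age) / config$age_threshold)
    g_winter <- 1 - config$winter_effect *
      pmax(0, d$winter_tmean - config$winter_t_threshold)
    g_vpd <- 1 - config$vpd_effect *
      pmax(0, d$summer_vpdmax - config$vpd_threshold)
    g_srad <- pmin(1.05, pmax(
      0.90, 1 + config$srad_gap_effect * (d$april_srad - config$srad_ref)))
    g_det <- u * g_age * g_winter * g_vpd * g_srad
  } else {
    g_det <- rep(1, m)
  }
  g <- pmin(config$gap_cap, pmax(1e-6, g_det * exp(eps)))

  plots <- d |>
    mutate(
      light_interception = li,
      yield_kernel_lbs_acre = y_p * g
    ) |>
    select("plot_id", "orchard_id", "cell_id", "year", "latitude",
           "longitude", "cultivar_id", "planting_year", "age",
           "row_spacing_m", "tree_spacing_m", "light_interception",
           "yield_kernel_lbs_acre")
  truth <- structure(list(
    frontier_slope = config$frontier_slope,
    age_threshold = config$age_threshold,
    winter_t_threshold = config$winter_t_threshold,
    vpd_threshold = config$vpd_threshold,
    seed = config$seed,
    gap = tibble(plot_id = d$plot_id, year = d$year,
                 g_det = g_det, gap_multiplier = g)
  ), class = "sim_truth")
  list(plots = plots, truth = truth)
}

#' Simulate a complete synthetic survey
#'
#' Runs [simulate_orchards()], [simulate_climate()] and [simulate_yields()]
#' under one configuration.
#'
#' @param config A [sim_config()].
#' @return An `almond_sim` list: `plots`, `monthly`, `daily`, `orchards`
#'   (cell coordinates), `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  skeleton <- simulate_orchards(config)
  climate <- simulate_climate(config, skeleton)
  yields <- simulate_yields(skeleton, climate, config)
  structure(list(
    plots = yields$plots,
    monthly = climate$monthly,
    daily = climate$daily,
    orchards = distinct(skeleton, .data$orchard_id, .data$cell_id,
                        .data$latitude, .data$longitude),
    truth = yields$truth,
    config = config
  ), class = "almond_sim")
}
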