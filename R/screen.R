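#' Category of a feature-table column
#'
#' Groups features for the cross-correlation rule of [pearson_screen()]:
#' precipitation, temperature, vpd, radiation (SRAD and daylength),
#' extremes (hot-day counts), biological (everything else).
#'
#' @param feature Character vector of column names.
#' @return A character vector of category labels.
#' @export
feature_category <- function(feature) {
  dplyr::case_when(
    grepl("(^|_)ppt_", paste0(feature, "_")) ~ "precipitation",
    grepl("^(ltm_)?(tmax|tmin|tmean)_", feature) ~ "temperature",
    grepl("^(ltm_)?vpdmax_", feature) ~ "vpd",
    grepl("^(ltm_)?(srad|dayl)_", feature) ~ "radiation",
    grepl("^hotdays_", feature) ~ "extremes",
    TRUE ~ "biological"
  )
}

#' Correlation screening of candidate features
#'
#' Ranks features by the absolute Pearson correlation with the target and
#' admits them greedily: a feature is selected when `|r| > r_min` with the
#' target and its absolute correlation with every already-selected feature
#' of the same category stays below `r_cross_max`. Both thresholds act on
#' absolute correlations (negative associations count). Constant columns
#' have undefined correlations and are auto-rejected.
#'
#' @param features A feature table (see [build_feature_table()]).
#' @param target Name of the numeric target column in `features` (or a
#'   numeric vector of length `nrow(features)`).
#' @param candidates Optional character vector restricting which columns are
#'   screened; defaults to all numeric columns except keys and the target.
#' @param r_min Minimum absolute target correlation (default 0.15).
#' @param r_cross_max Maximum absolute within-category cross-correlation
#'   among selected features (default 0.50).
#' @param categories Optional named character vector overriding
#'   [feature_category()] labels.
#' @return A `screen_result` tibble: `feature, category, r, p_value,
#'   selected, reason`, ordered by screening rank, with the thresholds as
#'   attributes.
#' @export
pearson_screen <- function(features, target, candidates = NULL,
                           r_min = 0.15, r_cross_max = 0.50,
                           categories = NULL) {
  if (is.character(target)) {
    target_name <- target
    y <- features[[target]]
    if (is.null(y)) {
      abort(sprintf("Target column `%s` not found.", target),
            class = "yieldgap_schema_error")
    }
  } else {
    target_name <- "target"
    y <- target
  }
  if (length(y) < 30) {
    abort("At least 30 rows are required for screening.",
          class = "yieldgap_invalid_input")
  }
  keys <- c("plot_id", "orchard_id", "cell_id", "year")
  candidates <- candidates %||% setdiff(
    names(features)[vapply(features, is.numeric, logical(1))],
    c(keys, target_name))
  X <- features[candidates]
  cat_lab <- if (is.null(categories)) feature_category(candidates) else
    unname(categories[candidates])

  stats_tbl <- purrr::map2_dfr(X, candidates, function(x, nm) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(feature = nm, r = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    tibble(feature = nm, r = unname(ct$estimate), p_value = ct$p.value)
  })
  stats_tbl$category <- cat_lab
  stats_tbl <- stats_tbl |>
    arrange(desc(abs(.data$r)), .data$feature)

  selected <- character(0)
  reason <- character(nrow(stats_tbl))
  sel <- logical(nrow(stats_tbl))
  for (i in seq_len(nrow(stats_tbl))) {
    f <- stats_tbl$feature[i]
    if (is.na(stats_tbl$r[i])) {
      reason[i] <- "constant (correlation undefined)"
      next
    }
    if (abs(stats_tbl$r[i]) <= r_min) {
      reason[i] <- "low target correlation"
      next
    }
    same_cat <- selected[feature_cat_of(selected, stats_tbl) ==
                           stats_tbl$category[i]]
    if (length(same_cat)) {
      cross <- vapply(same_cat, function(g) abs(cor(X[[f]], X[[g]])),
                      numeric(1))
      if (any(cross >= r_cross_max)) {
        reason[i] <- sprintf("redundant within category (|r| = %.2f with %s)",
                             max(cross), same_cat[which.max(cross)])
        next
      }
    }
    sel[i] <- TRUE
    reason[i] <- "selected"
    selected <- c(selected, f)
  }
  out <- stats_tbl |>
    mutate(selected = sel, reason = reason) |>
    select("feature", "category", "r", "p_value", "selected", "reason")
  structure(out, class = c("screen_result", class(out)),
            target = target_name, r_min = r_min, r_cross_max = r_cross_max)
}

feature_cat_of <- function(feats, stats_tbl) {
  stats_tbl$category[match(feats, stats_tbl$feature)]
}

#' Selected features of a screening result
#'
#' @param screen A `screen_result` from [pearson_screen()].
#' @return Character vector of selected feature names, in screening order.
#' @export
selected_features <- function(screen) {
  screen$feature[screen$selected]
}
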