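#' Bin plot-years by light interception
#'
#' Assigns every plot-year to a half-open LI bin `[k*w, (k+1)*w)` (percent
#' scale) and, within each bin, identifies the upper decile by yield: the
#' `ceiling(0.1 * n)` members with the highest yield (ties broken by stable
#' record order). Bins with fewer than `min_bin_count` members are retained
#' in the output but flagged unusable for frontier fitting.
#'
#' @param plots A plot table with `light_interception` (fraction) and
#'   `yield_kernel_lbs_acre`.
#' @param width_pct Bin width in LI percentage points (default 5).
#' @param min_bin_count Minimum members for a bin to enter the frontier fit
#'   (default 20, so the decile holds at least 2 samples).
#' @return A tibble of bins: bounds (`bin_lower`, `bin_upper`, percent),
#'   `n`, `usable`, decile size and decile means of LI (percent) and yield,
#'   plus a `members` list-column of per-bin member tables.
#' @export
bin_by_li <- function(plots, width_pct = 5, min_bin_count = 20) {
  if (!is.numeric(width_pct) || width_pct <= 0) {
    abort("`width_pct` must be a positive number.",
          class = "yieldgap_invalid_parameter")
  }
  if (nrow(plots) == 0) {
    abort("`plots` is empty.", class = "yieldgap_invalid_input")
  }
  members <- plots |>
    mutate(
      li_pct = .data$light_interception * 100,
      bin_lower = floor(.data$li_pct / width_pct) * width_pct
    ) |>
    select(any_of(c("plot_id", "year")), "li_pct",
           yield = "yield_kernel_lbs_acre", "bin_lower")
  members |>
    tidyr::nest(members = -"bin_lower") |>
    arrange(.data$bin_lower) |>
    mutate(
      bin_upper = .data$bin_lower + width_pct,
      n = vapply(.data$members, nrow, integer(1)),
      usable = .data$n >= min_bin_count,
      decile = purrr::map(.data$members, select_upper_decile),
      decile_n = vapply(.data$decile, nrow, integer(1)),
      li_decile_mean_pct = vapply(.data$decile, function(d) mean(d$li_pct),
                                  numeric(1)),
      yield_decile_mean = vapply(.data$decile, function(d) mean(d$yield),
                                 numeric(1))
    ) |>
    select("bin_lower", "bin_upper", "n", "usable", "decile_n",
           "li_decile_mean_pct", "yield_decile_mean", "members", "decile") |>
    structure(width_pct = width_pct, min_bin_count = min_bin_count)
}

#' Upper decile of a bin's members by yield
#'
#' Returns the `ceiling(0.1 * n)` rows with the highest `yield`; ties at the
#' cutoff are resolved by stable input order.
#'
#' @param members A tibble with a `yield` column.
#' @return The selected subset, in decreasing yield order.
#' @export
select_upper_decile <- function(members) {
  k <- ceiling(0.1 * nrow(members))
  ord <- order(-members$yield)  # stable: ties keep input order
  members[ord[seq_len(k)], , drop = FALSE]
}

#' Fit the zero-intercept yield-potential frontier
#'
#' Regresses the per-bin upper-decile mean yield on the upper-decile mean LI
#' (percent) with the intercept fixed at zero. The slope is the closed-form
#' least-squares estimator `sum(x*y) / sum(x^2)` over the usable bins'
#' decile means; `r2_binmeans` is the coefficient of determination of the
#' fitted line against those bin means.
#'
#' @param bins Output of [bin_by_li()].
#' @return An `li_frontier` object (slope in lbs/acre per LI percentage
#'   point, fit quality, bin summaries).
#' @export
fit_frontier <- function(bins) {
  usable <- bins |> filter(.data$usable)
  if (nrow(usable) < 3) {
    abort(sprintf("Only %d usable bin(s); at least 3 required.", nrow(usable)),
          class = "yieldgap_insufficient_data")
  }
  x <- usable$li_decile_mean_pct
  y <- usable$yield_decile_mean
  slope <- sum(x * y) / sum(x^2)
  fitted <- slope * x
  r2 <- rsq(y, fitted)
  structure(list(
    slope = slope,
    intercept = 0,
    r2_binmeans = r2,
    n_bins_used = nrow(usable),
    width_pct = attr(bins, "width_pct") %||%
      (usable$bin_upper[1] - usable$bin_lower[1]),
    min_bin_count = attr(bins, "min_bin_count") %||% min(usable$n),
    bins = bins |> select(-any_of(c("members", "decile")))
  ), class = "li_frontier")
}

#' Estimate the yield-potential frontier from a plot table
#'
#' Convenience wrapper: [bin_by_li()] then [fit_frontier()], optionally on a
#' single cultivar stratum.
#'
#' @inheritParams bin_by_li
#' @param cultivar Optional cultivar id; when given, the frontier is fitted
#'   on that stratum only.
#' @return An `li_frontier` object.
#' @export
li_frontier <- function(plots, width_pct = 5, min_bin_count = 20,
                        cultivar = NULL) {
  if (!is.null(cultivar)) {
    plots <- plots |> filter(.data$cultivar_id %in% cultivar)
  }
  fit_frontier(bin_by_li(plots, width_pct, min_bin_count))
}

#' Predicted yield potential at a light-interception level
#'
#' @param model An `li_frontier` fit.
#' @param li Light interception as a fraction in `(0, 1]` (vectorised).
#' @return Potential yield in lbs/acre: `slope * li * 100`.
#' @export
predict_potential <- function(model, li) {
  stopifnot(inherits(model, "li_frontier"))
  if (any(!is.finite(li)) || any(li <= 0) || any(li > 1)) {
    abort("`li` must lie in (0, 1].", class = "yieldgap_invalid_input")
  }
  model$slope * li * 100
}

#' @export
predict.li_frontier <- function(object, li, ...) predict_potential(object, li)

#' Normalized yield (yield-gap statistic)
#'
#' `y_n = y_o / y_p`: the observed yield as a fraction of the modelled
#' potential. Values above 1 are preserved, not clipped; `1 - y_n` is the
#' yield-gap proxy.
#'
#' @param y_o Observed yield (lbs/acre, >= 0), vectorised.
#' @param y_p Predicted potential (lbs/acre, > 0), vectorised.
#' @return The unitless normalized yield.
#' @export
normalize_yield <- function(y_o, y_p) {
  if (any(!is.finite(y_p)) || any(y_p <= 0)) {
    abort("`y_p` must be positive.", class = "yieldgap_invalid_input")
  }
  if (any(!is.finite(y_o)) || any(y_o < 0)) {
    abort("`y_o` must be non-negative.", class = "yieldgap_invalid_input")
  }
  y_o / y_p
}

#' Per-plot yield-gap records
#'
#' @param plots A plot table.
#' @param model An `li_frontier` fit.
#' @return A tibble `plot_id, year, y_o, y_p, y_n`.
#' @export
compute_gaps <- function(plots, model) {
  tibble(
    plot_id = plots$plot_id,
    year = plots$year,
    y_o = plots$yield_kernel_lbs_acre,
    y_p = predict_potential(model, plots$light_interception),
    y_n = normalize_yield(plots$yield_kernel_lbs_acre,
                          predict_potential(model, plots$light_interception))
  )
}

#' @export
print.li_frontier <- function(x, ...) {
  cat("Light-interception yield-potential frontier (zero intercept)\n")
  cat(sprintf("  slope: %.2f lbs/acre per LI percentage point\n", x$slope))
  cat(sprintf("  R^2 (bin means): %.4f over %d bins (width %g%%)\n",
              x$r2_binmeans, x$n_bins_used, x$width_pct))
  invisible(x)
}

#' @export
#' @method tidy li_frontier
tidy.li_frontier <- function(x, ...) {
  x$bins |> select("bin_lower", "bin_upper", "n", "usable", "decile_n",
                   "li_decile_mean_pct", "yield_decile_mean")
}

#' @export
#' @method glance li_frontier
glance.li_frontier <- function(x, ...) {
  tibble(slope = x$slope, intercept = 0, r2_binmeans = x$r2_binmeans,
         n_bins_used = x$n_bins_used, width_pct = x$width_pct)
}

#' Serialise a frontier fit to JSON
#'
#' @param model An `li_frontier` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frontier <- function(model, path) {
  jsonlite::write_json(list(
    slope = model$slope,
    intercept = 0,
    r2_binmeans = model$r2_binmeans,
    n_bins_used = model$n_bins_used,
    width_pct = model$width_pct,
    bins = model$bins
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
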