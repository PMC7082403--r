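#' Fraction of PAR intercepted by the canopy (fPAR)
#'
#' Computes the canopy light-interception fraction from paired PAR readings
#' taken below the canopy and a simultaneous full-sun reading above it:
#' `fPAR = 1 - mean(par_below) / par_above`.
#'
#' Below-canopy means up to 5% above `par_above` are treated as sensor noise
#' and clipped to `fPAR = 0`; larger excesses indicate inconsistent
#' measurements and raise an error.
#'
#' @param par_below Numeric vector of below-canopy PAR readings
#'   (photon flux, any unit consistent with `par_above`).
#' @param par_above Single above-canopy (full sun) PAR reading, must be > 0.
#' @param noise_tol Fractional tolerance for below readings exceeding
#'   `par_above` (default 0.05).
#' @return A single fraction in `[0, 1]`.
#' @examples
#' compute_fpar(c(250, 150), 1000) # 0.8
#' @export
compute_fpar <- function(par_below, par_above, noise_tol = 0.05) {
  assert_scalar_number(par_above, "par_above")
  if (par_above <= 0) {
    abort("`par_above` must be positive.", class = "yieldgap_invalid_input")
  }
  if (length(par_below) == 0 || !is.numeric(par_below)) {
    abort("`par_below` must contain at least one numeric reading.",
          class = "yieldgap_invalid_input")
  }
  if (any(!is.finite(par_below)) || any(par_below < 0)) {
    abort("`par_below` readings must be finite and non-negative.",
          class = "yieldgap_invalid_input")
  }
  ratio <- mean(par_below) / par_above
  if (ratio > 1 + noise_tol) {
    abort(sprintf(
      "Mean below-canopy PAR exceeds above-canopy PAR by %.1f%% (> %.0f%% tolerance).",
      100 * (ratio - 1), 100 * noise_tol
    ), class = "yieldgap_measurement_inconsistency")
  }
  min(max(1 - ratio, 0), 1)
}

#' Plot-level light interception from per-tree fPAR values
#'
#' The plot-level light interception is the arithmetic mean of the fPAR
#' values of the individually sampled trees.
#'
#' @param tree_fpars Numeric vector of per-tree fPAR fractions in `[0, 1]`.
#' @return A single fraction in `[0, 1]`.
#' @export
aggregate_plot_li <- function(tree_fpars) {
  if (length(tree_fpars) == 0 || !is.numeric(tree_fpars)) {
    abort("`tree_fpars` must contain at least one numeric value.",
          class = "yieldgap_invalid_input")
  }
  if (any(!is.finite(tree_fpars)) || any(tree_fpars < 0) || any(tree_fpars > 1)) {
    abort("`tree_fpars` values must lie in [0, 1].",
          class = "yieldgap_invalid_input")
  }
  mean(tree_fpars)
}

#' Summarise raw PAR transects into plot-level light interception
#'
#' Applies [compute_fpar()] per tree and [aggregate_plot_li()] per plot-year.
#'
#' @param par_tbl A data frame with columns
#'   `plot_id, year, tree_id, par_below, par_above`.
#' @return A tibble with `plot_id, year, n_trees, light_interception`.
#' @export
summarise_par_transects <- function(par_tbl) {
  required <- c("plot_id", "year", "tree_id", "par_below", "par_above")
  missing <- setdiff(required, names(par_tbl))
  if (length(missing)) {
    abort(sprintf("`par_tbl` is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "yieldgap_schema_error")
  }
  par_tbl |>
    group_by(.data$plot_id, .data$year, .data$tree_id) |>
    summarise(
      fpar = compute_fpar(.data$par_below, .data$par_above[1]),
      .groups = "drop_last"
    ) |>
    summarise(
      n_trees = n(),
      light_interception = aggregate_plot_li(.data$fpar),
      .groups = "drop"
    )
}

plot_schema <- c(
  "plot_id", "orchard_id", "year", "latitude", "longitude", "cultivar_id",
  "planting_year", "row_spacing_m", "tree_spacing_m", "light_interception",
  "yield_kernel_lbs_acre"
)

#' Load and validate a plot-year table
#'
#' Reads the canonical `plots.csv` schema (see Details), derives tree age as
#' `year - planting_year`, validates each row, and drops invalid rows with a
#' warning rather than aborting, so large files degrade gracefully.
#'
#' @details Expected header:
#' `plot_id,orchard_id,year,latitude,longitude,cultivar_id,planting_year,`
#' `row_spacing_m,tree_spacing_m,light_interception,yield_kernel_lbs_acre`.
#' Light interception is a fraction in `[0, 1]`; yield is dry-kernel
#' lbs/acre. Row validation rejects: non-finite yield or LI, LI outside
#' `[0, 1]`, negative yield, age < 0. Duplicate `(plot_id, year)` keys are an
#' error.
#'
#' @param path Path to the CSV file.
#' @return A validated plot tibble with an `age` column and a `provenance`
#'   attribute.
#' @export
load_plots <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "yieldgap_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(plot_schema, names(raw))
  if (length(missing)) {
    abort(sprintf("plots file is missing mandatory column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "yieldgap_schema_error")
  }
  validate_plots(raw, provenance = paste0("file:", path))
}

#' Validate an in-memory plot table
#'
#' @param plots A data frame using the `plots.csv` schema.
#' @param provenance Free-text provenance string stored as an attribute.
#' @return A validated plot tibble (invalid rows dropped with a warning).
#' @export
validate_plots <- function(plots, provenance = "in-memory") {
  plots <- as_tibble(plots)
  if (!"age" %in% names(plots)) {
    plots$age <- plots$year - plots$planting_year
  }
  num_cols <- c("year", "latitude", "longitude", "planting_year",
                "row_spacing_m", "tree_spacing_m", "light_interception",
                "yield_kernel_lbs_acre", "age")
  bad_type <- num_cols[!vapply(plots[num_cols], is.numeric, logical(1))]
  if (length(bad_type)) {
    abort(sprintf("Column(s) %s must be numeric.",
                  paste(bad_type, collapse = ", ")),
          class = "yieldgap_schema_error")
  }
  ok <- complete.cases(plots[num_cols]) &
    is.finite(plots$light_interception) &
    plots$light_interception >= 0 & plots$light_interception <= 1 &
    plots$yield_kernel_lbs_acre >= 0 &
    plots$age >= 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warn(sprintf("Dropped %d invalid plot row(s) (row index: %s).",
                 n_bad, paste(head(which(!ok), 10), collapse = ", ")))
    plots <- plots[ok, , drop = FALSE]
  }
  if (nrow(plots) == 0) {
    abort("No valid plot rows remain.", class = "yieldgap_invalid_input")
  }
  if (anyDuplicated(plots[c("plot_id", "year")])) {
    dup <- plots[duplicated(plots[c("plot_id", "year")]), c("plot_id", "year")]
    abort(sprintf("Duplicate (plot_id, year) keys, e.g. (%s, %s).",
                  dup$plot_id[1], dup$year[1]),
          class = "yieldgap_uniqueness_error")
  }
  attr(plots, "provenance") <- provenance
  plots
}

#' Write a plot table in the canonical CSV schema
#'
#' @param plots A validated plot tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  readr::write_csv(plots[, c(plot_schema, intersect("age", names(plots)))],
                   path, progress = FALSE)
  invisible(path)
}
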