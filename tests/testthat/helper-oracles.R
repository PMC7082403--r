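# Independent brute-force oracles used to cross-check the implementation.

# zero-intercept least-squares slope by iterative grid refinement
oracle_slope_grid <- function(x, y, lo = 0, hi = NULL, iters = 25) {
  hi <- hi %||% (2 * max(abs(y)) / max(abs(x)))
  for (i in seq_len(iters)) {
    grid <- seq(lo, hi, length.out = 41)
    sse <- vapply(grid, function(b) sum((y - b * x)^2), numeric(1))
    j <- which.min(sse)
    lo <- grid[max(1, j - 1)]
    hi <- grid[min(length(grid), j + 1)]
  }
  (lo + hi) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy correlation screen computed directly from a correlation matrix
oracle_screen <- function(X, y, categories, r_min = 0.15, r_cross_max = 0.50) {
  r <- vapply(X, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  ord <- order(-abs(r), names(X))
  selected <- character(0)
  for (i in ord) {
    f <- names(X)[i]
    if (is.na(r[i]) || abs(r[i]) <= r_min) next
    peers <- selected[categories[selected] == categories[f]]
    if (length(peers) &&
        any(abs(stats::cor(X[[f]], as.data.frame(X[peers]))) >= r_cross_max)) {
      next
    }
    selected <- c(selected, f)
  }
  selected
}

oracle_rpiq <- function(obs, pred) {
  q <- sort(obs)
  # type-7 quantile computed from first principles
  qt <- function(p) {
    h <- (length(q) - 1) * p + 1
    lo <- floor(h)
    q[lo] + (h - lo) * (q[min(lo + 1, length(q))] - q[lo])
  }
  (qt(0.75) - qt(0.25)) / sqrt(mean((obs - pred)^2))
}

# linear-interpolation (type 7) empirical quantile from first principles
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# small cached simulation shared by test files (built once per test run)
small_sim_env <- new.env()
small_sim <- function() {
  if (is.null(small_sim_env$sim)) {
    cfg <- sim_config(n_orchards = 6, plots_per_orchard_year = 8,
                      years = 2012:2016, seed = 42)
    small_sim_env$sim <- simulate_dataset(cfg)
  }
  small_sim_env$sim
}

small_features <- function() {
  if (is.null(small_sim_env$ft)) {
    sim <- small_sim()
    small_sim_env$ft <- suppressMessages(
      build_feature_table(sim$plots, sim$monthly, sim$daily))
  }
  small_sim_env$ft
}

# canonical plot fixture written to a temporary CSV
write_plot_fixture <- function(n = 10, path = tempfile(fileext = ".csv"),
                               tweak = identity) {
  plots <- tibble::tibble(
    plot_id = sprintf("P%02d", seq_len(n)),
    orchard_id = "O01",
    year = 2015L,
    latitude = 37.1,
    longitude = -120.5,
    cultivar_id = 18L,
    planting_year = 2008L,
    row_spacing_m = 6.7,
    tree_spacing_m = 4.9,
    light_interception = seq(0.2, 0.7, length.out = n),
    yield_kernel_lbs_acre = seq(1000, 3000, length.out = n)
  )
  plots <- tweak(plots)
  readr::write_csv(plots, path, progress = FALSE)
  path
}
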