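mk_plots <- function(li_pct, yield) {
  tibble::tibble(
    plot_id = sprintf("P%03d", seq_along(li_pct)),
    year = 2015L,
    light_interception = li_pct / 100,
    yield_kernel_lbs_acre = yield
  )
}

test_that("LI binning uses half-open intervals on the percent scale", {
  p <- mk_plots(c(12, 14, 17), c(100, 200, 300))
  bins <- bin_by_li(p, width_pct = 5, min_bin_count = 1)
  expect_equal(bins$bin_lower, c(10, 15))
  expect_equal(bins$n, c(2L, 1L))
  # a value exactly on a boundary belongs to the upper bin
  b15 <- bin_by_li(mk_plots(15, 100), width_pct = 5, min_bin_count = 1)
  expect_equal(b15$bin_lower, 15)
  expect_error(bin_by_li(p, width_pct = 0),
               class = "yieldgap_invalid_parameter")
  expect_error(bin_by_li(p[0, ], width_pct = 5),
               class = "yieldgap_invalid_input")
})

test_that("bin counts match a brute-force histogram on uniform draws", {
  set.seed(21)
  li <- runif(1000, 0.05, 0.90)
  p <- mk_plots(li * 100, runif(1000, 0, 4000))
  bins <- bin_by_li(p, width_pct = 5, min_bin_count = 1)
  ref <- table(floor(li * 100 / 5) * 5)
  expect_equal(setNames(bins$n, bins$bin_lower),
               setNames(as.integer(ref), names(ref)))
  expect_equal(sum(bins$n), 1000L)
})

test_that("the upper decile takes the ceil(0.1 n) highest yields", {
  m20 <- tibble::tibble(yield = 1:20)
  expect_equal(sort(select_upper_decile(m20)$yield), c(19, 20))
  m11 <- tibble::tibble(yield = 1:11)
  expect_equal(nrow(select_upper_decile(m11)), 2L)
  # ties at the cutoff resolve by stable record order
  tied <- tibble::tibble(id = 1:20, yield = c(rep(5, 19), 9))
  sel <- select_upper_decile(tied)
  expect_equal(sel$id, c(20L, 1L))
  # sorting oracle on a random bin
  set.seed(31)
  big <- tibble::tibble(id = 1:500, yield = rnorm(500))
  sel_big <- select_upper_decile(big)
  expect_equal(sort(sel_big$yield),
               sort(sort(big$yield, decreasing = TRUE)[1:50]))
})

test_that("frontier slope is the closed-form zero-intercept estimator", {
  mk_bins <- function(x, y, n = 100) {
    structure(
      tibble::tibble(bin_lower = x - 2.5, bin_upper = x + 2.5, n = n,
                     usable = TRUE, decile_n = 10L,
                     li_decile_mean_pct = x, yield_decile_mean = y),
      width_pct = 5, min_bin_count = 20)
  }
  # collinear bin means force the published-scale slope exactly
  m <- fit_frontier(mk_bins(c(10, 20, 50), c(579, 1158, 2895)))
  expect_equal(m$slope, 57.9, tolerance = 1e-12)
  expect_equal(m$r2_binmeans, 1.0, tolerance = 1e-12)

  m2 <- fit_frontier(mk_bins(c(1, 2, 4), c(2, 4, 8)))
  expect_equal(m2$slope, 2.0, tolerance = 1e-12)

  set.seed(41)
  for (rep in 1:10) {
    x <- runif(10, 10, 80)
    y <- 50 * x + rnorm(10, 0, 300)
    m3 <- fit_frontier(mk_bins(x, y))
    expect_equal(m3$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
    # independent oracles: grid-refined least squares and lm through origin
    expect_equal(m3$slope, oracle_slope_grid(x, y), tolerance = 1e-8)
    expect_equal(m3$slope, unname(coef(lm(y ~ 0 + x))), tolerance = 1e-10)
  }
  expect_error(fit_frontier(mk_bins(c(10, 20), c(579, 1158))),
               class = "yieldgap_insufficient_data")
})

test_that("undersized bins are flagged and excluded from the fit", {
  set.seed(51)
  li <- c(runif(200, 30, 60), runif(5, 80, 85))
  p <- mk_plots(li, 50 * li + rnorm(205, 0, 50))
  bins <- bin_by_li(p, width_pct = 5, min_bin_count = 20)
  expect_true(any(!bins$usable))
  m <- fit_frontier(bins)
  expect_equal(m$n_bins_used, sum(bins$usable))
})

test_that("potential prediction scales linearly and validates inputs", {
  m <- structure(list(slope = 57.9), class = "li_frontier")
  expect_equal(predict_potential(m, 0.50), 2895.0)
  expect_equal(predict_potential(m, 1.00), 5790.0)
  li <- sort(runif(50, 0.01, 1))
  expect_true(all(diff(predict_potential(m, li)) > 0))
  expect_error(predict_potential(m, 0), class = "yieldgap_invalid_input")
  expect_error(predict_potential(m, -0.1), class = "yieldgap_invalid_input")
  expect_error(predict_potential(m, 1.2), class = "yieldgap_invalid_input")
})

test_that("normalized yield is the exact quotient, preserved above 1", {
  expect_equal(normalize_yield(2895, 2895), 1.0)
  expect_equal(normalize_yield(0, 2895), 0.0)
  expect_equal(round(normalize_yield(3000, 2895), 4), 1.0363)
  expect_error(normalize_yield(100, 0), class = "yieldgap_invalid_input")
  expect_error(normalize_yield(-1, 100), class = "yieldgap_invalid_input")
})

test_that("normalizing a scaled potential recovers the gap multiplier", {
  m <- structure(list(slope = 57.9), class = "li_frontier")
  set.seed(61)
  g <- runif(100, 0.05, 1.4)
  li <- runif(100, 0.1, 0.9)
  y_p <- predict_potential(m, li)
  expect_equal(normalize_yield(y_p * g, y_p), g, tolerance = 1e-12)
})

test_that("removing below-frontier members never lowers the decile mean", {
  set.seed(71)
  for (rep in 1:5) {
    members <- tibble::tibble(yield = rnorm(200, 2000, 400))
    before <- mean(select_upper_decile(members)$yield)
    drop <- members$yield < quantile(members$yield, runif(1, 0.1, 0.7))
    after <- mean(select_upper_decile(members[!drop, ])$yield)
    expect_gte(after, before - 1e-9)
  }
})

test_that("per-cultivar frontiers use only the requested stratum", {
  sim <- small_sim()
  dominant <- 18L
  m_all <- li_frontier(sim$plots, min_bin_count = 5)
  m_cul <- li_frontier(sim$plots, min_bin_count = 5, cultivar = dominant)
  manual <- li_frontier(sim$plots[sim$plots$cultivar_id == dominant, ],
                        min_bin_count = 5)
  expect_equal(m_cul$slope, manual$slope)
  expect_equal(glance(m_all)$intercept, 0)
})

test_that("gap records pair observed and potential yields by plot-year", {
  sim <- small_sim()
  m <- li_frontier(sim$plots, min_bin_count = 5)
  gaps <- compute_gaps(sim$plots, m)
  expect_equal(nrow(gaps), nrow(sim$plots))
  expect_equal(gaps$y_n, gaps$y_o / gaps$y_p, tolerance = 1e-12)
  expect_true(all(gaps$y_p > 0))
})
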