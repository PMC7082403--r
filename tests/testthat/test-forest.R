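mk_reg_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    x1 = runif(n, 0, 10),
    x2 = runif(n, 0, 10),
    x3 = runif(n, 0, 10),
    y = 3 * x1 + rnorm(n, 0, 0.01)
  )
}

test_that("forest fits are deterministic and sane", {
  d <- mk_reg_data()
  f1 <- fit_rf(d, "y", c("x1", "x2", "x3"), num.trees = 100, seed = 9)
  f2 <- fit_rf(d, "y", c("x1", "x2", "x3"), num.trees = 100, seed = 9)
  expect_identical(predict(f1, d), predict(f2, d))
  expect_identical(f1$oob_predictions, f2$oob_predictions)
  # training fit beats out-of-bag, which beats chance
  r2_train <- 1 - mean((d$y - predict(f1, d))^2) / var(d$y)
  r2_oob <- f1$model$r.squared
  expect_gt(r2_train, r2_oob)
  expect_gt(r2_oob, 0)
})

test_that("a constant target yields constant predictions", {
  d <- mk_reg_data()
  d$y <- 5
  f <- fit_rf(d, "y", c("x1", "x2"), num.trees = 50, seed = 1)
  expect_equal(unique(predict(f, d)), 5)
})

test_that("cultivar one-hot encoding is aligned across subsets", {
  sim <- small_sim()
  f <- fit_rf(sim$plots, "yield_kernel_lbs_acre",
              c("age", "cultivar_id"), num.trees = 30, seed = 1)
  sub <- sim$plots[sim$plots$cultivar_id == 18L, ][1:5, ]
  expect_length(predict(f, sub), 5)
})

test_that("%IncMSE ranks the informative feature first, noise near zero", {
  d <- mk_reg_data(400)
  f <- fit_rf(d, "y", c("x1", "x2", "x3"), num.trees = 200, seed = 3)
  imp <- importance_incmse(f)
  expect_equal(imp$feature[imp$rank == 1], "x1")
  expect_lt(max(abs(imp$inc_mse_pct[imp$feature != "x1"])),
            0.05 * imp$inc_mse_pct[imp$feature == "x1"])
  expect_setequal(imp$rank, 1:3)
})

test_that("tree-level and forest-level importance engines agree", {
  d <- mk_reg_data(200)
  d$y <- 2 * d$x1 + d$x2 + rnorm(200, 0, 0.5)
  f <- fit_rf(d, "y", c("x1", "x2", "x3"), num.trees = 150, seed = 5)
  fast <- importance_incmse(f)
  slow <- importance_incmse(f, n_repeats = 10, seed = 2,
                            method = "oob_forest")
  expect_equal(fast$feature[1:2], c("x1", "x2"))
  expect_equal(slow$feature[1:2], c("x1", "x2"))
  # both express percent of baseline OOB MSE: same order of magnitude
  expect_equal(slow$inc_mse_pct[1] / fast$inc_mse_pct[1], 1,
               tolerance = 0.5)
})

test_that("importance broadly agrees with an independent forest package", {
  skip_if_not_installed("randomForest")
  d <- mk_reg_data(250)
  d$y <- 2 * d$x1 + d$x2 + rnorm(250, 0, 0.5)
  f <- fit_rf(d, "y", c("x1", "x2", "x3"), num.trees = 200, seed = 5)
  imp <- importance_incmse(f)
  set.seed(5)
  rf <- randomForest::randomForest(y ~ x1 + x2 + x3, data = d,
                                   ntree = 200, importance = TRUE)
  ref <- randomForest::importance(rf, type = 1, scale = FALSE)
  expect_equal(imp$feature[1],
               rownames(ref)[which.max(ref)])
  expect_gt(cor(imp$inc_mse_pct[match(rownames(ref), imp$feature)],
                as.numeric(ref), method = "spearman"), 0.9)
})

test_that("partial dependence matches brute-force averaging and slopes", {
  d <- mk_reg_data(300)
  # mtry = p so the informative feature is always available to each split
  f <- fit_rf(d, "y", c("x1", "x2"), num.trees = 100, mtry = 2, seed = 7)
  pd <- partial_dependence(f, "x1", grid_points = 20)
  # brute-force oracle: replace the column and average predictions
  for (i in c(1, 10, 20)) {
    Xv <- f$X
    Xv$x1 <- pd$value[i]
    expect_equal(pd$response[i],
                 mean(predict(f$model, data = Xv, num.threads = 1)$predictions),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(pd$value) > 0))
  # interior slope close to the generating coefficient of 3
  interior <- pd$value > 1 & pd$value < 9
  slope <- coef(lm(pd$response[interior] ~ pd$value[interior]))[2]
  expect_equal(unname(slope), 3, tolerance = 0.2)
  # a feature the model (almost) never uses has a flat curve
  pd2 <- partial_dependence(f, "x2", grid_points = 20)
  expect_lt(diff(range(pd2$response)), 0.05 * diff(range(pd$response)))
  expect_error(partial_dependence(f, "nope"),
               class = "yieldgap_lookup_error")
})

test_that("a forced step is recovered as a single split past the jump", {
  set.seed(13)
  n <- 400
  d <- tibble::tibble(x1 = sample(0:20, n, replace = TRUE),
                      x2 = runif(n),
                      y = as.numeric(x1 > 10))
  rules <- fit_representative_tree(d, "y", c("x1", "x2"), n_candidates = 5,
                                   seed = 1, max_depth = 2, minbucket = 20)
  root <- rules$nodes[rules$nodes$node == 1, ]
  expect_equal(root$feature, "x1")
  expect_gt(root$threshold, 10)
  expect_lte(root$threshold, 11)
  expect_match(rules$rules$rule, "x1", all = TRUE)
})

test_that("leaf sample sizes partition the root and rules are consistent", {
  sim <- small_sim()
  m <- li_frontier(sim$plots, min_bin_count = 5)
  gaps <- compute_gaps(sim$plots, m)
  d <- dplyr::inner_join(sim$plots, gaps[c("plot_id", "year", "y_n")],
                         by = c("plot_id", "year"))
  rules <- fit_representative_tree(d, "y_n", c("age", "latitude"),
                                   n_candidates = 5, seed = 2,
                                   minbucket = 20)
  leaves <- rules$nodes[rules$nodes$is_leaf, ]
  root_n <- rules$nodes$n[rules$nodes$node == 1]
  expect_equal(sum(leaves$n), root_n)
  # no rule contradicts itself: every leaf is reachable (non-empty n)
  expect_true(all(leaves$n > 0))
  expect_error(fit_representative_tree(d, "y_n", "age", n_candidates = 0),
               class = "yieldgap_config_error")
})
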