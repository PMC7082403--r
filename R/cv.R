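#' Ratio of performance to interquartile distance (RPIQ)
#'
#' `RPIQ = IQR(observed) / RMSE(observed, predicted)`: a spread-normalised
#' accuracy metric; larger is better. Defined as `Inf` (with a warning) when
#' the RMSE is exactly zero.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 4).
#' @return A single unitless value.
#' @export
rpiq <- function(observed, predicted) {
  if (length(observed) < 4 || length(observed) != length(predicted)) {
    abort("At least 4 paired observations are required.",
          class = "yieldgap_invalid_input")
  }
  e <- rmse(observed, predicted)
  iqr <- unname(diff(quantile(observed, c(0.25, 0.75), type = 7)))
  if (e == 0) {
    warn("RMSE is zero; RPIQ is infinite.")
    return(Inf)
  }
  iqr / e
}

#' Feature sets for the four yield-model scenarios
#'
#' Scenario A: biological variables including measured light interception;
#' B: biological plus the full meteorological set; C: biological plus the
#' screened (selected) meteorological subset; D: biological variables
#' excluding light interception, plus the full meteorological set.
#'
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param feature_names All available feature columns.
#' @param selected Selected meteorological features (required for C).
#' @return Character vector of feature columns for the scenario.
#' @export
scenario_features <- function(scenario, feature_names, selected = NULL) {
  scenario <- match.arg(scenario, c("A", "B", "C", "D"))
  bio <- intersect(bio_vars, feature_names)
  met <- setdiff(feature_names, bio)
  switch(scenario,
    A = bio,
    B = c(bio, met),
    C = {
      if (is.null(selected)) {
        abort("Scenario C needs the `selected` meteorological features.",
              class = "yieldgap_config_error")
      }
      c(bio, intersect(feature_names, selected))
    },
    D = c(setdiff(bio, "light_interception"), met)
  )
}

#' K-fold cross-validated random-forest evaluation
#'
#' Shuffles the rows with the given seed, partitions them into `k`
#' near-equal folds, fits the forest on `k - 1` folds and scores RMSE,
#' R-squared and RPIQ on the held-out fold.
#'
#' @param data A feature table with no missing values.
#' @param target Name of the numeric target column.
#' @param features Character vector of feature columns.
#' @param k Number of folds (default 6).
#' @param seed Integer seed controlling the shuffle and the forest fits.
#' @param num.trees,mtry,min.node.size Forest hyperparameters, see
#'   [fit_rf()].
#' @param scenario Optional scenario label stored with the report.
#' @return A `cv_report` tibble with one row per fold (`fold, n_test, rmse,
#'   r2, rpiq`); `glance()` gives mean and sd of each metric.
#' @export
cross_validate <- function(data, target, features, k = 6, seed = 1,
                           num.trees = 500, mtry = NULL, min.node.size = 5,
                           scenario = NA_character_) {
  missing_cols <- setdiff(c(target, features), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) absent from the data: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "yieldgap_schema_error")
  }
  n <- nrow(data)
  if (n < 10 * k) {
    abort(sprintf("At least %d rows are required for %d-fold CV.", 10 * k, k),
          class = "yieldgap_invalid_input")
  }
  # canonicalise row order on the plot-year key (when present) so fold
  # membership -- and hence every metric -- is invariant to input row order
  if (all(c("plot_id", "year") %in% names(data))) {
    data <- data[order(data$plot_id, data$year), , drop = FALSE]
  }
  set.seed(derive_seed(seed, "cv_folds"))
  fold_of <- integer(n)
  fold_of[sample(n)] <- rep(seq_len(k), length.out = n)
  rows <- purrr::map_dfr(seq_len(k), function(f) {
    test <- which(fold_of == f)
    fit <- fit_rf(data[-test, , drop = FALSE], target, features,
                  num.trees = num.trees, mtry = mtry,
                  min.node.size = min.node.size,
                  seed = derive_seed(seed, paste0("cv_fit_", f)))
    pred <- predict(fit, data[test, , drop = FALSE])
    obs <- data[[target]][test]
    tibble(fold = f, n_test = length(test),
           rmse = rmse(obs, pred), r2 = rsq(obs, pred),
           rpiq = rpiq(obs, pred))
  })
  structure(rows, class = c("cv_report", class(rows)),
            scenario = scenario, k = k, seed = seed,
            fold_policy = "seeded uniform shuffle at the plot-year level",
            fold_assignment = fold_of)
}

#' @export
#' @method glance cv_report
glance.cv_report <- function(x, ...) {
  tibble(
    scenario = attr(x, "scenario"),
    k = attr(x, "k"),
    rmse_mean = mean(x$rmse), rmse_sd = sd(x$rmse),
    r2_mean = mean(x$r2), r2_sd = sd(x$r2),
    rpiq_mean = mean(x$rpiq), rpiq_sd = sd(x$rpiq)
  )
}

#' @export
print.cv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "%d-fold CV%s: RMSE %.1f +/- %.1f, R^2 %.3f +/- %.3f, RPIQ %.2f +/- %.2f\n",
    g$k, if (is.na(g$scenario)) "" else paste0(" [scenario ", g$scenario, "]"),
    g$rmse_mean, g$rmse_sd, g$r2_mean, g$r2_sd, g$rpiq_mean, g$rpiq_sd))
  invisible(x)
}

#' Run the full model-comparison and interpretation suite
#'
#' For the overall-yield target, evaluates scenarios A-D with k-fold
#' cross-validation; for each of the three targets (yield, normalized yield
#' `y_n`, light interception), screens meteorological features against the
#' target, fits an interpretation forest on the screened set, and extracts
#' permutation importance, top partial-dependence curves and a
#' representative decision tree. LI is excluded from the predictors of the
#' normalized-yield model (the gap statistic already conditions on LI) and
#' of the LI model itself.
#'
#' @param features Output of [build_feature_table()].
#' @param gaps Output of [compute_gaps()].
#' @param seed Master seed for this stage.
#' @param scenarios Yield scenarios to cross-validate (default A-D).
#' @param k CV folds (default 6).
#' @param cv_trees Trees per CV forest (default 500).
#' @param interp_trees Trees per interpretation forest (default 500).
#' @param n_pdp Number of top-importance features given PDP curves
#'   (default 6).
#' @param pdp_background Background rows for PDP averaging (default all).
#' @param tree_candidates Bootstrap candidates for the representative tree
#'   (default 25).
#' @param r_min,r_cross_max Screening thresholds, see [pearson_screen()].
#' @return A `scenario_report` list: `yield` (with `cv` per scenario and
#'   interpretation outputs), `gap`, `li`, and the screening results.
#' @export
run_scenarios <- function(features, gaps, seed = 1,
                          scenarios = c("A", "B", "C", "D"), k = 6,
                          cv_trees = 500, interp_trees = 500, n_pdp = 6,
                          pdp_background = NULL, tree_candidates = 25,
                          r_min = 0.15, r_cross_max = 0.50) {
  data <- features |>
    inner_join(gaps[c("plot_id", "year", "y_n")], by = c("plot_id", "year"))
  keys <- c("plot_id", "orchard_id", "cell_id", "year")
  all_feats <- setdiff(names(data), c(keys, "yield_kernel_lbs_acre", "y_n"))
  met <- setdiff(all_feats, bio_vars)

  analyse_target <- function(target, candidate_features, label) {
    sc <- pearson_screen(data, target, candidates = met,
                         r_min = r_min, r_cross_max = r_cross_max)
    feats <- c(candidate_features, selected_features(sc))
    fit <- fit_rf(data, target, feats, num.trees = interp_trees,
                  seed = derive_seed(seed, paste0("fit_", label)))
    imp <- importance_incmse(fit, seed = derive_seed(seed, paste0("imp_", label)))
    top <- head(imp$feature, n_pdp)
    pdps <- purrr::map(top, partial_dependence, fit = fit,
                       background = pdp_background,
                       seed = derive_seed(seed, paste0("pdp_", label)))
    names(pdps) <- top
    rules <- fit_representative_tree(
      data, target, feats, n_candidates = tree_candidates,
      seed = derive_seed(seed, paste0("tree_", label)))
    list(screen = sc, features = feats, fit = fit, importance = imp,
         pdp = pdps, rules = rules)
  }

  yield_screen <- pearson_screen(data, "yield_kernel_lbs_acre",
                                 candidates = met,
                                 r_min = r_min, r_cross_max = r_cross_max)
  cv <- purrr::map(scenarios, function(s) {
    cross_validate(
      data, "yield_kernel_lbs_acre",
      scenario_features(s, all_feats, selected = selected_features(yield_screen)),
      k = k, seed = derive_seed(seed, paste0("cv_", s)),
      num.trees = cv_trees, scenario = s)
  })
  names(cv) <- scenarios

  bio_no_li <- setdiff(intersect(bio_vars, all_feats), "light_interception")
  out <- list(
    yield = c(list(cv = cv),
              analyse_target("yield_kernel_lbs_acre",
                             intersect(bio_vars, all_feats), "yield")),
    gap = analyse_target("y_n", bio_no_li, "gap"),
    li = analyse_target("light_interception", bio_no_li, "li"),
    seed = seed
  )
  structure(out, class = "scenario_report")
}

#' Scenario comparison table (cross-validation summary)
#'
#' @param report A `scenario_report` from [run_scenarios()].
#' @return A tibble with one row per scenario: mean and sd of RMSE,
#'   R-squared and RPIQ across folds.
#' @export
scenario_comparison <- function(report) {
  purrr::map_dfr(report$yield$cv, glance)
}
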