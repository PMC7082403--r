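#' One-hot encode model features
#'
#' Cultivar is a nominal code; for model fitting it is expanded into
#' indicator columns `cultivar_<id>` (one per observed id, sorted). All
#' other features pass through as numeric columns.
#'
#' @param data A feature table.
#' @param features Character vector of feature column names.
#' @param cultivar_levels Optional fixed set of cultivar ids (e.g. the
#'   training levels), so encodings of different row subsets align.
#' @return A numeric data frame of encoded predictors.
#' @export
encode_features <- function(data, features, cultivar_levels = NULL) {
  stopifnot(all(features %in% names(data)))
  out <- list()
  for (f in features) {
    if (f == "cultivar_id") {
      ids <- cultivar_levels %||% sort(unique(data[[f]]))
      for (id in ids) {
        out[[sprintf("cultivar_%d", id)]] <- as.numeric(data[[f]] == id)
      }
    } else {
      out[[f]] <- as.numeric(data[[f]])
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Fit a random-forest regressor
#'
#' Thin wrapper around [ranger::ranger()] with the classic regression-forest
#' defaults (500 trees, `floor(p/3)` candidate variables per split, minimum
#' node size 5), bootstrap resampling, retained in-bag records and raw
#' out-of-bag permutation importance. Single-threaded and seeded, so fits
#' are reproducible.
#'
#' @param data A feature table with no missing values.
#' @param target Name of the numeric target column.
#' @param features Character vector of feature columns.
#' @param num.trees,mtry,min.node.size Forest hyperparameters; `mtry = NULL`
#'   uses `max(1, floor(p/3))` over the encoded predictors.
#' @param seed Integer seed.
#' @return An `rf_fit` object wrapping the ranger model, the encoded
#'   training predictors, the target vector and out-of-bag error.
#' @export
fit_rf <- function(data, target, features, num.trees = 500, mtry = NULL,
                   min.node.size = 5, seed = 1) {
  y <- data[[target]]
  if (is.null(y)) {
    abort(sprintf("Target column `%s` not found.", target),
          class = "yieldgap_schema_error")
  }
  X <- encode_features(data, features)
  if (anyNA(X) || anyNA(y)) {
    abort("Missing values in predictors or target.",
          class = "yieldgap_invalid_input")
  }
  if (nrow(X) < 2 * min.node.size) {
    abort("Too few rows for the requested minimum node size.",
          class = "yieldgap_config_error")
  }
  mtry <- mtry %||% max(1, floor(ncol(X) / 3))
  model <- ranger::ranger(
    x = X, y = y,
    num.trees = num.trees, mtry = mtry, min.node.size = min.node.size,
    importance = "permutation", scale.permutation.importance = FALSE,
    keep.inbag = TRUE, oob.error = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(
    model = model,
    X = X,
    y = y,
    target = target,
    features = features,
    cultivar_levels = if ("cultivar_id" %in% features)
      sort(unique(data$cultivar_id)),
    encoded_features = names(X),
    oob_predictions = model$predictions,
    oob_mse = mean((y - model$predictions)^2),
    seed = seed
  ), class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  X <- if (all(object$encoded_features %in% names(newdata))) {
    newdata[object$encoded_features]
  } else {
    encode_features(newdata, object$features, object$cultivar_levels)
  }
  predict(object$model, data = X, num.threads = 1)$predictions
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("Random-forest regressor for `%s` (%d trees, %d features)\n",
              x$target, x$model$num.trees, length(x$encoded_features)))
  cat(sprintf("  OOB MSE: %.4g, OOB R^2: %.4f\n", x$oob_mse,
              x$model$r.squared))
  invisible(x)
}

#' @export
#' @method glance rf_fit
glance.rf_fit <- function(x, ...) {
  tibble(target = x$target, num_trees = x$model$num.trees,
         mtry = x$model$mtry, n = length(x$y),
         oob_mse = x$oob_mse, oob_r2 = x$model$r.squared)
}

#' Out-of-bag permutation importance (%IncMSE)
#'
#' Percent increase in out-of-bag mean-square error when a predictor's
#' values are permuted, relative to the baseline out-of-bag MSE of the full
#' model. The default engine (`"oob_tree"`) uses the classic per-tree
#' permutation scheme computed during fitting (one permutation draw per
#' tree, so the number of repeats equals the number of trees). The
#' `"oob_forest"` engine re-permutes each feature `n_repeats` times across
#' the whole table and rescores forest-level out-of-bag predictions; it is
#' slower and intended for verification at small n.
#'
#' @param fit An [fit_rf()] model.
#' @param n_repeats Permutation repeats for the `"oob_forest"` engine
#'   (default 10).
#' @param seed Integer seed for the `"oob_forest"` permutations.
#' @param method `"oob_tree"` (default) or `"oob_forest"`.
#' @return An `importance_table` tibble: `feature, inc_mse_pct, rank`, with
#'   the repeat count and seed as attributes.
#' @export
importance_incmse <- function(fit, n_repeats = 10, seed = 1,
                              method = c("oob_tree", "oob_forest")) {
  stopifnot(inherits(fit, "rf_fit"))
  method <- match.arg(method)
  if (method == "oob_tree") {
    raw <- fit$model$variable.importance
    inc <- 100 * raw / fit$oob_mse
    repeats <- fit$model$num.trees
  } else {
    inc <- oob_forest_importance(fit, n_repeats, seed)
    repeats <- n_repeats
  }
  out <- tibble(feature = names(inc), inc_mse_pct = unname(inc)) |>
    arrange(desc(.data$inc_mse_pct), .data$feature) |>
    mutate(rank = row_number())
  structure(out, class = c("importance_table", class(out)),
            n_repeats = repeats, seed = seed, method = method)
}

# forest-level OOB permutation importance: per-tree predictions are averaged
# over the trees for which each row is out of bag, before and after
# permuting one feature at a time.
oob_forest_importance <- function(fit, n_repeats, seed) {
  inbag <- do.call(cbind, fit$model$inbag.counts)  # n x trees
  oob <- inbag == 0
  has_oob <- rowSums(oob) > 0
  oob_mean <- function(pred_all) {
    rowSums(pred_all * oob) / pmax(1, rowSums(oob))
  }
  base_all <- predict(fit$model, data = fit$X, predict.all = TRUE,
                      num.threads = 1)$predictions
  base <- oob_mean(base_all)
  mse0 <- mean((fit$y[has_oob] - base[has_oob])^2)
  set.seed(seed)
  vapply(names(fit$X), function(f) {
    delta <- vapply(seq_len(n_repeats), function(r) {
      Xp <- fit$X
      Xp[[f]] <- Xp[[f]][sample(nrow(Xp))]
      pp <- predict(fit$model, data = Xp, predict.all = TRUE,
                    num.threads = 1)$predictions
      pm <- oob_mean(pp)
      mean((fit$y[has_oob] - pm[has_oob])^2) - mse0
    }, numeric(1))
    100 * mean(delta) / mse0
  }, numeric(1))
}

#' Partial dependence of the model response on one feature
#'
#' For each grid value `v` (equally spaced between the 1st and 99th
#' percentile of the feature), the response is the mean model prediction
#' over the background rows with that feature set to `v`.
#'
#' @param fit An [fit_rf()] model.
#' @param feature Name of an encoded feature.
#' @param grid_points Number of grid values (default 50).
#' @param background Optional number of background rows to subsample
#'   (default: all training rows).
#' @param seed Seed for the background subsample.
#' @return A `pdp_curve` tibble `value, response` with the grid policy as
#'   attributes.
#' @export
partial_dependence <- function(fit, feature, grid_points = 50,
                               background = NULL, seed = 1) {
  stopifnot(inherits(fit, "rf_fit"))
  if (!feature %in% names(fit$X)) {
    abort(sprintf("Feature `%s` is not in the model.", feature),
          class = "yieldgap_lookup_error")
  }
  X <- fit$X
  if (!is.null(background) && background < nrow(X)) {
    set.seed(seed)
    X <- X[sample(nrow(X), background), , drop = FALSE]
  }
  qs <- quantile(fit$X[[feature]], c(0.01, 0.99), type = 7, names = FALSE)
  grid <- unique(seq(qs[1], qs[2], length.out = grid_points))
  response <- vapply(grid, function(v) {
    Xv <- X
    Xv[[feature]] <- v
    mean(predict(fit$model, data = Xv, num.threads = 1)$predictions)
  }, numeric(1))
  out <- tibble(value = grid, response = response)
  structure(out, class = c("pdp_curve", class(out)),
            feature = feature, grid_points = grid_points,
            grid_policy = "equally spaced between 1st and 99th percentile",
            background = nrow(X))
}

#' Representative regression tree and its decision rules
#'
#' Fits `n_candidates` CART regression trees on bootstrap resamples, scores
#' each by RMSE on its out-of-bag rows, and returns the best tree as an
#' explicit rule set: internal nodes carry `(feature, threshold, n, mean
#' response)` and each leaf is described by the conjunction of predicates on
#' its path.
#'
#' @param data A feature table.
#' @param target Name of the numeric target column.
#' @param features Character vector of feature columns.
#' @param n_candidates Number of bootstrap candidate trees (default 25).
#' @param seed Integer seed.
#' @param max_depth Maximum tree depth (default 3).
#' @param minbucket Minimum observations per leaf (default 50).
#' @param cp rpart complexity parameter (default 0.001).
#' @return A `decision_rules` object: `nodes` and `rules` tibbles, the
#'   out-of-bag RMSE of the chosen tree and the fitted rpart object.
#' @export
fit_representative_tree <- function(data, target, features,
                                    n_candidates = 25, seed = 1,
                                    max_depth = 3, minbucket = 50,
                                    cp = 0.001) {
  if (n_candidates < 1) {
    abort("`n_candidates` must be at least 1.", class = "yieldgap_config_error")
  }
  X <- encode_features(data, features)
  y <- data[[target]]
  df <- cbind(.target = y, X)
  control <- rpart::rpart.control(maxdepth = max_depth,
                                  minbucket = min(minbucket, floor(nrow(df) / 4)),
                                  cp = cp, xval = 0,
                                  maxcompete = 0, maxsurrogate = 0)
  set.seed(seed)
  best <- NULL
  best_rmse <- Inf
  best_idx <- NA_integer_
  for (i in seq_len(n_candidates)) {
    idx <- sample(nrow(df), replace = TRUE)
    oob <- setdiff(seq_len(nrow(df)), unique(idx))
    fit <- rpart::rpart(.target ~ ., data = df[idx, , drop = FALSE],
                        method = "anova", control = control)
    score <- if (length(oob) > 0) {
      rmse(df$.target[oob], predict(fit, df[oob, , drop = FALSE]))
    } else {
      rmse(df$.target, predict(fit, df))
    }
    if (score < best_rmse) {
      best <- fit
      best_rmse <- score
      best_idx <- i
    }
  }
  if (nrow(best$frame) < 2) {
    abort("Tree constraints left no split; relax depth/leaf settings.",
          class = "yieldgap_config_error")
  }
  nodes <- tree_nodes(best)
  structure(list(
    nodes = nodes,
    rules = tree_rules(nodes),
    oob_rmse = best_rmse,
    candidate = best_idx,
    n_candidates = n_candidates,
    model = best
  ), class = "decision_rules")
}

# decode the rpart frame/splits pair into an explicit node table; primary
# splits appear in `splits` blockwise per internal node, in frame order
tree_nodes <- function(fit) {
  frame <- fit$frame
  node <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  feature <- ifelse(is_leaf, NA_character_, as.character(frame$var))
  threshold <- rep(NA_real_, nrow(frame))
  direction <- rep(NA_real_, nrow(frame))
  idx <- 1
  for (i in seq_len(nrow(frame))) {
    if (!is_leaf[i]) {
      threshold[i] <- fit$splits[idx, "index"]
      direction[i] <- fit$splits[idx, "ncat"]  # -1: left is <, +1: left is >=
      idx <- idx + 1 + frame$ncompete[i] + frame$nsurrogate[i]
    }
  }
  tibble(node = node, is_leaf = is_leaf, feature = feature,
         threshold = threshold, split_direction = direction,
         n = frame$n, mean_response = frame$yval) |>
    arrange(.data$node)
}

tree_rules <- function(nodes) {
  leaves <- nodes |> filter(.data$is_leaf)
  info <- nodes[match(seq_len(max(nodes$node)), nodes$node), ]
  rule_for <- function(leaf) {
    preds <- character(0)
    child <- leaf
    while (child > 1) {
      parent <- child %/% 2
      left <- child %% 2 == 0
      op <- if (info$split_direction[parent] < 0) {
        if (left) "<" else ">="
      } else {
        if (left) ">=" else "<"
      }
      preds <- c(sprintf("%s %s %.4g", info$feature[parent], op,
                         info$threshold[parent]), preds)
      child <- parent
    }
    paste(preds, collapse = " & ")
  }
  leaves |>
    mutate(rule = vapply(.data$node, rule_for, character(1))) |>
    select(leaf = "node", "rule", "n", "mean_response")
}

#' @export
print.decision_rules <- function(x, ...) {
  cat(sprintf("Representative regression tree (candidate %d of %d, OOB RMSE %.4g)\n",
              x$candidate, x$n_candidates, x$oob_rmse))
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  [n=%4d, mean=%.3f] %s\n", x$rules$n[i],
                x$rules$mean_response[i], x$rules$rule[i]))
  }
  invisible(x)
}

#' @export
#' @method tidy decision_rules
tidy.decision_rules <- function(x, ...) x$nodes
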