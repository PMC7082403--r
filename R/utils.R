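#' Derive a stage-specific seed from a master seed
#'
#' Mixes a master integer seed with a stage label so that every pipeline
#' stage draws from an independent, reproducible stream, and adding a stage
#' never perturbs the randomness of existing ones.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"orchards"`, `"cv"`).
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit integer
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# shared numeric helpers ------------------------------------------------

rmse <- function(observed, predicted) {
  sqrt(mean((observed - predicted)^2))
}

rsq <- function(observed, predicted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / ss_tot
}

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
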