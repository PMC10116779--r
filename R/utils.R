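## internal helpers

## stop with a classed condition so callers/tests can match on class
stop_healthineq <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "healthineq_error"), ...)
}

assert_prob_vector <- function(p, name, tol = 1e-12) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0)) {
    stop_healthineq(
      sprintf("marginal probabilities for '%s' must be finite and non-negative", name),
      "healthineq_config_error"
    )
  }
  if (abs(sum(p) - 1) > tol) {
    stop_healthineq(
      sprintf("marginal probabilities for '%s' sum to %.15g, not 1", name, sum(p)),
      "healthineq_config_error"
    )
  }
  invisible(p)
}

## run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## derive a stream-specific 31-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + (as.integer(stream) %% 997L) * 7L + 1L
}

## weighted mean with positive-weight check
wmean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  sum(w * x) / sum(w)
}
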