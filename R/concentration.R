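#' Erreygers corrected concentration index
#'
#' For a bounded outcome `y` in `[a, b]` with weighted fractional ranks `r`,
#' the Erreygers corrected concentration index (CCI) is
#' \deqn{CCI = \frac{4\mu}{b-a} \cdot \frac{2\,cov_w(y, r)}{\mu}
#'           = \frac{8\,cov_w(y, r)}{b-a},}
#' the standard concentration index `2 cov/mu` rescaled so the attainable
#' range is `[-1, 1]` for any bounded outcome. The simplified `8 cov/(b-a)`
#' form is used throughout, so a degenerate mean (`mu = 0`) is handled
#' without dividing by it. With ranks ascending from most to least deprived
#' (the package convention), a negative index means the outcome is
#' concentrated among the most deprived.
#'
#' @param v A [ranked_vector()].
#' @return The index value (dimensionless, in `[-1, 1]`).
#' @export
#' @examples
#' v <- ranked_vector(c(1, 1, 0, 0), factor(c(2, 2, 1, 1), levels = 1:2))
#' erreygers_cci(v) # -1: perfect pro-deprived concentration
erreygers_cci <- function(v) {
  stopifnot(inherits(v, "ranked_vector"))
  8 * weighted_cov(v$y, v$r, v$w) / (v$b - v$a)
}

#' Wagstaff normalised concentration index
#'
#' The standard concentration index `C = 2 cov_w(y, r) / mu` multiplied by
#' Wagstaff's bounded-outcome normalisation `(b - a) mu / ((b - mu)(mu - a))`,
#' i.e. `2 cov_w(y, r) (b - a) / ((b - mu)(mu - a))`. Undefined when the mean
#' sits on a bound. Shares the covariance factor with [erreygers_cci()], so
#' the two variants always agree in sign; for a 0/1 outcome they satisfy
#' `Erreygers = 4 mu (1 - mu) * Wagstaff`.
#'
#' @inheritParams erreygers_cci
#' @return The index value.
#' @export
wagstaff_ci <- function(v) {
  stopifnot(inherits(v, "ranked_vector"))
  if (v$mu <= v$a || v$mu >= v$b) {
    stop_healthineq("Wagstaff normalisation undefined: mean on an outcome bound",
                    "healthineq_degenerate_error")
  }
  2 * weighted_cov(v$y, v$r, v$w) * (v$b - v$a) / ((v$b - v$mu) * (v$mu - v$a))
}

cci_statistic <- function(v, variant) {
  switch(variant,
    erreygers = erreygers_cci(v),
    wagstaff = wagstaff_ci(v),
    stop_healthineq(sprintf("unknown variant '%s'", variant),
                    "healthineq_input_error")
  )
}

#' Standard error and p-value for a concentration index
#'
#' Default method is a nonparametric bootstrap: records are resampled with
#' replacement carrying their weights, ranks are recomputed and the index
#' re-evaluated per replicate; the SE is the replicate standard deviation
#' and the p-value a two-sided normal approximation of `index / se`. The
#' alternative is a delta-method (linearisation) SE from the
#' influence-function representation of the weighted rank covariance,
#' treating ranks as fixed.
#'
#' @param v A [ranked_vector()].
#' @param variant `"erreygers"` or `"wagstaff"`.
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @param reps Bootstrap replicates (default 1000; fewer than 50 warns).
#' @param seed Integer seed for the bootstrap resampling.
#' @return List with `se`, `p_value`, `method`, `reps`.
#' @export
cci_inference <- function(v, variant = "erreygers",
                          method = c("bootstrap", "delta"),
                          reps = 1000, seed = 1) {
  stopifnot(inherits(v, "ranked_vector"))
  method <- match.arg(method)
  est <- cci_statistic(v, variant)

  if (method == "bootstrap") {
    if (reps < 50) rlang::warn("fewer than 50 bootstrap replicates is unreliable")
    n <- length(v$y)
    stats_ <- with_seed(seed, {
      vapply(seq_len(reps), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        ## fixed external ranks stay fixed; own ranks are re-estimated
        vb <- ranked_vector(v$y[idx], v$levels[idx], v$w[idx], c(v$a, v$b),
                            rank_table = v$rank_table)
        tryCatch(cci_statistic(vb, variant), error = function(e) NA_real_)
      }, numeric(1))
    })
    stats_ <- stats_[is.finite(stats_)]
    se <- sd(stats_)
    if (!is.finite(se) || se == 0) {
      stop_healthineq("degenerate bootstrap distribution (zero variance)",
                      "healthineq_degenerate_error")
    }
  } else {
    se <- delta_se(v, variant)
  }
  z <- est / se
  list(se = se, p_value = 2 * pnorm(-abs(z)), method = method,
       reps = if (method == "bootstrap") reps else NA_integer_)
}

## linearised SE treating ranks as fixed
delta_se <- function(v, variant) {
  w <- v$w / sum(v$w)
  mu <- v$mu
  rbar <- sum(w * v$r)
  cv <- sum(w * (v$y - mu) * (v$r - rbar))
  if (variant == "erreygers") {
    psi <- 8 / (v$b - v$a) * ((v$y - mu) * (v$r - rbar) - cv)
  } else {
    g <- (v$b - mu) * (mu - v$a)
    d_cov <- 2 * (v$b - v$a) / g
    d_mu <- -2 * cv * (v$b - v$a) * (v$b + v$a - 2 * mu) / g^2
    psi <- d_cov * ((v$y - mu) * (v$r - rbar) - cv) + d_mu * (v$y - mu)
  }
  sqrt(sum(w^2 * psi^2))
}

#' Concentration index of an outcome over a deprivation dimension
#'
#' Data-frame-first wrapper: builds the ranked outcome from a survey table,
#' computes the requested concentration index and (optionally) its
#' inference, and returns a fitted object with [generics::tidy()] /
#' [generics::glance()] methods. Non-responders (missing outcome) are
#' excluded; weights default to `combined_weight` if present, else
#' `design_weight`, else equal.
#'
#' @param data Survey table (one row per adult).
#' @param outcome Column name of the outcome (e.g. `"excess_weight"`,
#'   `"obese"`, or `"bmi"`).
#' @param dimension Deprivation dimension to rank on (`"imd_quintile"`,
#'   `"occupation"` or `"education"`).
#' @param weights Optional column name of the analysis weight.
#' @param variant `"erreygers"` (default) or `"wagstaff"`.
#' @param bounds Outcome bounds `c(a, b)`; default `c(0, 1)` for flags and
#'   `c(12, 60)` when `outcome == "bmi"`.
#' @param inference `"bootstrap"`, `"delta"` or `"none"`.
#' @param reps,seed Bootstrap settings, see [cci_inference()].
#' @param stratum Optional label stored with the estimate.
#' @param rank_data Optional reference table from which to compute the
#'   category ranks (e.g. the national responder set when estimating a
#'   regional stratum with nationally anchored ranks); default: ranks from
#'   `data` itself.
#' @return Object of class `cci_fit`.
#' @export
#' @examples
#' tab <- generate_population(synthetic_config(n_individuals = 400, seed = 7))
#' fit <- concentration_index(tab, "excess_weight", "imd_quintile",
#'                            inference = "delta")
#' broom::tidy(fit)
concentration_index <- function(data, outcome, dimension,
                                weights = NULL,
                                variant = c("erreygers", "wagstaff"),
                                bounds = NULL,
                                inference = c("bootstrap", "delta", "none"),
                                reps = 1000, seed = 1, stratum = "all",
                                rank_data = NULL) {
  variant <- match.arg(variant)
  inference <- match.arg(inference)
  if (!outcome %in% names(data)) {
    stop_healthineq(sprintf("outcome column '%s' not found", outcome),
                    "healthineq_input_error")
  }
  if (!dimension %in% names(data)) {
    stop_healthineq(sprintf("dimension column '%s' not found", dimension),
                    "healthineq_input_error")
  }
  bounds <- bounds %||% (if (outcome == "bmi") c(12, 60) else c(0, 1))

  keep <- !is.na(data[[outcome]])
  d <- data[keep, ]
  w <- if (!is.null(weights)) d[[weights]] else d[["combined_weight"]] %||%
    d[["design_weight"]] %||% rep(1, nrow(d))
  if (anyNA(w)) {
    stop_healthineq("analysis weights missing for some responders",
                    "healthineq_input_error")
  }
  rank_table <- NULL
  if (!is.null(rank_data)) {
    keep_r <- !is.na(rank_data[[outcome]])
    rd <- rank_data[keep_r, ]
    wr <- if (!is.null(weights)) rd[[weights]] else rd[["combined_weight"]] %||%
      rd[["design_weight"]] %||% rep(1, nrow(rd))
    rank_table <- category_fractional_ranks(rd[[dimension]], wr)
  }
  v <- ranked_vector(d[[outcome]], d[[dimension]], w, bounds,
                     rank_table = rank_table)
  est <- cci_statistic(v, variant)
  inf <- if (inference == "none") {
    list(se = NA_real_, p_value = NA_real_, method = "none", reps = NA_integer_)
  } else {
    cci_inference(v, variant, method = inference, reps = reps, seed = seed)
  }
  structure(
    list(
      index_value = est, variant = variant, se = inf$se,
      p_value = inf$p_value, n = length(v$y),
      n_effective = sum(v$w)^2 / sum(v$w^2),
      stratum = stratum, outcome = outcome, dimension = dimension,
      bounds = c(v$a, v$b), method = inf$method, reps = inf$reps
    ),
    class = "cci_fit"
  )
}

#' @export
print.cci_fit <- function(x, ...) {
  cat(sprintf("<cci_fit> %s index of %s over %s [%s]\n",
              x$variant, x$outcome, x$dimension, x$stratum))
  cat(sprintf("  %.4f (se %.4f, p %.3g, n %d)\n",
              x$index_value, x$se, x$p_value, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname concentration_index
#' @param x A `cci_fit` object.
#' @param ... Unused.
#' @export
tidy.cci_fit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, outcome = x$outcome, dimension = x$dimension,
    variant = x$variant, estimate = x$index_value, std.error = x$se,
    statistic = x$index_value / x$se, p.value = x$p_value, n = x$n
  )
}

#' @rdname concentration_index
#' @export
glance.cci_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_effective = x$n_effective, method = x$method,
    reps = x$reps, lower_bound = x$bounds[1], upper_bound = x$bounds[2]
  )
}
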