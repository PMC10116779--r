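#' Weighted logistic outcome model over a factor set
#'
#' Fits the binary outcome on categorical main effects with analysis
#' weights (weighted quasi-likelihood logistic fit) and returns the fitted
#' probabilities plus the weighted Bernoulli log-likelihood. An empty factor
#' set returns the weighted prevalence for every record. If the fit shows
#' (quasi-)separation, a ridge-penalised logistic fit (small penalty) is
#' used instead, with a warning.
#'
#' @param data Survey table rows with the outcome observed.
#' @param factors Character vector of covariate column names (may be empty).
#' @param outcome Column name of the 0/1 outcome.
#' @param weights Optional column name of the analysis weight (default:
#'   `combined_weight` if present, else equal).
#' @return List with `p` (fitted probabilities in (0, 1)), `loglik`
#'   (weighted log-likelihood), `k` (number of estimated parameters) and
#'   `n`.
#' @export
fit_outcome_model <- function(data, factors, outcome, weights = NULL) {
  y <- data[[outcome]]
  if (is.null(y) || anyNA(y) || !all(y %in% c(0, 1))) {
    stop_healthineq(sprintf("outcome '%s' must be complete and binary", outcome),
                    "healthineq_input_error")
  }
  n <- nrow(data)
  w <- if (!is.null(weights)) data[[weights]] else
    data[["combined_weight"]] %||% rep(1, n)
  w <- w / mean(w) # mean-1 normalisation keeps the loglik on the n scale

  if (length(factors) == 0) {
    p <- rep(wmean(y, w), n)
    return(list(p = p, w = w, loglik = wloglik(y, p, w), k = 1L, n = n))
  }

  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(factors, collapse = " + "))),
    data = data
  )
  fit <- suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = binomial())
  )
  p <- fit$fitted.values
  eps <- 1e-10
  if (!fit$converged || any(p < eps) || any(p > 1 - eps)) {
    rlang::warn("separation in outcome model; falling back to ridge-penalised fit")
    p <- ridge_logit_probs(X, y, w)
  }
  list(p = as.numeric(p), w = w, loglik = wloglik(y, p, w), k = ncol(X), n = n)
}

wloglik <- function(y, p, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

ridge_logit_probs <- function(X, y, w, lambda = 1e-4) {
  Xp <- X[, -1, drop = FALSE] # glmnet adds its own intercept
  fit <- glmnet::glmnet(Xp, y, family = "binomial", weights = w,
                        alpha = 0, lambda = lambda, standardize = FALSE)
  as.numeric(stats::predict(fit, Xp, type = "response"))
}

#' Dissimilarity index of fitted outcome probabilities
#'
#' `DI = sum(w |p_i - pbar|) / (2 pbar sum(w))` with `pbar` the weighted
#' mean probability: the weighted mean absolute deviation of
#' model-predicted probabilities from the overall prevalence, scaled by
#' twice the prevalence. This is the "explained inequality" quantity the
#' Shapley decomposition partitions; it is 0 when the model predicts the
#' same probability for everyone and is bounded above by `1 - pbar`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param w Positive weights (default: equal).
#' @return The dissimilarity index (dimensionless, in `[0, 1)`).
#' @export
#' @examples
#' dissimilarity_index(c(0.2, 0.6)) # 0.25
dissimilarity_index <- function(p, w = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  w <- w %||% rep(1, length(p))
  stopifnot(length(w) == length(p), all(w > 0))
  pbar <- wmean(p, w)
  if (pbar == 0) {
    stop_healthineq("mean probability is 0; dissimilarity index undefined",
                    "healthineq_degenerate_error")
  }
  sum(w * abs(p - pbar)) / (2 * pbar * sum(w))
}

#' Bayesian information criterion
#'
#' `BIC = k log(n) - 2 loglik`.
#'
#' @param loglik Log-likelihood of the fitted model.
#' @param k_params Number of estimated parameters.
#' @param n Number of observations (>= 1).
#' @return The BIC value.
#' @export
#' @examples
#' bic(-100, 3, 1000) # 220.7233
bic <- function(loglik, k_params, n) {
  stopifnot(n >= 1)
  k_params * log(n) - 2 * loglik
}

## DI for every factor subset, memoised over the 2^m lattice
subset_di <- function(data, factors, outcome, weights) {
  m <- length(factors)
  di <- numeric(2^m)
  di[1] <- 0 # DI of the empty set is defined as 0
  for (mask in seq_len(2^m - 1)) {
    members <- factors[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L]
    fit <- fit_outcome_model(data, members, outcome, weights)
    di[mask + 1] <- dissimilarity_index(fit$p, fit$w)
  }
  di
}

#' Shapley decomposition of the dissimilarity index
#'
#' Attributes the dissimilarity index of the full outcome model to its
#' factors: each factor receives the average of its marginal DI contribution
#' over all elimination sequences, computed by exact enumeration of the
#' `2^m` factor subsets with one (memoised) model fit per subset,
#' \deqn{\phi_k = \sum_{S \not\ni k} \frac{|S|!\,(m-|S|-1)!}{m!}
#'       \left[DI(S \cup \{k\}) - DI(S)\right],}
#' with `DI` of the empty set 0, so the values satisfy the efficiency axiom
#' `sum(phi) = DI(full)` exactly.
#'
#' @param data Survey table rows with the outcome observed.
#' @param factors Character vector of 2-12 covariate column names, each with
#'   at least two observed levels.
#' @param outcome Column name of the 0/1 outcome.
#' @param weights Optional weight column, see [fit_outcome_model()].
#' @param p_values `"none"` (default), or `"bootstrap"` to attach
#'   record-bootstrap p-values via [decomposition_pvalues()].
#' @param reps,seed Bootstrap settings when `p_values = "bootstrap"`.
#' @return Object of class `shapley_decomp` with the full-model DI, a
#'   per-factor tibble (`shapley_value`, `contrib_percent`, `p_value`), the
#'   full-model BIC, and `n`.
#' @export
#' @examples
#' tab <- generate_population(synthetic_config(n_individuals = 600, seed = 3))
#' dec <- shapley_decompose(tab, c("imd_quintile", "gender", "age_group"),
#'                          "excess_weight")
#' broom::tidy(dec)
shapley_decompose <- function(data, factors, outcome, weights = NULL,
                              p_values = c("none", "bootstrap"),
                              reps = 200, seed = 1) {
  p_values <- match.arg(p_values)
  m <- length(factors)
  if (m < 1 || m > 12) {
    stop_healthineq("need between 1 and 12 factors", "healthineq_input_error")
  }
  single <- factors[vapply(factors, function(f) {
    length(unique(data[[f]][!is.na(data[[outcome]])])) < 2
  }, logical(1))]
  if (length(single)) {
    stop_healthineq(
      sprintf("factor(s) with a single observed level: %s",
              paste(single, collapse = ", ")),
      "healthineq_input_error"
    )
  }

  di <- subset_di(data, factors, outcome, weights)
  phi <- shapley_from_subsets(di, m)

  full_fit <- fit_outcome_model(data, factors, outcome, weights)
  di_full <- di[length(di)]
  res <- tibble::tibble(
    factor = factors,
    shapley_value = phi,
    contrib_percent = 100 * phi / di_full,
    p_value = NA_real_
  )
  out <- structure(
    list(
      DI = di_full, factors = res, outcome = outcome, n = full_fit$n,
      loglik = full_fit$loglik, k = full_fit$k,
      bic = bic(full_fit$loglik, full_fit$k, full_fit$n),
      subset_di = di
    ),
    class = "shapley_decomp"
  )
  if (p_values == "bootstrap") {
    pv <- decomposition_pvalues(data, factors, outcome, weights,
                                reps = reps, seed = seed)
    out$factors$p_value <- pv$p_value[match(factors, pv$factor)]
    out$boot_se <- pv$se
  }
  out
}

## exact Shapley values from the 2^m subset-DI vector
shapley_from_subsets <- function(di, m) {
  masks <- 0:(2^m - 1)
  sizes <- vapply(masks, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(m - 1))) != 0L),
                  numeric(1))
  ## weight of a subset of size s in the marginal sum: s! (m-s-1)! / m!
  wt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1:m) - lfactorial(m))
  vapply(seq_len(m), function(k) {
    bit <- bitwShiftL(1L, k - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[without + 1]
    sum(wt[s + 1] * (di[without + bit + 1] - di[without + 1]))
  }, numeric(1))
}

#' Bootstrap p-values for Shapley contributions
#'
#' Nonparametric bootstrap over records: each replicate resamples rows with
#' replacement, recomputes the full Shapley decomposition, and the p-value
#' per factor is the two-sided normal-approximation test of
#' `shapley_value != 0` using the replicate SD. Non-finite replicates are
#' dropped with a log message; more than 5% dropped is an error.
#'
#' @inheritParams shapley_decompose
#' @param reps Bootstrap replicates (>= 100).
#' @return Tibble with columns `factor`, `estimate`, `se`, `p_value`.
#' @export
decomposition_pvalues <- function(data, factors, outcome, weights = NULL,
                                  reps = 200, seed = 1) {
  if (reps < 100) {
    stop_healthineq("need at least 100 bootstrap replicates", "healthineq_input_error")
  }
  m <- length(factors)
  est <- shapley_from_subsets(subset_di(data, factors, outcome, weights), m)
  n <- nrow(data)
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        suppressWarnings(
          shapley_from_subsets(subset_di(data[idx, ], factors, outcome, weights), m)
        ),
        error = function(e) rep(NA_real_, m)
      )
    }, numeric(m))
  })
  boot <- matrix(boot, nrow = m)
  ok <- colSums(!is.finite(boot)) == 0
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    rlang::inform(sprintf("decomposition_pvalues: %d replicate(s) dropped", n_drop))
  }
  if (n_drop > 0.05 * reps) {
    stop_healthineq("more than 5% of bootstrap replicates were non-finite",
                    "healthineq_degenerate_error")
  }
  se <- apply(boot[, ok, drop = FALSE], 1, sd)
  tibble::tibble(
    factor = factors, estimate = est, se = se,
    p_value = 2 * pnorm(-abs(est / se))
  )
}

#' Forward specification ladder for the decomposition
#'
#' Runs the three nested model specifications used throughout the analysis:
#' specification 1 holds intrinsic characteristics (region, age band,
#' gender, ethnic background) plus the deprivation dimension under study;
#' specification 2 adds personal circumstances (limiting illness, marital
#' status, urbanicity); specification 3 includes all three deprivation
#' dimensions jointly. Each step reports the Shapley decomposition of its
#' DI and the model BIC, so the ladder doubles as a BIC-based model
#' comparison.
#'
#' @param data Survey table rows with the outcome observed.
#' @param outcome Column name of the 0/1 outcome.
#' @param dimension Deprivation dimension under study for specifications
#'   1-2 (`"imd_quintile"`, `"occupation"` or `"education"`).
#' @param weights,p_values,reps,seed Passed to [shapley_decompose()].
#' @return Object of class `spec_ladder`: list of `shapley_decomp` objects
#'   (named `spec1`-`spec3`) plus a `bic_table` tibble.
#' @export
specification_ladder <- function(data, outcome, dimension = "imd_quintile",
                                 weights = NULL,
                                 p_values = c("none", "bootstrap"),
                                 reps = 200, seed = 1) {
  p_values <- match.arg(p_values)
  sets <- specification_factors(dimension)
  missing_cols <- setdiff(unique(unlist(sets)), names(data))
  if (length(missing_cols)) {
    stop_healthineq(
      sprintf("missing covariate column(s): %s", paste(missing_cols, collapse = ", ")),
      "healthineq_input_error"
    )
  }
  fits <- purrr::imap(sets, function(fs, nm) {
    shapley_decompose(data, fs, outcome, weights,
                      p_values = p_values, reps = reps,
                      seed = derive_seed(seed, match(nm, names(sets))))
  })
  bic_table <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(specification = nm, DI = f$DI, loglik = f$loglik,
                   k = f$k, n = f$n, bic = f$bic)
  })
  structure(list(fits = fits, bic_table = bic_table, outcome = outcome,
                 dimension = dimension),
            class = "spec_ladder")
}

## the three nested factor sets
specification_factors <- function(dimension) {
  base <- c("region", "age_group", "gender", "ethnicity")
  circumstances <- c("limiting_illness", "marital_status", "urbanicity")
  list(
    spec1 = c(base, dimension),
    spec2 = c(base, circumstances, dimension),
    spec3 = c(base, circumstances, deprivation_dimensions())
  )
}

#' @export
print.shapley_decomp <- function(x, ...) {
  cat(sprintf("<shapley_decomp> outcome %s, DI %.4f, n %d, BIC %.1f\n",
              x$outcome, x$DI, x$n, x$bic))
  print(x$factors)
  invisible(x)
}

#' @export
print.spec_ladder <- function(x, ...) {
  cat(sprintf("<spec_ladder> outcome %s, dimension %s\n", x$outcome, x$dimension))
  print(x$bic_table)
  invisible(x)
}

#' @rdname shapley_decompose
#' @param x A `shapley_decomp` object.
#' @param ... Unused.
#' @export
tidy.shapley_decomp <- function(x, ...) {
  dplyr::mutate(x$factors, outcome = x$outcome, DI = x$DI, n = x$n,
                .before = 1)
}

#' @rdname shapley_decompose
#' @export
glance.shapley_decomp <- function(x, ...) {
  tibble::tibble(DI = x$DI, n = x$n, loglik = x$loglik, k = x$k, bic = x$bic)
}

#' @rdname specification_ladder
#' @param x A `spec_ladder` object.
#' @param ... Unused.
#' @export
tidy.spec_ladder <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    dplyr::mutate(tidy(f), specification = nm, .before = 1)
  })
}

#' @rdname specification_ladder
#' @export
glance.spec_ladder <- function(x, ...) x$bic_table
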