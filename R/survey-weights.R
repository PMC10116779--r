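#' Fit the response-propensity model for BMI non-response
#'
#' Main-effects logistic regression of the response indicator on fully
#' observed covariates; the fitted probabilities feed the inverse
#' probability weights that correct complete-case selection bias under MAR.
#'
#' @param table Survey table with a `responded` indicator and complete
#'   covariates.
#' @param covariates Character vector of dimension names to use as
#'   main-effect predictors (default: all ten).
#' @return Tibble with columns `id` and `propensity` (in (0, 1]); the fitted
#'   model's deviance and degrees of freedom are attached as attribute
#'   `fit_summary`.
#' @export
fit_response_propensity <- function(table, covariates = all_dimensions()) {
  if (!"responded" %in% names(table)) {
    stop_healthineq("table has no 'responded' indicator", "healthineq_input_error")
  }
  bad <- covariates[!covariates %in% names(table)]
  if (length(bad)) {
    stop_healthineq(sprintf("covariate(s) not in table: %s", paste(bad, collapse = ", ")),
                    "healthineq_input_error")
  }
  resp <- as.integer(table$responded)

  if (all(resp == 1L)) {
    rlang::warn("all records responded; propensities set to 1 (ipw factor 1)")
    return(structure(
      tibble::tibble(id = table$id, propensity = 1),
      fit_summary = list(deviance = 0, df = 0, covariates = character(0))
    ))
  }

  ## drop single-level covariates (no information, breaks model.matrix)
  usable <- covariates[vapply(covariates, function(v) {
    length(unique(table[[v]])) > 1
  }, logical(1))]

  if (!length(usable)) {
    p <- mean(resp)
    return(structure(
      tibble::tibble(id = table$id, propensity = p),
      fit_summary = list(deviance = NA_real_, df = 0, covariates = character(0))
    ))
  }

  f <- stats::as.formula(paste("resp ~", paste(usable, collapse = " + ")))
  dat <- table[usable]
  dat$resp <- resp
  fit <- suppressWarnings(glm(f, data = dat, family = binomial()))
  p <- stats::fitted(fit)

  eps <- 1e-8
  if (any(p < eps) || any(p > 1 - eps)) {
    stop_healthineq(
      paste("response model shows (quasi-)separation: some fitted propensities",
            "are numerically 0 or 1; collapse sparse covariate levels and refit"),
      "healthineq_separation_error"
    )
  }
  structure(
    tibble::tibble(id = table$id, propensity = as.numeric(p)),
    fit_summary = list(deviance = fit$deviance, df = fit$df.residual,
                       covariates = usable)
  )
}

#' Inverse probability weighting factors
#'
#' Responders are up-weighted by the inverse of their (floored) response
#' propensity; non-responders get `NA` (they carry no analysis weight).
#'
#' @param propensity Numeric vector of response propensities in (0, 1].
#' @param responded Integer/logical response indicator (same length).
#' @param floor Lower bound applied to propensities before inversion
#'   (default 0.02), bounding the variance inflation from extreme weights.
#' @return Numeric vector of IPW factors (`NA` for non-responders).
#' @export
#' @examples
#' compute_ipw(c(0.5, 0.8), c(1, 1))
compute_ipw <- function(propensity, responded, floor = 0.02) {
  if (any(propensity <= 0, na.rm = TRUE)) {
    stop_healthineq("propensities must be > 0", "healthineq_input_error")
  }
  stopifnot(length(propensity) == length(responded))
  out <- ifelse(as.integer(responded) == 1L, 1 / pmax(propensity, floor), NA_real_)
  as.numeric(out)
}

#' Rake weights to population margins (iterative proportional fitting)
#'
#' Adjusts starting weights so the weighted marginal distribution of each
#' targeted dimension matches its population quota, cycling over dimensions
#' until every achieved margin is within `tol` of target (classical IPF /
#' raking). A single-dimension target converges in one pass
#' (post-stratification).
#'
#' @param table Survey table (rows to be raked; typically responders only).
#' @param weights Positive starting weights, one per row.
#' @param targets Margin-target tibble (`dimension`, `level`, `target`), see
#'   [margin_targets()].
#' @param tol Convergence tolerance on margin proportions (default 1e-6).
#' @param max_iter Maximum IPF cycles (default 50).
#' @return Numeric vector of raking factors (`raked weight / starting
#'   weight`), with a `convergence` attribute (iterations, max deviation).
#' @export
rake <- function(table, weights, targets, tol = 1e-6, max_iter = 50) {
  targets <- validate_margin_targets(targets)
  stopifnot(length(weights) == nrow(table), all(weights > 0))
  dims <- unique(targets$dimension)

  ## pre-resolve factor index and target vector per dimension
  plan <- lapply(dims, function(dim) {
    tg <- targets[targets$dimension == dim, ]
    lev_in_data <- as.character(unique(table[[dim]]))
    empty <- setdiff(tg$level, lev_in_data)
    if (length(empty)) {
      stop_healthineq(
        sprintf("dimension '%s' has no records at targeted level(s): %s",
                dim, paste(empty, collapse = ", ")),
        "healthineq_raking_error"
      )
    }
    idx <- match(as.character(table[[dim]]), tg$level)
    if (anyNA(idx)) {
      stop_healthineq(
        sprintf("dimension '%s' has records at levels without a target", dim),
        "healthineq_raking_error"
      )
    }
    list(dim = dim, idx = idx, target = tg$target)
  })

  w <- weights
  total <- sum(weights)
  max_dev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (pl in plan) {
      cur <- as.vector(rowsum(w, pl$idx)) / sum(w)
      w <- w * (pl$target / cur)[pl$idx]
    }
    w <- w * (total / sum(w)) # preserve the weight total across cycles
    max_dev <- max(vapply(plan, function(pl) {
      cur <- as.vector(rowsum(w, pl$idx)) / sum(w)
      max(abs(cur - pl$target))
    }, numeric(1)))
    if (max_dev <= tol) break
  }
  if (max_dev > tol) {
    stop_healthineq(
      sprintf("raking did not converge in %d iterations (max margin deviation %.2e)",
              max_iter, max_dev),
      "healthineq_raking_error",
      max_deviation = max_dev
    )
  }
  structure(w / weights,
            convergence = list(iterations = iter, max_deviation = max_dev))
}

#' Combine design, IPW and raking factors into analysis weights
#'
#' The combined weight is the product of the three factors, capped at
#' `cap_multiple` times its median (extreme-weight trimming) and normalised
#' to mean 1 over responders, so the weighted responder count equals the
#' responder count.
#'
#' @param design Positive design weights.
#' @param ipw IPW factors from [compute_ipw()] (`NA` for non-responders).
#' @param raking Raking factors (`NA` allowed for non-responders).
#' @param cap_multiple Cap on combined weights as a multiple of their median
#'   (default 5).
#' @return Tibble with columns `design_weight`, `ipw_factor`,
#'   `raking_factor`, `combined_weight` (`NA` for non-responders); number of
#'   capped weights attached as attribute `n_capped`.
#' @export
combine_weights <- function(design, ipw, raking, cap_multiple = 5) {
  stopifnot(length(design) == length(ipw), length(ipw) == length(raking))
  if (any(design <= 0, na.rm = TRUE) || any(ipw <= 0, na.rm = TRUE) ||
      any(raking <= 0, na.rm = TRUE)) {
    stop_healthineq("all weight factors must be positive", "healthineq_input_error")
  }
  combined <- design * ipw * raking
  resp <- !is.na(combined)
  cap <- cap_multiple * median(combined[resp])
  n_capped <- sum(combined[resp] > cap)
  if (n_capped > 0) {
    rlang::inform(sprintf("combine_weights: %d weight(s) capped at %.3g", n_capped, cap))
    combined[resp] <- pmin(combined[resp], cap)
  }
  combined[resp] <- combined[resp] / mean(combined[resp])
  structure(
    tibble::tibble(design_weight = design, ipw_factor = ipw,
                   raking_factor = raking, combined_weight = combined),
    n_capped = n_capped
  )
}

#' Attach analysis weights to a survey table
#'
#' Convenience wrapper running the full weighting stage: fit the response
#' propensity, invert it (floored), rake responders to the margin targets,
#' and combine with the design weight.
#'
#' @param table Survey table with `responded` and `design_weight`.
#' @param targets Margin-target tibble, or `NULL` to skip raking.
#' @param covariates Propensity-model covariates (default all ten).
#' @param floor,cap_multiple,tol,max_iter Passed to the stage functions.
#' @return The table with columns `ipw_factor`, `raking_factor` and
#'   `combined_weight` appended (`NA` for non-responders).
#' @export
add_analysis_weights <- function(table, targets = NULL,
                                 covariates = all_dimensions(),
                                 floor = 0.02, cap_multiple = 5,
                                 tol = 1e-6, max_iter = 50) {
  prop <- fit_response_propensity(table, covariates)
  ipw <- compute_ipw(prop$propensity, table$responded, floor = floor)

  raking <- rep(NA_real_, nrow(table))
  resp <- table$responded == 1L
  if (!is.null(targets)) {
    start <- table$design_weight[resp] * ipw[resp]
    raking[resp] <- rake(table[resp, ], start, targets,
                         tol = tol, max_iter = max_iter)
  } else {
    raking[resp] <- 1
  }

  wv <- combine_weights(table$design_weight, ipw, raking,
                        cap_multiple = cap_multiple)
  table$ipw_factor <- wv$ipw_factor
  table$raking_factor <- wv$raking_factor
  table$combined_weight <- wv$combined_weight
  table
}
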