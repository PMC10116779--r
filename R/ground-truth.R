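#' Analytic ground truth for a synthetic configuration
#'
#' Computes, by exact expectation over the discrete covariate grid (no
#' simulation), the population quantities implied by a [synthetic_config()]:
#' mean BMI, the prevalences of the three nested outcomes, the expected
#' missing-BMI fraction, and the true Erreygers corrected concentration
#' index (CCI) of each outcome over each deprivation dimension.
#'
#' The additive structure of every linear predictor is exploited: the
#' distribution of the summed covariate effects is built by convolving the
#' per-dimension effect distributions. The joint distribution of the three
#' copula-linked deprivation scales is obtained by Gauss-Hermite quadrature
#' over the shared latent factor, so the result is a deterministic
#' numerical expectation, exact up to quadrature error (64 nodes, far below
#' any tolerance used in this package). BMI-threshold outcome probabilities
#' use the Gaussian c.d.f.; the floor at `bmi_floor` is handled with the
#' censored-Gaussian mean formula and does not affect threshold
#' probabilities (the floor lies below every cut-point).
#'
#' @param config A [synthetic_config()].
#' @param distorted Use the quota-distorted sampling marginals (the
#'   distribution records are actually drawn from, default) or the
#'   undistorted target marginals.
#' @return A list of class `ground_truth`: `mean_bmi`, `prevalence` (named:
#'   excess_weight, obese, morbid), `expected_missing`, and `cci` — a tibble
#'   with one row per (outcome, dimension) giving the true Erreygers index.
#' @export
#' @examples
#' gt <- ground_truth(synthetic_config(n_individuals = 100, seed = 1))
#' gt$prevalence["excess_weight"]
#' dplyr::filter(gt$cci, outcome == "excess_weight")
ground_truth <- function(config, distorted = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  marg <- sampling_marginals(config, distorted = distorted)
  triple <- deprivation_dimensions()
  joint3 <- copula_triple_joint(marg, config$copula_rho)

  binary_mode <- !is.null(config$binary_gradient)
  eff <- if (binary_mode) config$binary_gradient$effects else config$bmi_model$effects
  icpt <- if (binary_mode) config$binary_gradient$intercept else config$bmi_model$intercept
  sigma <- config$bmi_model$residual_sd
  floor_ <- config$bmi_floor
  cuts <- c(excess_weight = 25, obese = 30, morbid = 35)

  ## P(outcome | total linear effect s)
  prev_fun <- function(s, cut) {
    if (binary_mode) {
      if (cut == 25) plogis(icpt + s) else rep(0, length(s))
    } else {
      pnorm((icpt + s - cut) / sigma)
    }
  }
  ## E[BMI | total linear effect s]
  mean_fun <- function(s) {
    if (binary_mode) {
      22 + 5 * plogis(icpt + s) # BMI pinned to 27/22 by the flag
    } else {
      m <- icpt + s
      a <- (floor_ - m) / sigma
      floor_ * pnorm(a) + m * (1 - pnorm(a)) + sigma * dnorm(a)
    }
  }

  ## distribution of the summed effects over all dimensions
  indep_dims <- setdiff(all_dimensions(), triple)
  atoms_indep <- conv_dims(eff, marg, indep_dims)
  atoms_triple <- list(
    value = as.vector(outer_sum3(eff, joint3)$value),
    prob = as.vector(joint3$prob)
  )
  atoms_all <- conv_atoms(atoms_indep, atoms_triple)

  mean_bmi <- sum(atoms_all$prob * mean_fun(atoms_all$value))
  prevalence <- vapply(cuts, function(ct) {
    sum(atoms_all$prob * prev_fun(atoms_all$value, ct))
  }, numeric(1))

  ## true CCI per (outcome, deprivation dimension)
  cci_rows <- purrr::map_dfr(triple, function(dim) {
    K <- length(marg[[dim]])
    p_lv <- marg[[dim]]
    ## per-level conditional prevalence for each outcome
    cond_prev <- matrix(0, nrow = K, ncol = length(cuts),
                        dimnames = list(NULL, names(cuts)))
    for (l in seq_len(K)) {
      atoms_l <- conditional_rest_atoms(eff, marg, joint3, dim, l, indep_dims)
      for (ct in names(cuts)) {
        cond_prev[l, ct] <- sum(atoms_l$prob * prev_fun(atoms_l$value + eff[[dim]][l], cuts[[ct]]))
      }
    }
    purrr::map_dfr(names(cuts), function(ct) {
      tibble::tibble(
        outcome = ct, dimension = dim,
        cci = cci_from_group_prevalence(p_lv, cond_prev[, ct])
      )
    })
  })

  expected_missing <- 0
  if (!is.null(config$missingness_logit)) {
    ml <- config$missingness_logit
    matoms <- conv_dims(ml$coefficients, marg, indep_dims)
    mtrip <- list(
      value = as.vector(outer_sum3(ml$coefficients, joint3)$value),
      prob = as.vector(joint3$prob)
    )
    matoms <- conv_atoms(matoms, mtrip)
    expected_missing <- sum(matoms$prob * plogis(ml$intercept + matoms$value))
  }

  structure(
    list(mean_bmi = mean_bmi, prevalence = prevalence,
         expected_missing = expected_missing, cci = cci_rows),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  mean BMI %.3f kg/m^2; prevalence: excess %.4f, obese %.4f, morbid %.4f\n",
              x$mean_bmi, x$prevalence[["excess_weight"]],
              x$prevalence[["obese"]], x$prevalence[["morbid"]]))
  cat(sprintf("  expected missing fraction %.4f\n", x$expected_missing))
  print(x$cci)
  invisible(x)
}

#' True Erreygers index from per-group prevalences
#'
#' Closed-form Erreygers corrected concentration index for a discrete
#' deprivation scale with known group shares and within-group outcome
#' prevalences. Groups are taken in coding order (level 1 = least deprived);
#' ranks run from most deprived (low rank) to least deprived (high rank), so
#' an outcome concentrated among the deprived yields a negative index.
#'
#' @param group_probs Population share of each level, in coding order
#'   (least-deprived first); must sum to 1.
#' @param group_prevalence Outcome prevalence (or bounded-outcome mean) per
#'   level, same order.
#' @param a,b Outcome bounds (defaults 0/1 for a prevalence).
#' @return The Erreygers index, `8 * cov(y, r) / (b - a)`.
#' @export
#' @examples
#' ## half the population deprived with prevalence 0.5, the rest 0:
#' cci_from_group_prevalence(c(0.5, 0.5), c(0, 0.5)) # -0.5
cci_from_group_prevalence <- function(group_probs, group_prevalence, a = 0, b = 1) {
  assert_prob_vector(group_probs, "group_probs", tol = 1e-9)
  stopifnot(length(group_probs) == length(group_prevalence), b > a)
  ## most-deprived-first ordering = reverse of coding order
  ord <- rev(seq_along(group_probs))
  p <- group_probs[ord]
  prev <- group_prevalence[ord]
  r <- cumsum(p) - p / 2
  mu <- sum(p * prev)
  covar <- sum(p * r * prev) - mu * sum(p * r)
  8 * covar / (b - a)
}

## ---- internal expectation machinery ------------------------------------

## atoms = list(value, prob); convolution of two independent atom sets
conv_atoms <- function(a, b) {
  list(
    value = as.vector(outer(a$value, b$value, "+")),
    prob = as.vector(outer(a$prob, b$prob))
  )
}

## aggregate duplicate atom values to keep sizes bounded
dedupe_atoms <- function(a, digits = 9) {
  key <- format(round(a$value, digits), scientific = TRUE, digits = 12)
  s <- rowsum(a$prob, key)
  v <- rowsum(a$value * a$prob, key) / s # prob-weighted mean of near-equal values
  list(value = as.vector(v), prob = as.vector(s))
}

## distribution of summed effects over the given independent dimensions
conv_dims <- function(effects, marg, dims) {
  atoms <- list(value = 0, prob = 1)
  for (dim in dims) {
    atoms <- conv_atoms(atoms, list(value = effects[[dim]], prob = marg[[dim]]))
    atoms <- dedupe_atoms(atoms)
  }
  atoms
}

## joint distribution of the three deprivation scales under the one-factor
## Gaussian copula, by Gauss-Hermite quadrature over the shared factor
copula_triple_joint <- function(marg, rho, n_nodes = 64) {
  dims <- deprivation_dimensions()
  sizes <- vapply(dims, function(d) length(marg[[d]]), integer(1))
  if (rho == 0) {
    pr <- outer(outer(marg[[dims[1]]], marg[[dims[2]]]), marg[[dims[3]]])
    dim(pr) <- sizes
    return(list(dims = dims, prob = pr))
  }
  gh <- pracma::gaussHermite(n_nodes)
  u <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  pr <- array(0, dim = sizes)
  thr <- lapply(dims, function(d) qnorm(c(0, cumsum(marg[[d]]))))
  for (i in seq_along(u)) {
    cond <- lapply(thr, function(t) {
      z <- (t - sqrt(rho) * u[i]) / sqrt(1 - rho)
      diff(pnorm(z))
    })
    pr <- pr + w[i] * outer(outer(cond[[1]], cond[[2]]), cond[[3]])
  }
  pr <- pr / sum(pr) # remove residual quadrature mass deficit (~1e-12)
  list(dims = dims, prob = pr)
}

## array of summed effects matching the triple-joint probability array
outer_sum3 <- function(effects, joint3) {
  d <- joint3$dims
  v <- outer(outer(effects[[d[1]]], effects[[d[2]]], "+"), effects[[d[3]]], "+")
  list(value = v)
}

## distribution of the summed effects of every dimension except `dim`,
## conditional on `dim` being at level `l`
conditional_rest_atoms <- function(effects, marg, joint3, dim, l, indep_dims) {
  if (dim %in% joint3$dims) {
    ax <- which(joint3$dims == dim)
    others <- joint3$dims[-ax]
    ## slice the joint at dim = l and renormalise
    idx <- switch(ax,
      `1` = joint3$prob[l, , ],
      `2` = joint3$prob[, l, ],
      `3` = joint3$prob[, , l]
    )
    pl <- idx / sum(idx)
    v <- outer(effects[[others[1]]], effects[[others[2]]], "+")
    rest_triple <- list(value = as.vector(v), prob = as.vector(pl))
    conv_atoms(conv_dims(effects, marg, indep_dims), rest_triple)
  } else {
    ## dim independent of the triple: condition drops it, nothing else changes
    trip <- list(
      value = as.vector(outer_sum3(effects, joint3)$value),
      prob = as.vector(joint3$prob)
    )
    conv_atoms(conv_dims(effects, marg, setdiff(indep_dims, dim)), trip)
  }
}
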