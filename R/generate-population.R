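#' Generate a synthetic survey population
#'
#' Draws `n_individuals` adult records from the generating model described by
#' a [synthetic_config()]: covariate categories from the (quota-distorted)
#' marginals with the three deprivation scales linked by a one-factor
#' Gaussian copula, BMI from the additive linear model with Gaussian
#' residual floored at `bmi_floor`, and the nested excess-weight / obesity /
#' morbid-obesity flags derived from the BMI cut-points (25, 30, 35 kg/m^2).
#' All records start as responders with observed BMI; apply
#' [impose_missingness()] afterwards to emulate BMI non-response.
#'
#' Output is byte-identical for identical `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @return A tibble (one row per adult) with columns `id`, `bmi`,
#'   `excess_weight`, `obese`, `morbid`, the ten covariate dimensions as
#'   factors with codebook levels, `design_weight` and `responded`.
#' @export
#' @examples
#' tab <- generate_population(synthetic_config(n_individuals = 100, seed = 1))
#' dplyr::count(tab, imd_quintile)
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cb <- survey_codebook()
  n <- config$n_individuals
  marg <- sampling_marginals(config)
  triple <- deprivation_dimensions()
  rho <- config$copula_rho

  with_seed(config$seed, {
    u_factor <- if (rho > 0) rnorm(n) else numeric(n)
    levels_idx <- lapply(all_dimensions(), function(dim) {
      p <- marg[[dim]]
      if (rho > 0 && dim %in% triple) {
        z <- sqrt(rho) * u_factor + sqrt(1 - rho) * rnorm(n)
        u01 <- pnorm(z)
      } else {
        u01 <- runif(n)
      }
      ## higher latent quantile -> higher level index (more deprived for the
      ## ordered scales); pmin guards the top cell against cumsum round-off
      pmin(findInterval(u01, cumsum(p), left.open = TRUE) + 1L, length(p))
    })
    names(levels_idx) <- all_dimensions()

    lin <- config$bmi_model$intercept
    for (dim in all_dimensions()) {
      lin <- lin + config$bmi_model$effects[[dim]][levels_idx[[dim]]]
    }
    lin <- unname(lin)

    if (is.null(config$binary_gradient)) {
      bmi <- lin + rnorm(n, sd = config$bmi_model$residual_sd)
      bmi <- pmax(bmi, config$bmi_floor)
    } else {
      lp <- config$binary_gradient$intercept
      for (dim in all_dimensions()) {
        lp <- lp + config$binary_gradient$effects[[dim]][levels_idx[[dim]]]
      }
      lp <- unname(lp)
      flag <- rbinom(n, 1L, plogis(lp))
      ## BMI pinned to flag-consistent values so flag/BMI invariants hold
      bmi <- ifelse(flag == 1L, 27, 22)
    }

    out <- tibble::tibble(
      id = seq_len(n),
      bmi = bmi,
      excess_weight = as.integer(bmi >= 25),
      obese = as.integer(bmi >= 30),
      morbid = as.integer(bmi >= 35)
    )
    for (dim in all_dimensions()) {
      out[[dim]] <- factor(cb[[dim]][levels_idx[[dim]]], levels = cb[[dim]])
    }
    out$design_weight <- 1
    out$responded <- 1L
    out
  })
}

#' Impose missing-at-random BMI non-response
#'
#' Masks BMI (and the derived flags) for a random subset of records, with
#' per-record missingness probability from the configured logit on observed
#' covariates only — the mechanism is MAR by construction because BMI never
#' enters the logit. `responded` is set to 0 for masked records.
#'
#' @param table A complete-BMI survey table from [generate_population()].
#' @param config The [synthetic_config()] whose `missingness_logit` to apply.
#' @return The table with `bmi` and flags set to `NA` where `responded == 0`;
#'   the realised missing fraction is attached as attribute
#'   `missing_fraction` and reported via a message.
#' @export
impose_missingness <- function(table, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (anyNA(table$bmi)) {
    stop_healthineq("table already has missing BMI; expected complete data",
                    "healthineq_input_error")
  }
  ml <- config$missingness_logit
  if (is.null(ml)) return(table)

  lp <- rep(ml$intercept, nrow(table))
  for (dim in all_dimensions()) {
    lp <- lp + ml$coefficients[[dim]][as.integer(table[[dim]])]
  }
  p_miss <- unname(plogis(lp))
  if (any(p_miss >= 1)) {
    stop_healthineq("missingness logit yields probability >= 1 for some cell",
                    "healthineq_config_error")
  }

  out <- with_seed(derive_seed(config$seed, 2L), {
    miss <- rbinom(nrow(table), 1L, p_miss) == 1L
    table$responded <- as.integer(!miss)
    table$bmi[miss] <- NA_real_
    table$excess_weight[miss] <- NA_integer_
    table$obese[miss] <- NA_integer_
    table$morbid[miss] <- NA_integer_
    table
  })
  frac <- mean(out$responded == 0L)
  rlang::inform(sprintf("impose_missingness: %.1f%% of records masked", 100 * frac))
  attr(out, "missing_fraction") <- frac
  out
}
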