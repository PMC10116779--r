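#' Configuration for the synthetic survey generator
#'
#' Builds and validates the full parameterisation of the synthetic-population
#' generator: marginal category probabilities for every covariate dimension,
#' an additive BMI model (intercept + per-level effects + Gaussian residual),
#' an optional direct log-odds model for the excess-weight flag, a
#' missing-at-random (MAR) logit for BMI non-response, per-level sampling
#' multipliers emulating quota imbalance, and a one-factor Gaussian copula
#' correlating the three deprivation scales.
#'
#' The defaults emulate the structure of the 2019 English health examination
#' survey the package is designed around: 6,387 adults across nine regions,
#' Table-style marginal distributions for age, gender, ethnicity, education
#' (8 ordered levels), occupation (6 ordered levels) and IMD quintile, a mean
#' BMI near 27.9 kg/m^2 with marginal SD near 5.6, an excess-weight
#' (BMI >= 25) prevalence near 0.68, and 18.6% MAR missingness in measured
#' BMI driven by age and limiting illness. Deprivation gradients in BMI are
#' monotone per scale (e.g. +0.4 kg/m^2 per IMD quintile step towards the
#' most deprived).
#'
#' @param n_individuals Number of records to generate (>= 1).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output tables.
#' @param region_probs Length-9 probability vector over regions (sums to 1).
#' @param category_specs Named list of marginal probability vectors for the
#'   non-region dimensions (see [survey_codebook()]); each sums to 1.
#' @param bmi_model List with `intercept` (kg/m^2), `effects` (named list of
#'   per-level additive effects in kg/m^2, one vector per dimension; missing
#'   dimensions contribute 0) and `residual_sd` (kg/m^2, > 0).
#' @param binary_gradient Optional list with `intercept` and `effects` (same
#'   shape as `bmi_model$effects`, log-odds units) specifying a direct
#'   logistic model for the excess-weight flag. When supplied the flag is
#'   drawn from this model and BMI is set to a value consistent with the flag
#'   (27 if flagged, 22 otherwise); a validation mode used for index
#'   parameter-recovery studies.
#' @param missingness_logit List with `intercept` and `coefficients` (named
#'   list of per-level log-odds offsets) for the probability that the BMI
#'   measurement is missing. Covariates only — no BMI term — so the mechanism
#'   is MAR by construction. `NULL` disables missingness.
#' @param quota_distortion Optional named list of per-level sampling
#'   multipliers; sampling marginals are proportional to
#'   `marginal * multiplier`, emulating quota under/over-shoot that raking to
#'   the true margins corrects.
#' @param copula_rho Equicorrelation of the latent Gaussian one-factor copula
#'   linking IMD quintile, education and occupation (in `[0, 1)`); 0 makes
#'   all dimensions independent.
#' @param bmi_floor Lower truncation for generated BMI (kg/m^2); values below
#'   are floored (measurement-scale censoring, not rejection).
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_population()], [impose_missingness()], [ground_truth()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_individuals = 500, seed = 1)
#' cfg$bmi_model$intercept
synthetic_config <- function(n_individuals = 6387,
                             seed = 2019L,
                             region_probs = default_region_probs(),
                             category_specs = default_category_specs(),
                             bmi_model = default_bmi_model(),
                             binary_gradient = NULL,
                             missingness_logit = default_missingness_logit(),
                             quota_distortion = default_quota_distortion(),
                             copula_rho = 0.3,
                             bmi_floor = 12) {
  cb <- survey_codebook()

  if (!is.numeric(n_individuals) || length(n_individuals) != 1 || n_individuals < 1) {
    stop_healthineq("n_individuals must be a single count >= 1", "healthineq_config_error")
  }
  n_individuals <- as.integer(n_individuals)
  seed <- as.integer(seed)

  if (length(region_probs) != length(cb$region)) {
    stop_healthineq("region_probs must have 9 entries (one per region)",
                    "healthineq_config_error")
  }
  assert_prob_vector(region_probs, "region")
  region_probs <- setNames(as.numeric(region_probs), cb$region)

  specs <- utils::modifyList(default_category_specs(), category_specs %||% list())
  for (dim in setdiff(all_dimensions(), "region")) {
    p <- specs[[dim]]
    if (is.null(p) || length(p) != length(cb[[dim]])) {
      stop_healthineq(
        sprintf("category_specs$%s must have %d entries", dim, length(cb[[dim]])),
        "healthineq_config_error"
      )
    }
    assert_prob_vector(p, dim)
    specs[[dim]] <- setNames(as.numeric(p), cb[[dim]])
  }

  bmi_model$effects <- complete_effects(bmi_model$effects %||% list(), cb)
  if (!is.numeric(bmi_model$residual_sd) || bmi_model$residual_sd <= 0) {
    stop_healthineq("bmi_model$residual_sd must be > 0", "healthineq_config_error")
  }
  if (!is.null(binary_gradient)) {
    binary_gradient$effects <- complete_effects(binary_gradient$effects %||% list(), cb)
    binary_gradient$intercept <- binary_gradient$intercept %||% 0
  }
  if (!is.null(missingness_logit)) {
    missingness_logit$coefficients <-
      complete_effects(missingness_logit$coefficients %||% list(), cb,
                       allow_minus_inf = TRUE)
    missingness_logit$intercept <- missingness_logit$intercept %||% qlogis(0.186)
  }
  if (!is.null(quota_distortion)) {
    for (dim in names(quota_distortion)) {
      m <- quota_distortion[[dim]]
      if (!dim %in% all_dimensions() || length(m) != length(cb[[dim]]) || any(m <= 0)) {
        stop_healthineq(
          sprintf("quota_distortion$%s must give one positive multiplier per level", dim),
          "healthineq_config_error"
        )
      }
      quota_distortion[[dim]] <- setNames(as.numeric(m), cb[[dim]])
    }
  }
  if (copula_rho < 0 || copula_rho >= 1) {
    stop_healthineq("copula_rho must be in [0, 1)", "healthineq_config_error")
  }

  structure(
    list(
      n_individuals = n_individuals,
      seed = seed,
      region_probs = region_probs,
      category_specs = specs,
      bmi_model = bmi_model,
      binary_gradient = binary_gradient,
      missingness_logit = missingness_logit,
      quota_distortion = quota_distortion,
      copula_rho = copula_rho,
      bmi_floor = bmi_floor
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  n_individuals:", x$n_individuals, "  seed:", x$seed, "\n")
  cat("  bmi: intercept", x$bmi_model$intercept, "kg/m^2, residual sd",
      x$bmi_model$residual_sd, "\n")
  cat("  copula_rho:", x$copula_rho,
      " missingness:", if (is.null(x$missingness_logit)) "none" else "MAR logit",
      " binary_gradient:", if (is.null(x$binary_gradient)) "none" else "set", "\n")
  invisible(x)
}

## fill unspecified dimensions with zero effects; validate lengths
complete_effects <- function(effects, cb, allow_minus_inf = FALSE) {
  out <- lapply(all_dimensions(), function(dim) {
    e <- effects[[dim]]
    if (is.null(e)) return(setNames(rep(0, length(cb[[dim]])), cb[[dim]]))
    if (length(e) != length(cb[[dim]])) {
      stop_healthineq(
        sprintf("effects for '%s' must have %d entries", dim, length(cb[[dim]])),
        "healthineq_config_error"
      )
    }
    ok <- is.finite(e) | (allow_minus_inf & e == -Inf)
    if (!all(ok)) {
      stop_healthineq(sprintf("effects for '%s' must be finite", dim),
                      "healthineq_config_error")
    }
    setNames(as.numeric(e), cb[[dim]])
  })
  setNames(out, all_dimensions())
}

#' @rdname synthetic_config
#' @export
default_region_probs <- function() {
  ## regional sample shares of the emulated 2019 survey (n = 6,387)
  n <- c(548, 833, 664, 573, 606, 771, 776, 1020, 596)
  setNames(n / sum(n), survey_codebook()$region)
}

#' @rdname synthetic_config
#' @export
default_category_specs <- function() {
  norm <- function(p) p / sum(p)
  list(
    age_group = norm(c(0.11, 0.17, 0.18, 0.18, 0.17, 0.14, 0.06)),
    gender = c(0.45, 0.55),
    ethnicity = norm(c(0.87, 0.02, 0.08, 0.03, 0.01)),
    ## level 1 = degree-equivalent ... level 8 = full-time student
    education = c(0.31, 0.11, 0.14, 0.18, 0.04, 0.01, 0.19, 0.02),
    ## level 1 = managerial/professional ... level 6 = other
    occupation = norm(c(0.39, 0.14, 0.11, 0.07, 0.28, 0.02)),
    ## level 1 = least deprived quintile ... level 5 = most deprived
    imd_quintile = c(0.21, 0.20, 0.20, 0.19, 0.20),
    limiting_illness = c(0.75, 0.25),
    marital_status = c(0.25, 0.50, 0.10, 0.07, 0.08),
    urbanicity = c(0.18, 0.82)
  )
}

#' @rdname synthetic_config
#' @export
default_bmi_model <- function() {
  list(
    intercept = 24.9,
    effects = list(
      region = c(0.6, 0.4, 0.2, 0.3, 0.6, -0.1, -0.7, -0.5, 0.4),
      age_group = c(-1.5, -0.6, 0.2, 0.7, 0.9, 0.8, 0.3),
      gender = c(0.3, 0),
      ethnicity = c(0, 0.3, -0.3, 0.8, -0.2),
      education = seq(0, 2.1, length.out = 8),
      occupation = seq(0, 1.25, length.out = 6),
      imd_quintile = seq(0, 1.6, length.out = 5),
      limiting_illness = c(0, 1.6),
      marital_status = c(0, 0.3, 0.2, 0.4, 0.5),
      urbanicity = c(0.3, 0)
    ),
    residual_sd = 5.5
  )
}

#' @rdname synthetic_config
#' @export
default_missingness_logit <- function() {
  ## intercept solved so the expected missing fraction is 0.186 under the
  ## default age/illness marginals
  list(
    intercept = -1.699012,
    coefficients = list(
      age_group = c(0.3, 0.1, 0, 0, 0, 0.2, 0.5),
      limiting_illness = c(0, 0.4)
    )
  )
}

#' @rdname synthetic_config
#' @export
default_quota_distortion <- function() {
  list(
    region = c(1.15, 1.10, 1.05, 1.00, 1.00, 0.95, 0.80, 0.90, 1.10),
    occupation = c(0.90, 1.00, 1.00, 1.00, 1.15, 1.00)
  )
}

## marginal distributions actually used for sampling (quota-distorted)
sampling_marginals <- function(config, distorted = TRUE) {
  marg <- c(list(region = config$region_probs), config$category_specs)
  marg <- marg[all_dimensions()]
  if (distorted && !is.null(config$quota_distortion)) {
    for (dim in names(config$quota_distortion)) {
      p <- marg[[dim]] * config$quota_distortion[[dim]]
      marg[[dim]] <- p / sum(p)
    }
  }
  marg
}
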