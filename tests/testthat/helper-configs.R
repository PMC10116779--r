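# Small synthetic-config builders shared across test files.

# no deprivation gradients anywhere; independent covariates; no distortion
cfg_zero_gradient <- function(n, seed) {
  synthetic_config(
    n_individuals = n, seed = seed,
    bmi_model = list(intercept = 27, effects = list(), residual_sd = 5),
    missingness_logit = NULL, quota_distortion = NULL, copula_rho = 0
  )
}

# default-style gradients but undistorted sampling and no missingness, so
# the unweighted sample draws straight from the ground-truth distribution
cfg_gradient_clean <- function(n, seed, rho = 0.3) {
  synthetic_config(
    n_individuals = n, seed = seed,
    missingness_logit = NULL, quota_distortion = NULL, copula_rho = rho
  )
}

# direct logistic excess-weight flag with an IMD log-odds gradient
cfg_binary_gradient <- function(n, seed, imd_slope = 0.3) {
  synthetic_config(
    n_individuals = n, seed = seed,
    binary_gradient = list(
      intercept = -0.5,
      effects = list(imd_quintile = imd_slope * (0:4))
    ),
    missingness_logit = NULL, quota_distortion = NULL, copula_rho = 0
  )
}

# MAR missingness driven by limiting illness, which also drives BMI, so the
# complete-case mean is biased and IPW has something to correct
cfg_mar_illness <- function(n, seed) {
  synthetic_config(
    n_individuals = n, seed = seed,
    bmi_model = list(
      intercept = 26,
      effects = list(limiting_illness = c(0, 3),
                     imd_quintile = 0.4 * (0:4)),
      residual_sd = 5
    ),
    missingness_logit = list(intercept = -2.2,
                             coefficients = list(limiting_illness = c(0, 2))),
    quota_distortion = NULL, copula_rho = 0
  )
}

# small well-formed survey fixture built in code
make_survey_fixture <- function(n = 10, seed = 1) {
  tab <- generate_population(synthetic_config(
    n_individuals = n, seed = seed, quota_distortion = NULL,
    missingness_logit = NULL
  ))
  tab
}
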