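test_that("dissimilarity index: equal probabilities, two-group hand value, bound", {
  expect_equal(dissimilarity_index(rep(0.3, 10)), 0)
  ## two equal-weight groups at 0.2 and 0.6: (0.5*0.2 + 0.5*0.2) / (2*0.4)
  expect_equal(dissimilarity_index(c(0.2, 0.6)), 0.25)
  expect_error(dissimilarity_index(rep(0, 5)), class = "healthineq_degenerate_error")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    w <- runif(length(p), 0.2, 3)
    pbar <- weighted.mean(p, w)
    expect_lt(dissimilarity_index(p, w), 1 - pbar + 1e-12)
  }
})

test_that("outcome model: empty factor set, saturated binary factor, nesting", {
  tab <- generate_population(cfg_gradient_clean(2000, seed = 21))
  f0 <- fit_outcome_model(tab, character(0), "excess_weight")
  expect_equal(unique(f0$p), mean(tab$excess_weight), tolerance = 1e-12)

  f1 <- fit_outcome_model(tab, "gender", "excess_weight")
  prev <- tapply(tab$excess_weight, tab$gender, mean)
  expect_equal(sort(unique(round(f1$p, 10))),
               sort(as.numeric(round(prev, 10))))

  ## adding a factor never decreases the in-sample log-likelihood
  f2 <- fit_outcome_model(tab, c("gender", "imd_quintile"), "excess_weight")
  expect_gte(f2$loglik, f1$loglik - 1e-8)
})

test_that("BIC follows k log(n) - 2 loglik", {
  expect_equal(bic(-100, 3, 1000), 3 * log(1000) + 200)
  expect_equal(round(bic(-100, 3, 1000), 4), 220.7233)
  expect_equal(bic(-50, 0, 10), 100)
})

test_that("Shapley axioms: efficiency, single factor, symmetry of exchangeable copies", {
  tab <- generate_population(cfg_gradient_clean(1500, seed = 23))

  ## one factor: its value is the full-model DI (efficiency with m = 1)
  d1 <- shapley_decompose(tab, "imd_quintile", "excess_weight")
  expect_equal(d1$factors$shapley_value, d1$DI, tolerance = 1e-10)

  ## identical copies of one covariate receive identical values
  tab$imd_copy <- tab$imd_quintile
  d2 <- shapley_decompose(tab, c("imd_quintile", "imd_copy", "gender"),
                          "excess_weight")
  v <- d2$factors$shapley_value
  expect_equal(v[1], v[2], tolerance = 1e-10)

  ## efficiency: values sum to the full DI
  d3 <- shapley_decompose(tab, c("imd_quintile", "gender", "age_group",
                                 "limiting_illness"), "excess_weight")
  expect_equal(sum(d3$factors$shapley_value), d3$DI, tolerance = 1e-8)
  expect_equal(sum(d3$factors$contrib_percent), 100, tolerance = 1e-6)

  ## symmetry: factor order does not change any factor's value
  d3r <- shapley_decompose(tab, rev(c("imd_quintile", "gender", "age_group",
                                      "limiting_illness")), "excess_weight")
  m <- match(d3$factors$factor, d3r$factors$factor)
  expect_equal(d3$factors$shapley_value, d3r$factors$shapley_value[m],
               tolerance = 1e-10)

  ## degenerate factor errors
  tab$const <- factor("a")
  expect_error(shapley_decompose(tab, c("const", "gender"), "excess_weight"),
               class = "healthineq_input_error")
})

test_that("subset-enumeration Shapley equals the permutation average for m = 4", {
  tab <- generate_population(cfg_gradient_clean(1000, seed = 29))
  factors <- c("imd_quintile", "gender", "age_group", "limiting_illness")
  di <- healthineq:::subset_di(tab, factors, "excess_weight", NULL)
  phi_subsets <- healthineq:::shapley_from_subsets(di, 4)
  phi_perms <- shapley_permutation_oracle(di, 4)
  expect_equal(phi_subsets, phi_perms, tolerance = 1e-12)
})

test_that("bootstrap p-values separate dominant and null factors", {
  cfg <- synthetic_config(
    n_individuals = 2500, seed = 31,
    bmi_model = list(intercept = 25,
                     effects = list(imd_quintile = 1.2 * (0:4)),
                     residual_sd = 4),
    missingness_logit = NULL, quota_distortion = NULL, copula_rho = 0
  )
  tab <- generate_population(cfg)
  pv <- decomposition_pvalues(tab, c("imd_quintile", "marital_status"),
                              "excess_weight", reps = 100, seed = 3)
  expect_lt(pv$p_value[pv$factor == "imd_quintile"], 0.01)
  expect_gt(pv$p_value[pv$factor == "marital_status"], 0.01)
  expect_error(decomposition_pvalues(tab, "imd_quintile", "excess_weight",
                                     reps = 50),
               class = "healthineq_input_error")
})

test_that("specification ladder nests factor sets and reports BIC per step", {
  sets <- healthineq:::specification_factors("imd_quintile")
  expect_true(all(sets$spec1 %in% sets$spec2))
  expect_true(all(setdiff(sets$spec2, "imd_quintile") %in% sets$spec3))
  expect_setequal(sets$spec3,
                  c("region", "age_group", "gender", "ethnicity",
                    "limiting_illness", "marital_status", "urbanicity",
                    "imd_quintile", "occupation", "education"))

  tab <- generate_population(cfg_gradient_clean(1200, seed = 33))
  lad <- specification_ladder(tab, "excess_weight", "imd_quintile")
  expect_named(lad$fits, c("spec1", "spec2", "spec3"))
  expect_equal(nrow(lad$bic_table), 3)
  expect_true(all(diff(lad$bic_table$DI) >= -1e-8) ||
                lad$bic_table$DI[3] >= lad$bic_table$DI[1])
  td <- generics::tidy(lad)
  expect_true(all(c("specification", "factor", "shapley_value",
                    "contrib_percent") %in% names(td)))
  expect_error(specification_ladder(dplyr::select(tab, -region), "excess_weight"),
               "region", class = "healthineq_input_error")
})

test_that("illness-driven outcomes put illness ahead of every spec-1 factor", {
  cfg <- synthetic_config(
    n_individuals = 4000, seed = 35,
    bmi_model = list(intercept = 26,
                     effects = list(limiting_illness = c(0, 4),
                                    imd_quintile = 0.3 * (0:4)),
                     residual_sd = 4),
    missingness_logit = NULL, quota_distortion = NULL, copula_rho = 0
  )
  tab <- generate_population(cfg)
  lad <- specification_ladder(tab, "excess_weight", "imd_quintile")
  t2 <- lad$fits$spec2$factors
  ill <- t2$contrib_percent[t2$factor == "limiting_illness"]
  spec1_factors <- setdiff(lad$fits$spec1$factors$factor, "limiting_illness")
  expect_true(all(ill > t2$contrib_percent[t2$factor %in% spec1_factors]))
})
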