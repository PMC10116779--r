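test_that("weighted fractional ranks follow the cumulative mid-rank formula", {
  ## five equally weighted singleton categories (5 = most deprived)
  r <- weighted_fractional_rank(factor(1:5, levels = 1:5))
  expect_equal(r, c(0.9, 0.7, 0.5, 0.3, 0.1))

  ## all records in one category share rank 0.5
  expect_equal(weighted_fractional_rank(factor(rep(2, 7), levels = 1:3)),
               rep(0.5, 7))

  ## category weights 0.25 / 0.50 / 0.25 (most deprived first: 0.125, 0.5, 0.875)
  lv <- factor(c(3, 2, 1), levels = 1:3) # 3 = most deprived
  r <- weighted_fractional_rank(lv, weights = c(0.25, 0.50, 0.25))
  expect_equal(r, c(0.125, 0.5, 0.875))

  expect_error(weighted_fractional_rank(factor(c("1", NA), levels = "1")),
               class = "healthineq_input_error")
})

test_that("weighted mean rank is 0.5 on random weighted instances", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    lv <- factor(sample(1:sample(2:8, 1), n, replace = TRUE))
    w <- runif(n, 0.1, 5)
    r <- weighted_fractional_rank(lv, w)
    expect_lt(abs(weighted.mean(r, w) - 0.5), 1e-10)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("weighted covariance: hand value, constant case, unweighted reduction", {
  expect_equal(weighted_cov(c(1, 0), c(0.25, 0.75)), -0.125)
  expect_equal(weighted_cov(rep(3, 10), runif(10)), 0)
  set.seed(2)
  y <- rnorm(20); r <- runif(20)
  expect_equal(weighted_cov(y, r), cov(y, r) * 19 / 20, tolerance = 1e-12)
  expect_error(weighted_cov(1, 1), class = "healthineq_input_error")
})

test_that("Erreygers index: exact values on canonical cases", {
  ## constant outcome -> 0
  v <- ranked_vector(rep(1, 6), factor(rep(1:3, 2), levels = 1:3))
  expect_equal(erreygers_cci(v), 0)

  ## perfect pro-deprived binary concentration -> -1
  v <- ranked_vector(c(1, 1, 0, 0), factor(c(2, 2, 1, 1), levels = 1:2))
  expect_equal(erreygers_cci(v), -1, tolerance = 1e-12)

  ## degenerate bounds error
  expect_error(ranked_vector(c(0, 1), factor(1:2), bounds = c(1, 1)),
               class = "healthineq_input_error")
})

test_that("Wagstaff index: perfect concentration, degenerate mean, binary identity", {
  v <- ranked_vector(c(1, 1, 0, 0), factor(c(2, 2, 1, 1), levels = 1:2))
  expect_equal(wagstaff_ci(v), -1, tolerance = 1e-12)

  vdeg <- ranked_vector(rep(0, 4), factor(c(1, 1, 2, 2), levels = 1:2))
  expect_error(wagstaff_ci(vdeg), class = "healthineq_degenerate_error")

  ## E = 4 mu (1 - mu) W for 0/1 outcomes, to 1e-12
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    lv <- factor(sample(1:5, n, replace = TRUE), levels = 1:5)
    w <- runif(n, 0.5, 2)
    v <- ranked_vector(y, lv, w)
    expect_equal(erreygers_cci(v), 4 * v$mu * (1 - v$mu) * wagstaff_ci(v),
                 tolerance = 1e-12)
    ## shared covariance factor: identical sign
    expect_equal(sign(erreygers_cci(v)), sign(wagstaff_ci(v)))
  }
})

test_that("mirror symmetry: reversing the deprivation order flips the sign", {
  set.seed(55)
  for (i in 1:10) {
    n <- 50
    K <- sample(3:6, 1)
    y <- runif(n)
    lv <- sample(1:K, n, replace = TRUE)
    w <- runif(n, 0.5, 2)
    v <- ranked_vector(y, factor(lv, levels = 1:K), w)
    v_rev <- ranked_vector(y, factor(K + 1 - lv, levels = 1:K), w)
    expect_equal(erreygers_cci(v), -erreygers_cci(v_rev), tolerance = 1e-12)
  }
})

test_that("Erreygers is invariant to affine rescaling with matching bounds", {
  set.seed(66)
  y <- runif(40, 12, 45)
  lv <- factor(sample(1:5, 40, replace = TRUE), levels = 1:5)
  w <- runif(40, 0.5, 2)
  v <- ranked_vector(y, lv, w, bounds = c(12, 60))
  for (alpha in c(0.5, 2, 10)) {
    beta <- 3
    v2 <- ranked_vector(alpha * y + beta, lv, w,
                        bounds = c(alpha * 12 + beta, alpha * 60 + beta))
    expect_equal(erreygers_cci(v2), erreygers_cci(v), tolerance = 1e-12)
  }
})

test_that("duplicating a record equals doubling its weight", {
  y <- c(1, 0, 1, 0, 1)
  lv <- factor(c(1, 2, 3, 1, 2), levels = 1:3)
  w <- c(1, 1, 1, 1, 1)
  v_dup <- ranked_vector(c(y, y[2]), factor(c(lv, lv[2]), levels = 1:3), c(w, 1))
  v_wt <- ranked_vector(y, lv, c(1, 2, 1, 1, 1))
  expect_equal(erreygers_cci(v_dup), erreygers_cci(v_wt), tolerance = 1e-12)
  expect_equal(wagstaff_ci(v_dup), wagstaff_ci(v_wt), tolerance = 1e-12)
})

test_that("formula equals the concentration-curve oracle on enumerated instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    K <- sample(2:6, 1)
    binary <- i %% 2 == 0
    y <- if (binary) rbinom(n, 1, 0.5) else runif(n)
    if (sum(y) == 0) y[1] <- if (binary) 1 else 0.5
    lv <- factor(sample(1:K, n, replace = TRUE), levels = 1:K)
    w <- if (i %% 3 == 0) rep(1, n) else runif(n, 0.2, 3)
    v <- ranked_vector(y, lv, w, c(0, 1))
    expect_equal(erreygers_cci(v), cci_curve_oracle(y, lv, w, c(0, 1)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap and delta-method standard errors agree within 15%", {
  tab <- generate_population(cfg_gradient_clean(5000, seed = 13))
  v <- ranked_vector(tab$excess_weight, tab$imd_quintile)
  boot <- cci_inference(v, "erreygers", method = "bootstrap", reps = 400, seed = 5)
  delta <- cci_inference(v, "erreygers", method = "delta")
  expect_lt(abs(boot$se - delta$se) / delta$se, 0.15)
  expect_true(boot$p_value >= 0 && boot$p_value <= 1)
})

test_that("inference warns on tiny replicate counts and errors when degenerate", {
  tab <- generate_population(cfg_gradient_clean(300, seed = 14))
  v <- ranked_vector(tab$excess_weight, tab$imd_quintile)
  expect_warning(cci_inference(v, reps = 20, seed = 1), "50")
  vconst <- ranked_vector(rep(1, 100), factor(rep(1:2, 50), levels = 1:2))
  expect_error(suppressWarnings(cci_inference(vconst, reps = 60, seed = 1)),
               class = "healthineq_degenerate_error")
})

test_that("concentration_index tidies into one estimate row", {
  tab <- generate_population(cfg_gradient_clean(800, seed = 15))
  fit <- concentration_index(tab, "excess_weight", "education",
                             inference = "delta", stratum = "England")
  td <- generics::tidy(fit)
  expect_named(td, c("stratum", "outcome", "dimension", "variant", "estimate",
                     "std.error", "statistic", "p.value", "n"))
  expect_equal(td$stratum, "England")
  expect_equal(generics::glance(fit)$n, nrow(tab))
})
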