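make_resp_table <- function(resp, group = NULL) {
  n <- length(resp)
  tibble::tibble(
    id = seq_len(n), responded = as.integer(resp),
    gender = factor(if (is.null(group)) rep("male", n) else group,
                    levels = c("male", "female")),
    design_weight = 1
  )
}

test_that("response propensity: intercept-only, all-responders and saturated cases", {
  ## 80% responders, no usable covariate -> constant 0.8
  tab <- make_resp_table(rep(c(1, 1, 1, 1, 0), 20))
  prop <- fit_response_propensity(tab, covariates = "gender")
  expect_equal(prop$propensity, rep(0.8, 100), tolerance = 1e-12)

  ## everyone responded -> warning, propensity 1
  expect_warning(p1 <- fit_response_propensity(make_resp_table(rep(1, 50)),
                                               covariates = "gender"),
                 "propensities set to 1")
  expect_equal(p1$propensity, rep(1, 50))

  ## one binary covariate, response 0.9 / 0.6 -> saturated fit recovers both
  g <- rep(c("male", "female"), each = 100)
  resp <- c(rep(c(1, 0), c(90, 10)), rep(c(1, 0), c(60, 40)))
  prop <- fit_response_propensity(make_resp_table(resp, g), covariates = "gender")
  expect_equal(unique(round(prop$propensity[1:100], 10)), 0.9)
  expect_equal(unique(round(prop$propensity[101:200], 10)), 0.6)
})

test_that("ipw factors invert floored propensities for responders only", {
  expect_equal(compute_ipw(c(0.5, 0.8), c(1, 1)), c(2, 1.25))
  expect_equal(compute_ipw(0.001, 1, floor = 0.02), 50)
  expect_true(is.na(compute_ipw(0.5, 0)))
  expect_error(compute_ipw(c(0.5, 0), c(1, 1)), class = "healthineq_input_error")
})

test_that("raking at the fixed point returns unit factors in one cycle", {
  tab <- tibble::tibble(
    gender = factor(rep(c("male", "female"), c(45, 55)),
                    levels = c("male", "female"))
  )
  targets <- tibble::tibble(dimension = "gender", level = c("male", "female"),
                            target = c(0.45, 0.55))
  f <- rake(tab, rep(1, 100), targets)
  expect_equal(as.numeric(f), rep(1, 100), tolerance = 1e-12)
  expect_equal(attr(f, "convergence")$iterations, 1L)
})

test_that("2x2 raking matches a brute-force IPF oracle to 1e-6", {
  ## cells: rows gender, cols urbanicity, counts 30,20 / 20,30
  tab <- tibble::tibble(
    gender = factor(rep(c("male", "male", "female", "female"), c(30, 20, 20, 30)),
                    levels = c("male", "female")),
    urbanicity = factor(rep(c("0", "1", "0", "1"), c(30, 20, 20, 30)),
                        levels = c("0", "1"))
  )
  targets <- dplyr::bind_rows(
    tibble::tibble(dimension = "gender", level = c("male", "female"),
                   target = c(0.6, 0.4)),
    tibble::tibble(dimension = "urbanicity", level = c("0", "1"),
                   target = c(0.5, 0.5))
  )
  f <- rake(tab, rep(1, 100), targets, tol = 1e-9)
  w <- rep(1, 100) * f

  oracle <- ipf_oracle(matrix(c(30, 20, 20, 30), 2, byrow = TRUE),
                       c(0.6, 0.4), c(0.5, 0.5))
  oracle <- oracle / sum(oracle) * 100
  got <- tapply(w, list(tab$gender, tab$urbanicity), sum)
  expect_equal(unclass(got), unclass(oracle), tolerance = 1e-6,
               ignore_attr = TRUE)

  ## achieved margins within 1e-6 of targets
  expect_lt(abs(sum(w[tab$gender == "male"]) / sum(w) - 0.6), 1e-6)
  expect_lt(abs(sum(w[tab$urbanicity == "0"]) / sum(w) - 0.5), 1e-6)

  ## raking preserves the weight total
  expect_equal(sum(w), 100, tolerance = 1e-9)

  ## idempotence: raking already-raked weights moves nothing beyond tol
  f2 <- rake(tab, w, targets, tol = 1e-9)
  expect_lt(max(abs(f2 - 1)), 1e-6)
})

test_that("single-dimension raking is exact post-stratification in one pass", {
  tab <- tibble::tibble(
    imd_quintile = factor(rep(as.character(1:5), c(10, 30, 20, 25, 15)),
                          levels = as.character(1:5))
  )
  targets <- tibble::tibble(dimension = "imd_quintile",
                            level = as.character(1:5), target = rep(0.2, 5))
  f <- rake(tab, rep(1, 100), targets)
  expect_equal(attr(f, "convergence")$iterations, 1L)
  shares <- tapply(f, tab$imd_quintile, sum) / sum(f)
  expect_equal(as.numeric(shares), rep(0.2, 5), tolerance = 1e-12)
})

test_that("raking errors name empty targeted levels", {
  tab <- tibble::tibble(gender = factor(rep("male", 10),
                                        levels = c("male", "female")))
  targets <- tibble::tibble(dimension = "gender", level = c("male", "female"),
                            target = c(0.5, 0.5))
  expect_error(rake(tab, rep(1, 10), targets), "female",
               class = "healthineq_raking_error")
})

test_that("combined weights multiply, cap at 5x median, and normalise to mean 1", {
  wv <- combine_weights(rep(1, 4), rep(1, 4), rep(1, 4))
  expect_equal(wv$combined_weight, rep(1, 4))

  wv <- combine_weights(2, 2, 0.5)
  expect_equal(wv$design_weight * wv$ipw_factor * wv$raking_factor, 2)

  w_raw <- c(rep(1, 99), 100)
  wv <- suppressMessages(combine_weights(w_raw, rep(1, 100), rep(1, 100)))
  expect_equal(attr(wv, "n_capped"), 1L)
  expect_equal(mean(wv$combined_weight), 1, tolerance = 1e-12)
  expect_error(combine_weights(-1, 1, 1), class = "healthineq_input_error")
})

test_that("IPW corrects MAR selection bias in the mean BMI", {
  cfg <- cfg_mar_illness(30000, seed = 77)
  full <- generate_population(cfg)
  full_mean <- mean(full$bmi)
  tab <- suppressMessages(impose_missingness(full, cfg))
  tab <- suppressMessages(add_analysis_weights(tab, targets = NULL))
  resp <- dplyr::filter(tab, responded == 1L)

  cc_mean <- mean(resp$bmi)
  ipw_mean <- weighted.mean(resp$bmi, resp$combined_weight)
  se <- sd(resp$bmi) / sqrt(nrow(resp))

  ## complete-case mean is clearly biased; weighted mean is not
  expect_gt(abs(cc_mean - full_mean), 4 * se)
  expect_lt(abs(ipw_mean - full_mean), 3 * se)
})

test_that("margin targets round-trip through CSV and reject bad tables", {
  cfg <- synthetic_config(n_individuals = 10, seed = 1)
  tg <- margin_targets(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_margin_targets(tg, path)
  expect_equal(read_margin_targets(path), tg)
  bad <- tg
  bad$target[1] <- bad$target[1] + 0.1
  expect_error(rake(generate_population(cfg), rep(1, 10), bad),
               class = "healthineq_io_error")
})
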