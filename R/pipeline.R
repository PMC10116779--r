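#' Validate a survey table against the codebook
#'
#' Checks that all mandatory columns are present, every categorical value is
#' a declared codebook level, design weights are positive, and BMI presence
#' matches the response indicator. Records with BMI below the plausibility
#' floor (12 kg/m^2) are excluded, with a log message; category columns are
#' converted to factors with codebook level order. Derived flags are checked
#' against the BMI cut-points and recomputed if absent.
#'
#' @param table A data frame of survey records (e.g. from [read_survey()]).
#' @param bmi_floor Plausibility floor below which BMI records are dropped.
#' @return A validated tibble; counts of dropped rows attached as attribute
#'   `n_dropped`.
#' @export
validate_survey <- function(table, bmi_floor = 12) {
  cb <- survey_codebook()
  mandatory <- c("id", "bmi", all_dimensions(), "design_weight", "responded")
  missing_cols <- setdiff(mandatory, names(table))
  if (length(missing_cols)) {
    stop_healthineq(
      sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
      "healthineq_validation_error"
    )
  }

  for (dim in all_dimensions()) {
    vals <- as.character(table[[dim]])
    bad <- which(!vals %in% cb[[dim]])
    if (length(bad)) {
      stop_healthineq(
        sprintf("row %d: unknown level '%s' for '%s' (allowed: %s)",
                bad[1], vals[bad[1]], dim, paste(cb[[dim]], collapse = ", ")),
        "healthineq_validation_error", rows = bad
      )
    }
    table[[dim]] <- factor(vals, levels = cb[[dim]])
  }

  bad_w <- which(!is.finite(table$design_weight) | table$design_weight <= 0)
  if (length(bad_w)) {
    stop_healthineq(
      sprintf("row %d: non-positive design weight", bad_w[1]),
      "healthineq_validation_error", rows = bad_w
    )
  }

  resp <- as.integer(table$responded)
  mismatch <- which((is.na(table$bmi) & resp == 1L) | (!is.na(table$bmi) & resp == 0L))
  if (length(mismatch)) {
    stop_healthineq(
      sprintf("row %d: BMI presence inconsistent with 'responded'", mismatch[1]),
      "healthineq_validation_error", rows = mismatch
    )
  }
  table$responded <- resp

  low <- which(!is.na(table$bmi) & table$bmi < bmi_floor)
  if (length(low)) {
    rlang::inform(sprintf("validate_survey: %d record(s) with BMI < %g excluded",
                          length(low), bmi_floor))
    table <- table[-low, ]
  }

  table <- derive_outcomes(table)
  out <- tibble::as_tibble(table)
  attr(out, "n_dropped") <- length(low)
  out
}

#' Derive BMI category and nested excess-weight flags
#'
#' Classifies responders' BMI into the adult categories with half-open
#' intervals `[lower, upper)`: underweight (< 18.5), healthy weight
#' (18.5-<25), overweight (25-<30), obesity I (30-<35), obesity II
#' (35-<40) and obesity III (>= 40), and sets the three nested flags
#' `excess_weight` (BMI >= 25), `obese` (>= 30), `morbid` (>= 35).
#' Underweight records keep all flags 0 and stay in every denominator.
#'
#' @param table Survey table with a `bmi` column (`NA` for non-responders).
#' @return The table with `bmi_category` and the three flags
#'   (re)computed; all `NA` where BMI is missing.
#' @export
#' @examples
#' derive_outcomes(tibble::tibble(bmi = c(18.4, 25, 29.999, 30, 41, NA)))
derive_outcomes <- function(table) {
  cuts <- c(-Inf, 18.5, 25, 30, 35, 40, Inf)
  labels <- c("underweight", "healthy", "overweight",
              "obesity_1", "obesity_2", "obesity_3")
  table$bmi_category <- cut(table$bmi, breaks = cuts, labels = labels,
                            right = FALSE)
  table$excess_weight <- as.integer(table$bmi >= 25)
  table$obese <- as.integer(table$bmi >= 30)
  table$morbid <- as.integer(table$bmi >= 35)
  table
}

#' Analysis configuration
#'
#' Declarative description of a full inequality-accounting run: the input
#' (a [synthetic_config()] or a survey CSV path), which outcomes,
#' deprivation dimensions, strata and index variants to estimate, and the
#' inference settings. The seed governs every random element and is
#' recorded in the report, so a run is regenerable bit-identically.
#'
#' @param input A [synthetic_config()] or a path to a survey CSV.
#' @param outcomes Subset of `c("excess_weight", "obese", "morbid")`.
#' @param dimensions Subset of the deprivation dimensions.
#' @param strata Subset of `c("national", "region", "gender")`.
#' @param variants Subset of `c("erreygers", "wagstaff")`.
#' @param reps Bootstrap replicates for index inference.
#' @param seed Master seed.
#' @param min_stratum_n Strata with fewer responders are skipped (logged).
#' @param rank_within_stratum Recompute fractional ranks inside each
#'   stratum (default) rather than carrying national ranks.
#' @param decompose Run the specification-ladder decomposition.
#' @param decomposition_reps Bootstrap replicates for decomposition
#'   p-values; 0 disables p-values.
#' @param targets Margin-target tibble, path to one, or `NULL` to derive
#'   from a synthetic input's quota distortion.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input,
                            outcomes = c("excess_weight", "obese", "morbid"),
                            dimensions = deprivation_dimensions(),
                            strata = "national",
                            variants = c("erreygers", "wagstaff"),
                            reps = 200, seed = 1, min_stratum_n = 100,
                            rank_within_stratum = TRUE,
                            decompose = TRUE, decomposition_reps = 0,
                            targets = NULL) {
  outcomes <- match.arg(outcomes, c("excess_weight", "obese", "morbid"),
                        several.ok = TRUE)
  dimensions <- match.arg(dimensions, deprivation_dimensions(), several.ok = TRUE)
  strata <- match.arg(strata, c("national", "region", "gender"), several.ok = TRUE)
  variants <- match.arg(variants, c("erreygers", "wagstaff"), several.ok = TRUE)
  if (!length(outcomes) || !length(dimensions)) {
    stop_healthineq("need at least one outcome and one dimension",
                    "healthineq_config_error")
  }
  structure(
    list(input = input, outcomes = outcomes, dimensions = dimensions,
         strata = strata, variants = variants, reps = reps,
         seed = as.integer(seed), min_stratum_n = min_stratum_n,
         rank_within_stratum = rank_within_stratum,
         decompose = decompose, decomposition_reps = decomposition_reps,
         targets = targets),
    class = "analysis_config"
  )
}

#' Run the full inequality-accounting analysis
#'
#' Orchestrates the pipeline described by an [analysis_config()]: input
#' acquisition (synthetic generation + MAR missingness, or CSV read) and
#' validation, weighting (response propensity, IPW, raking, combination),
#' concentration-index estimation per (stratum x outcome x dimension x
#' variant) with within-stratum fractional ranks, and the Shapley
#' specification ladder per outcome. Strata with fewer responders than
#' `min_stratum_n` are skipped with a logged reason. Fully seeded: the same
#' config yields an identical report.
#'
#' @param config An [analysis_config()].
#' @return Object of class `ineq_report`: `indices` (tidy estimate table),
#'   `skipped`, `decompositions`, `weighting` diagnostics and `meta`
#'   (seed, config hash, package version).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  ## --- input -------------------------------------------------------------
  if (inherits(config$input, "synthetic_config")) {
    tab <- generate_population(config$input)
    tab <- suppressMessages(impose_missingness(tab, config$input))
    targets <- config$targets %||% margin_targets(config$input)
  } else {
    tab <- read_survey(config$input)
    targets <- config$targets
    if (is.character(targets)) targets <- read_margin_targets(targets)
  }
  tab <- validate_survey(tab)

  ## --- weighting ---------------------------------------------------------
  tab <- suppressMessages(add_analysis_weights(tab, targets))
  responders <- dplyr::filter(tab, .data$responded == 1L)
  weighting <- tibble::tibble(
    n_total = nrow(tab),
    n_responders = nrow(responders),
    missing_fraction = 1 - nrow(responders) / nrow(tab),
    max_combined_weight = max(responders$combined_weight),
    min_combined_weight = min(responders$combined_weight)
  )

  ## --- stratified indices ------------------------------------------------
  strata_tbl <- stratum_table(responders, config$strata)
  design <- tidyr::expand_grid(
    stratum = names(strata_tbl),
    outcome = config$outcomes,
    dimension = config$dimensions,
    variant = config$variants
  )
  cell_seed <- function(i) derive_seed(config$seed, 100L + i)
  rows <- purrr::pmap(
    c(design, list(i = seq_len(nrow(design)))),
    function(stratum, outcome, dimension, variant, i) {
      d <- strata_tbl[[stratum]]
      if (nrow(d) < config$min_stratum_n) {
        return(list(skip = tibble::tibble(
          stratum = stratum, outcome = outcome, dimension = dimension,
          variant = variant, n = nrow(d),
          reason = sprintf("n = %d below floor %d", nrow(d), config$min_stratum_n)
        )))
      }
      fit <- concentration_index(
        d, outcome, dimension, weights = "combined_weight",
        variant = variant,
        inference = if (config$reps > 0) "bootstrap" else "delta",
        reps = config$reps, seed = cell_seed(i), stratum = stratum,
        rank_data = if (config$rank_within_stratum) NULL else responders
      )
      list(est = tidy(fit))
    }
  )
  indices <- purrr::map_dfr(rows, "est")
  skipped <- purrr::map_dfr(rows, "skip")

  ## --- decompositions ----------------------------------------------------
  decompositions <- NULL
  if (isTRUE(config$decompose)) {
    pv <- if (config$decomposition_reps >= 100) "bootstrap" else "none"
    decompositions <- purrr::map(
      setNames(config$outcomes, config$outcomes),
      function(oc) {
        specification_ladder(
          responders, oc, dimension = config$dimensions[1],
          weights = "combined_weight", p_values = pv,
          reps = config$decomposition_reps,
          seed = derive_seed(config$seed, 7L + match(oc, config$outcomes))
        )
      }
    )
  }

  structure(
    list(
      indices = indices, skipped = skipped, decompositions = decompositions,
      weighting = weighting,
      meta = list(
        seed = config$seed,
        config_hash = rlang::hash(unclass(config)),
        package_version = as.character(utils::packageVersion("healthineq"))
      )
    ),
    class = "ineq_report"
  )
}

## named list of responder subsets per configured stratification
stratum_table <- function(responders, strata) {
  out <- list()
  if ("national" %in% strata) out[["England"]] <- responders
  if ("region" %in% strata) {
    for (rg in levels(responders$region)) {
      out[[rg]] <- dplyr::filter(responders, .data$region == rg)
    }
  }
  if ("gender" %in% strata) {
    for (g in levels(responders$gender)) {
      out[[paste0("gender:", g)]] <- dplyr::filter(responders, .data$gender == g)
    }
  }
  out
}

#' @export
print.ineq_report <- function(x, ...) {
  cat("<ineq_report>\n")
  cat(sprintf("  %d index estimate(s), %d skipped cell(s), seed %d\n",
              nrow(x$indices), nrow(x$skipped), x$meta$seed))
  print(x$indices, n = 10)
  invisible(x)
}

#' @rdname run_analysis
#' @param x An `ineq_report`.
#' @param ... Unused.
#' @export
tidy.ineq_report <- function(x, ...) x$indices

#' @rdname run_analysis
#' @export
glance.ineq_report <- function(x, ...) {
  dplyr::bind_cols(x$weighting,
                   tibble::tibble(seed = x$meta$seed,
                                  config_hash = x$meta$config_hash))
}

#' Concordance of the two index variants
#'
#' Joins the Erreygers and Wagstaff estimates of a report on (stratum,
#' outcome, dimension) and summarises their agreement: the share of pairs
#' with the same sign, and the Spearman rank correlation of the values
#' computed within each outcome (the Wagstaff normalisation depends on the
#' outcome mean, so cross-outcome rankings are not comparable) and averaged.
#' Pairs where both estimates are within `eps` of zero are flagged unstable
#' (sign agreement is undefined noise there) and excluded from the
#' agreement share.
#'
#' @param report An `ineq_report` containing both variants.
#' @param eps Threshold below which a pair counts as degenerate.
#' @return List with `sign_agreement`, `rank_correlation`, `n_pairs`,
#'   `n_unstable` and the paired tibble.
#' @export
compare_variants <- function(report, eps = 1e-3) {
  stopifnot(inherits(report, "ineq_report"))
  idx <- report$indices
  if (!all(c("erreygers", "wagstaff") %in% idx$variant)) {
    stop_healthineq("report does not contain both index variants",
                    "healthineq_input_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(idx, "stratum", "outcome", "dimension", "variant", "estimate"),
    names_from = "variant", values_from = "estimate"
  )
  wide <- dplyr::filter(wide, !is.na(.data$erreygers) & !is.na(.data$wagstaff))
  unstable <- abs(wide$erreygers) < eps & abs(wide$wagstaff) < eps
  stable <- wide[!unstable, ]
  per_outcome <- vapply(split(wide, wide$outcome), function(d) {
    if (nrow(d) > 2) cor(d$erreygers, d$wagstaff, method = "spearman") else NA_real_
  }, numeric(1))
  list(
    sign_agreement = if (nrow(stable)) mean(sign(stable$erreygers) == sign(stable$wagstaff)) else NA_real_,
    rank_correlation = mean(per_outcome, na.rm = TRUE),
    rank_correlation_by_outcome = per_outcome,
    n_pairs = nrow(wide),
    n_unstable = sum(unstable),
    pairs = wide
  )
}

#' Reproduce the England analysis on licensed survey microdata
#'
#' Runs the full national + regional + gender-stratified pipeline on a
#' user-supplied survey extract (the restricted-access 2019 English health
#' examination survey, obtainable under licence from NHS Digital as
#' "health-survey-for-england/2019", recoded to this package's schema — see
#' [survey_codebook()]). The package does not and cannot ship that file.
#'
#' @param path Path to the recoded microdata CSV (see [read_survey()]).
#' @param targets Optional margin-target CSV path for raking.
#' @param reps Bootstrap replicates.
#' @param seed Seed.
#' @return An `ineq_report`.
#' @export
reproduce_hse_analysis <- function(path, targets = NULL, reps = 1000, seed = 2019) {
  if (!file.exists(path)) {
    stop_healthineq(
      sprintf("survey microdata not found at '%s' (restricted-access input)", path),
      "healthineq_io_error"
    )
  }
  run_analysis(analysis_config(
    input = path, strata = c("national", "region", "gender"),
    reps = reps, seed = seed, targets = targets
  ))
}
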