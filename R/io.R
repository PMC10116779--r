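#' Read and write survey tables
#'
#' Survey tables are stored as plain CSV with a one-line versioned comment
#' header (`# healthineq survey v1`). When a generating [synthetic_config()]
#' is supplied, it is written alongside as a JSON sidecar (`<path>.config.json`)
#' so a synthetic dataset travels with its provenance.
#'
#' @param table A survey table (see [generate_population()] or
#'   [validate_survey()]).
#' @param path File path for the CSV.
#' @param config Optional [synthetic_config()] to record in the sidecar.
#' @return `write_survey()` returns `path` invisibly; `read_survey()` returns
#'   a validated survey tibble with the sidecar config (if found) attached as
#'   attribute `config`.
#' @export
write_survey <- function(table, path, config = NULL) {
  header <- "# healthineq survey v1"
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  readr::write_csv(table, path, append = TRUE, col_names = TRUE)
  if (!is.null(config)) {
    cfg <- unclass(config)
    jsonlite::write_json(cfg, paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# healthineq survey")) {
    stop_healthineq("not a healthineq survey file (missing versioned header)",
                    "healthineq_io_error")
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tab <- validate_survey(tab)
  sidecar <- paste0(path, ".config.json")
  if (file.exists(sidecar)) {
    attr(tab, "config") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  tab
}

#' Read and write raking margin targets
#'
#' Margin targets are stored as CSV with columns `dimension`, `level`,
#' `target` (proportions in (0, 1]; per-dimension targets sum to 1).
#'
#' @param targets A margin-target tibble, e.g. from [margin_targets()].
#' @param path File path for the CSV.
#' @return `write_margin_targets()` returns `path` invisibly;
#'   `read_margin_targets()` returns a validated tibble.
#' @export
write_margin_targets <- function(targets, path) {
  readr::write_csv(targets, path)
  invisible(path)
}

#' @rdname write_margin_targets
#' @export
read_margin_targets <- function(path) {
  tg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_margin_targets(tg)
}

#' Margin targets implied by a synthetic configuration
#'
#' The undistorted marginal distributions of a [synthetic_config()] are the
#' population quotas the generator's quota distortion pulls the sample away
#' from; raking responders back to these margins undoes the imbalance.
#'
#' @param config A [synthetic_config()].
#' @param dimensions Which dimensions to target (default: the distorted ones,
#'   or region if none were distorted).
#' @return Tibble with columns `dimension`, `level`, `target`.
#' @export
margin_targets <- function(config, dimensions = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(dimensions)) {
    dimensions <- names(config$quota_distortion) %||% "region"
  }
  marg <- sampling_marginals(config, distorted = FALSE)
  purrr::map_dfr(dimensions, function(dim) {
    tibble::tibble(dimension = dim, level = names(marg[[dim]]),
                   target = as.numeric(marg[[dim]]))
  })
}

validate_margin_targets <- function(targets) {
  need <- c("dimension", "level", "target")
  if (!all(need %in% names(targets))) {
    stop_healthineq("margin targets need columns dimension, level, target",
                    "healthineq_io_error")
  }
  if (any(targets$target <= 0 | targets$target > 1)) {
    stop_healthineq("margin target proportions must be in (0, 1]",
                    "healthineq_io_error")
  }
  sums <- tapply(targets$target, targets$dimension, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(bad)) {
    stop_healthineq(
      sprintf("margin targets for %s do not sum to 1", paste(bad, collapse = ", ")),
      "healthineq_io_error"
    )
  }
  cb <- survey_codebook()
  for (dim in unique(targets$dimension)) {
    if (!dim %in% names(cb)) {
      stop_healthineq(sprintf("unknown dimension '%s' in margin targets", dim),
                      "healthineq_io_error")
    }
    extra <- setdiff(targets$level[targets$dimension == dim], cb[[dim]])
    if (length(extra)) {
      stop_healthineq(
        sprintf("unknown level(s) %s for dimension '%s'",
                paste(extra, collapse = ", "), dim),
        "healthineq_io_error"
      )
    }
  }
  tibble::as_tibble(targets)
}
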