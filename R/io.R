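#' Read and write trial tables
#'
#' Trials travel as delimited text (CSV) in the shared schema:
#' `subject_id, group, task, condition, staircase_id, trial_index, level,
#' level_unit, outcome`. `read_trials()` validates on load and reports the
#' first offending row and field by name.
#'
#' @param path File path.
#' @return `read_trials()` returns a validated tibble of trials.
#' @export
read_trials <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  tryCatch(
    validate_trials(data),
    error = function(e) {
      rlang::abort(sprintf("Invalid trial file '%s': %s", path,
                           conditionMessage(e)))
    }
  )
  data
}

#' @rdname read_trials
#' @param data Tibble of trials in the shared schema.
#' @export
write_trials <- function(data, path) {
  validate_trials(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Validate a trial table against the shared schema
#'
#' @param data Candidate trial tibble.
#' @return Invisibly `TRUE`; aborts with a message naming the missing
#'   column or the first offending row and field otherwise.
#' @export
validate_trials <- function(data) {
  missing <- setdiff(trial_schema, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing trial column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad_level <- which(!is.finite(data$level))
  if (length(bad_level) > 0) {
    rlang::abort(sprintf("Row %d: field 'level' is not a finite number.",
                         bad_level[1]))
  }
  bad_out <- which(!data$outcome %in% c(0, 1))
  if (length(bad_out) > 0) {
    rlang::abort(sprintf("Row %d: field 'outcome' must be 0 or 1.",
                         bad_out[1]))
  }
  known_units <- c("dB", "dB_ratio", "log2_arcsec")
  bad_unit <- which(!data$level_unit %in% known_units)
  if (length(bad_unit) > 0) {
    rlang::abort(sprintf(
      "Row %d: field 'level_unit' must be one of %s.",
      bad_unit[1], paste(known_units, collapse = ", ")))
  }
  invisible(TRUE)
}

artifact_header <- function(seed = NULL) {
  list(
    schema_version = dichoptics_schema_version,
    package = "dichoptics",
    package_version = as.character(utils::packageVersion("dichoptics")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Serialise gain-control constants and fitted parameters to JSON
#'
#' Writes a flat key-value document with the model constants
#' (`m, p, q, S, Z`), the linear and dB parameters
#' (`gR, gL, wR, wL, GR, GL, WR, WL`), and the derived suppression
#' strengths (`supstrR, supstrL`).
#'
#' @param fit A `gc_fit` from [fit_gain_control()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gc_params <- function(fit, path) {
  stopifnot(inherits(fit, "gc_fit"))
  p <- fit$params
  s <- suppression_strength(p)
  k <- fit$consts
  doc <- list(m = k$m, p = k$p, q = k$q, S = k$S, Z = k$Z,
              gR = p$gR, gL = p$gL, wR = p$wR, wL = p$wL,
              GR = p$GR, GL = p$GL, WR = p$WR, WL = p$WL,
              supstrR = s$supstrR, supstrL = s$supstrL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gc_params
#' @export
read_gc_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(doc)
}

#' Write subject summaries to JSON
#'
#' @param summaries Tibble from [analyze_subjects()].
#' @param path Output path.
#' @param seed Optional seed to stamp in the artifact header.
#' @return Invisibly, the path.
#' @export
write_subject_summaries <- function(summaries, path, seed = NULL) {
  doc <- list(header = artifact_header(seed),
              subjects = summaries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read a group report (JSON)
#'
#' The report is schema-versioned; `read_group_report()` refuses a file
#' whose schema version does not match the package's.
#'
#' @param report A `group_report` from [analyze_group()].
#' @param path File path.
#' @param seed Optional seed stamped in the header.
#' @return `write_group_report()` the path, invisibly;
#'   `read_group_report()` the parsed report as a list.
#' @export
write_group_report <- function(report, path, seed = NULL) {
  stopifnot(inherits(report, "group_report"))
  doc <- list(
    header = artifact_header(seed),
    groups = report$groups,
    n = report$n,
    descriptives = report$descriptives,
    tests = report$tests,
    anova = if (!is.null(report$anova)) {
      list(table = report$anova$table, posthoc = report$anova$posthoc)
    },
    correlations = report$correlations,
    stereo_correlations = report$stereo_correlations,
    fisher = report$fisher,
    power = report$power,
    alpha = report$alpha
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_report
#' @export
read_group_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- doc$header$schema_version
  if (is.null(sv) || !identical(sv, dichoptics_schema_version)) {
    rlang::abort(sprintf(
      "Schema version mismatch in '%s': file has '%s', package expects '%s'.",
      path, if (is.null(sv)) "<none>" else sv, dichoptics_schema_version))
  }
  doc
}
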