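#' Normalize a reported finding label against the knowledge base
#'
#' Exact lookup after case folding and punctuation/whitespace collapsing,
#' against both primary labels and synonyms. No clinical NLP is attempted:
#' a label that matches nothing returns `NA`, and such findings are retained
#' in the case (flagged unresolved) rather than dropped.
#'
#' @param raw_label character vector of reported labels.
#' @param kb a `triage_kb`.
#' @return Character vector of finding ids, `NA` where unmatched.
#' @examples
#' kb <- generate_kb(2, 4, 2, seed = 1)
#' normalize_finding(kb$findings$label[1], kb)
#' normalize_finding("xyzzy", kb)
#' @export
normalize_finding <- function(raw_label, kb) {
  lookup <- finding_lookup(kb)
  out <- unname(lookup[normalize_label(raw_label)])
  as.character(out)
}

#' Derive findings from out-of-range vital signs
#'
#' Each measured vital is compared against the age-banded reference range in
#' the configured threshold table; a value outside `[low, high]` yields one
#' derived finding (e.g. `tachycardia`, `hypotension`, `fever`, `hypoxia`).
#' Derived findings then participate in scoring exactly like reported ones.
#'
#' @param vitals named list / one-row data frame with any of `heart_rate`,
#'   `respiratory_rate`, `systolic_bp`, `temperature`, `spo2`; missing or
#'   `NA` entries are skipped.
#' @param demographics list with `age` (years) and `sex`.
#' @param thresholds threshold table as in [default_vital_thresholds()].
#' @return A tibble of derived case findings (columns `finding_id`,
#'   `raw_label`, `duration_hours`, `reported_severity`, `source`); zero
#'   rows when every vital is in range.
#' @examples
#' interpret_vitals(list(heart_rate = 130), list(age = 30, sex = "male"))
#' @export
interpret_vitals <- function(vitals, demographics,
                             thresholds = default_vital_thresholds()) {
  vitals <- vitals[!purrr::map_lgl(vitals, ~ is.null(.x) || is.na(.x))]
  if (length(vitals) == 0L) return(empty_case_findings())
  known <- unique(thresholds$vital)
  bad <- setdiff(names(vitals), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown vital(s): ", paste(bad, collapse = ", ")))
  }
  age <- demographics$age
  derived <- character()
  for (v in sort(names(vitals))) {
    value <- as.numeric(vitals[[v]])
    if (value <= 0) abort(paste0("vital '", v, "' must be positive"))
    if (v == "spo2" && value > 100) abort("spo2 cannot exceed 100")
    row <- thresholds[thresholds$vital == v &
                        age >= thresholds$age_lo &
                        age < thresholds$age_hi, , drop = FALSE]
    if (nrow(row) == 0L) {
      abort(paste0("no threshold row covers age ", age, " for vital '", v, "'"))
    }
    row <- row[1L, ]
    if (value < row$low && !is.na(row$low_finding)) {
      derived <- c(derived, row$low_finding)
    } else if (value > row$high && !is.na(row$high_finding)) {
      derived <- c(derived, row$high_finding)
    }
  }
  if (length(derived) == 0L) return(empty_case_findings())
  tibble::tibble(
    finding_id = derived,
    raw_label = derived,
    duration_hours = NA_real_,
    reported_severity = NA_integer_,
    source = "derived_from_vitals"
  )
}

empty_case_findings <- function() {
  tibble::tibble(
    finding_id = character(), raw_label = character(),
    duration_hours = numeric(), reported_severity = integer(),
    source = character()
  )
}

#' Parse one structured case record into a patient case
#'
#' Normalizes the reported finding labels against the KB, interprets vitals
#' into derived findings, and enforces the case invariants. Unknown labels
#' are never silently dropped: they are carried with `finding_id = NA` and
#' surfaced downstream in provenance notes, but a record in which *no*
#' finding resolves (and no vital is deranged) is an error — the engine has
#' nothing to score.
#'
#' @param record named list or one-row data frame with `case_id` (optional),
#'   `age`, `sex`, `findings` (character vector, or one `;`-separated
#'   string), optional `duration_hours` (scalar or one per finding),
#'   optional `reported_severity`, and optional vitals (`hr`, `rr`, `sbp`,
#'   `temp`, `spo2` or full names).
#' @param kb a `triage_kb`.
#' @param config a [triage_config()] (supplies vital thresholds).
#' @return An object of class `patient_case`: list with `case_id`,
#'   `demographics`, `findings` tibble, `vitals`.
#' @seealso [read_cases()], [triage_case()]
#' @export
parse_case <- function(record, kb, config = triage_config()) {
  record <- as.list(record)
  if (is.null(record$age) || is.null(record$sex)) {
    abort("case record must provide 'age' and 'sex'")
  }
  age <- as.numeric(record$age)
  if (is.na(age) || age < 0) abort("field 'age' must be a non-negative number")
  sex <- as.character(record$sex)
  if (!sex %in% c("female", "male", "unknown")) {
    abort("field 'sex' must be one of female/male/unknown")
  }
  demographics <- list(age = age, sex = sex)

  labels <- record$findings
  if (is.list(labels)) labels <- unlist(labels, use.names = FALSE)
  if (length(labels) == 1L && grepl(";", labels %||% "")) {
    labels <- trimws(strsplit(labels, ";", fixed = TRUE)[[1]])
  }
  labels <- as.character(labels[!is.na(labels) & nzchar(labels)])

  durations <- record$duration_hours
  if (is.null(durations)) durations <- NA_real_
  durations <- suppressWarnings(as.numeric(unlist(durations)))
  durations <- rep_len(durations, max(length(labels), 1L))
  severities <- record$reported_severity
  if (is.null(severities)) severities <- NA_integer_
  severities <- rep_len(as.integer(unlist(severities)),
                        max(length(labels), 1L))

  reported <- if (length(labels) > 0L) {
    tibble::tibble(
      finding_id = normalize_finding(labels, kb),
      raw_label = labels,
      duration_hours = durations,
      reported_severity = severities,
      source = "reported"
    )
  } else {
    empty_case_findings()
  }

  vital_alias <- c(hr = "heart_rate", rr = "respiratory_rate",
                   sbp = "systolic_bp", temp = "temperature", spo2 = "spo2",
                   heart_rate = "heart_rate",
                   respiratory_rate = "respiratory_rate",
                   systolic_bp = "systolic_bp", temperature = "temperature")
  vitals <- record[names(record) %in% names(vital_alias)]
  names(vitals) <- vital_alias[names(vitals)]
  vitals <- purrr::map(vitals, ~ suppressWarnings(as.numeric(.x)))
  vitals <- vitals[!purrr::map_lgl(vitals, ~ is.null(.x) || is.na(.x))]
  derived <- interpret_vitals(vitals, demographics,
                              thresholds = config$vital_thresholds)
  if (nrow(derived) > 0L) {
    derived$finding_id <- normalize_finding(derived$raw_label, kb)
    # a derived vital finding the KB does not model stays flagged, like any
    # other unresolved label
  }

  findings <- dplyr::bind_rows(reported, derived)
  if (sum(!is.na(findings$finding_id)) == 0L) {
    abort(paste0(
      "empty case",
      if (!is.null(record$case_id)) paste0(" '", record$case_id, "'"),
      ": no reported or derived finding resolves in the knowledge base"
    ))
  }

  structure(
    list(
      case_id = as.character(record$case_id %||% NA_character_),
      demographics = demographics,
      findings = findings,
      vitals = vitals
    ),
    class = "patient_case"
  )
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case>", x$case_id, "- age", x$demographics$age,
      x$demographics$sex, "\n")
  cat("  findings:",
      paste(ifelse(is.na(x$findings$finding_id), paste0("?", x$findings$raw_label),
                   x$findings$finding_id), collapse = ", "), "\n")
  invisible(x)
}

#' Read a batch of cases from JSON or TSV
#'
#' JSON files hold a list of case records; TSV files carry one case per row
#' with columns `case_id, age, sex, findings` (semicolon-joined labels),
#' optional `duration_hours, hr, rr, sbp, temp, spo2`.
#'
#' @param path path to a `.json` or `.tsv`/`.txt` case file.
#' @param kb a `triage_kb`.
#' @param config a [triage_config()].
#' @return A list of `patient_case` objects.
#' @export
read_cases <- function(path, kb, config = triage_config()) {
  if (!file.exists(path)) abort(paste0("case file not found: ", path))
  records <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    purrr::transpose(as.list(df))
  }
  purrr::map(records, parse_case, kb = kb, config = config)
}
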