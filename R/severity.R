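#' Case-specific integer severity of one diagnosis
#'
#' A diagnosis's contribution to the triage score is the severity it would
#' justify for *this* presentation: the most severe (numerically smallest)
#' `severity_for_diagnosis` among the case findings associated with the
#' diagnosis, clamped into the diagnosis's curated severity range. When no
#' case finding matches an association of the diagnosis, the rounded
#' midpoint of the range is used.
#'
#' @inheritParams diagnosis_score
#' @return Integer severity in 1..5 (1 = most severe).
#' @export
diagnosis_case_severity <- function(kb, case, diagnosis_id) {
  if (!diagnosis_id %in% kb$diagnoses$id) {
    abort(paste0("unknown diagnosis id: ", diagnosis_id))
  }
  d <- kb$diagnoses[kb$diagnoses$id == diagnosis_id, ]
  assoc <- kb$associations[kb$associations$diagnosis_id == diagnosis_id, ]
  case_ids <- case$findings$finding_id
  matched <- assoc[assoc$finding_id %in% case_ids[!is.na(case_ids)], ]
  if (nrow(matched) > 0L) {
    s <- min(matched$severity_for_diagnosis)
    s <- min(max(s, d$severity_severe), d$severity_mild)
  } else {
    s <- round_half_away((d$severity_severe + d$severity_mild) / 2)
  }
  as.integer(s)
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Aggregate a differential into a fractional severity
#'
#' The weighted mean of per-diagnosis integer severities over the
#' differential, using the normalized differential weights; lies in
#' `[1, 5]`.
#'
#' @param differential a `triage_differential` (or data frame with
#'   `diagnosis_id` and `weight`).
#' @param severities named numeric vector or named list mapping each
#'   `diagnosis_id` in the differential to its integer severity.
#' @return Fractional severity in `[1, 5]`.
#' @examples
#' d <- tibble::tibble(diagnosis_id = c("a", "b"), weight = c(0.6, 0.4))
#' aggregate_severity(d, c(a = 2, b = 3))
#' @export
aggregate_severity <- function(differential, severities) {
  severities <- unlist(severities)
  missing <- setdiff(differential$diagnosis_id, names(severities))
  if (length(missing) > 0L) {
    abort(paste0("no severity supplied for diagnosis: ",
                 paste(missing, collapse = ", ")))
  }
  s <- severities[differential$diagnosis_id]
  if (any(!s %in% 1:5)) abort("severities must be integers in 1..5")
  sum(differential$weight * s)
}

#' Round a fractional severity to an integer triage level
#'
#' Fractional parts outside the configured mid-band round to the nearest
#' integer. Fractional parts inside the band (default `[0.40, 0.60]`, which
#' always contains .5) are ambiguous and are resolved by clinical context:
#' a recommended critical test for an urgent/emergent diagnosis in the
#' differential, or a short symptom duration, rounds *up in urgency* — to
#' the next highest triage level, i.e. the numerically smaller integer
#' (level 1 is most severe) — erring on the side of safety; otherwise the
#' score rounds down in urgency to the numerically larger integer.
#'
#' @param fractional fractional severity in `[1, 5]`.
#' @param has_critical_test does any urgent/emergent diagnosis in the
#'   differential carry a critical test recommendation?
#' @param short_duration is the (minimum known) symptom duration short?
#' @param band closed mid-band interval within (0, 1).
#' @return Integer severity in 1..5.
#' @examples
#' round_severity(3.5, has_critical_test = TRUE, short_duration = FALSE)  # 3
#' round_severity(3.5, has_critical_test = FALSE, short_duration = FALSE) # 4
#' round_severity(2.3) # 2
#' @export
round_severity <- function(fractional, has_critical_test = FALSE,
                           short_duration = FALSE, band = c(0.40, 0.60)) {
  stopifnot(fractional >= 1, fractional <= 5,
            band[1] > 0, band[2] < 1, band[1] <= band[2])
  frac <- fractional - floor(fractional)
  out <- if (frac >= band[1] && frac <= band[2]) {
    if (has_critical_test || short_duration) {
      floor(fractional)   # toward 1: more severe
    } else {
      ceiling(fractional) # toward 5: less severe
    }
  } else {
    round_half_away(fractional)
  }
  as.integer(min(max(out, 1), 5))
}

#' Triage one case end to end
#'
#' Runs the full pipeline: build the weighted differential, attach each
#' entry's case-specific integer severity, average them into the fractional
#' severity, and round via the mid-band rule. The critical-test trigger is
#' on iff some differential entry whose diagnosis can be urgent/emergent
#' (most severe attainable level numerically `<=`
#' `config$critical_severity_max`) recommends at least one critical test;
#' the short-duration trigger is on iff the minimum known finding duration
#' is below `config$short_duration_hours`.
#'
#' @param kb a `triage_kb`.
#' @param case a `patient_case`.
#' @param config a [triage_config()].
#' @return An object of class `triage_result`: list with `case_id`,
#'   `fractional_severity`, `final_severity`, `rounding_trigger` (`none`,
#'   `critical_test_or_short_duration`, or `no_critical_long_duration`),
#'   `differential` (with per-entry `severity` column), and `notes`
#'   (provenance strings, including any unresolved finding labels).
#' @seealso [triage_cases()], [tidy.triage_result()]
#' @export
triage_case <- function(kb, case, config = triage_config()) {
  differential <- build_differential(kb, case, K = config$top_k,
                                     config = config)
  severities <- purrr::map_int(differential$diagnosis_id,
                               diagnosis_case_severity, kb = kb, case = case)
  differential$severity <- severities
  fractional <- aggregate_severity(
    differential, stats::setNames(severities, differential$diagnosis_id)
  )

  dx <- kb$diagnoses[match(differential$diagnosis_id, kb$diagnoses$id), ]
  has_critical_test <- any(
    dx$severity_severe <= config$critical_severity_max &
      lengths(dx$critical_tests) > 0L
  )
  durations <- case$findings$duration_hours
  durations <- durations[!is.na(durations)]
  short_duration <- length(durations) > 0L &&
    min(durations) < config$short_duration_hours

  frac <- fractional - floor(fractional)
  in_band <- frac >= config$rounding_band[1] && frac <= config$rounding_band[2]
  trigger <- if (!in_band) {
    "none"
  } else if (has_critical_test || short_duration) {
    "critical_test_or_short_duration"
  } else {
    "no_critical_long_duration"
  }
  final <- round_severity(fractional, has_critical_test, short_duration,
                          band = config$rounding_band)

  notes <- character()
  unresolved <- case$findings$raw_label[is.na(case$findings$finding_id)]
  if (length(unresolved) > 0L) {
    notes <- c(notes, paste0("unresolved finding label(s): ",
                             paste(unresolved, collapse = ", ")))
  }
  if (in_band) {
    notes <- c(notes, paste0(
      "mid-band fraction ", format(round(frac, 3), nsmall = 3),
      "; critical test: ", has_critical_test,
      "; short duration: ", short_duration
    ))
  }

  structure(
    list(
      case_id = case$case_id,
      fractional_severity = fractional,
      final_severity = final,
      rounding_trigger = trigger,
      differential = differential,
      notes = notes
    ),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result>", x$case_id, "\n")
  cat("  fractional severity:", format(round(x$fractional_severity, 3),
                                       nsmall = 3), "\n")
  cat("  final severity:", x$final_severity,
      " (rounding trigger:", x$rounding_trigger, ")\n")
  top <- utils::head(x$differential, 3L)
  cat("  top of differential:",
      paste0(top$diagnosis_id, " (w=", format(round(top$weight, 3),
                                              nsmall = 3), ")",
             collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Triage a batch of cases into a tibble
#'
#' Convenience wrapper applying [triage_case()] to a list of cases and
#' binding the one-row summaries.
#'
#' @param cases list of `patient_case` objects (e.g. from [read_cases()] or
#'   [generate_cases()]).
#' @param kb a `triage_kb`.
#' @param config a [triage_config()].
#' @return A tibble with columns `case_id`, `fractional_severity`,
#'   `final_severity`, `rounding_trigger`.
#' @export
triage_cases <- function(cases, kb, config = triage_config()) {
  purrr::map_dfr(cases, function(case) {
    tidy(triage_case(kb, case, config = config))
  })
}
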