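#' Engine configuration
#'
#' Bundles every tunable constant of the triage engine into one list so a
#' whole run is reproducible from a single object. Values can be overridden
#' individually, or loaded from a YAML/JSON file with [read_config()].
#'
#' @details
#' The frequency-category probabilities are representative point values for
#' the curated category ranges (a category is a label such as "very common:
#' occurs in >50% of presentations"); the defaults are the arithmetic
#' midpoints of those ranges, with `key` sharing the `very_common` value —
#' a key finding's required-ness is instead expressed through
#' `key_missing_penalty`, the factor applied to a diagnosis's score for each
#' of its key findings absent from the presentation. `unmatched_finding_epsilon`
#' is the likelihood assigned to a case finding that has no curated
#' association with the diagnosis being scored.
#'
#' @param frequency_probabilities named numeric vector with entries
#'   `key`, `very_common`, `common`, `uncommon`, `rare`, each in (0, 1].
#' @param key_missing_penalty multiplicative penalty in (0, 1] for a key
#'   finding absent from the case.
#' @param unmatched_finding_epsilon likelihood in (0, 1) for a case finding
#'   not associated with the diagnosis.
#' @param top_k number of top-ranked diagnoses retained in the differential.
#' @param rounding_band closed interval within (0, 1); fractional severities
#'   whose fractional part falls inside it are rounded by the critical-test /
#'   symptom-duration rule rather than to the nearest integer.
#' @param short_duration_hours durations strictly below this count as "short"
#'   for the rounding rule (hours).
#' @param critical_severity_max a differential entry can trigger the
#'   critical-test rule only if its diagnosis's most severe attainable level
#'   is at or above this urgency (numerically `<=` this value; 1 = most severe).
#' @param vital_thresholds data frame of age-banded normal ranges, as
#'   returned by [default_vital_thresholds()].
#'
#' @return A list of class `triage_config`.
#' @examples
#' cfg <- triage_config(top_k = 10)
#' cfg$frequency_probabilities[["common"]]
#' @export
triage_config <- function(frequency_probabilities = c(
                            key = 0.75, very_common = 0.75, common = 0.30,
                            uncommon = 0.055, rare = 0.005
                          ),
                          key_missing_penalty = 0.05,
                          unmatched_finding_epsilon = 0.001,
                          top_k = 100,
                          rounding_band = c(0.40, 0.60),
                          short_duration_hours = 48,
                          critical_severity_max = 2,
                          vital_thresholds = default_vital_thresholds()) {
  freq <- frequency_probabilities
  missing_cats <- setdiff(frequency_categories(), names(freq))
  if (length(missing_cats) > 0L) {
    abort(paste0(
      "frequency_probabilities is missing categories: ",
      paste(missing_cats, collapse = ", ")
    ))
  }
  if (any(freq <= 0 | freq > 1)) {
    abort("frequency_probabilities must lie in (0, 1]")
  }
  stopifnot(
    key_missing_penalty > 0, key_missing_penalty <= 1,
    unmatched_finding_epsilon > 0, unmatched_finding_epsilon < 1,
    top_k >= 1,
    length(rounding_band) == 2L,
    rounding_band[1] > 0, rounding_band[2] < 1,
    rounding_band[1] <= rounding_band[2],
    short_duration_hours > 0,
    critical_severity_max %in% 1:5
  )
  structure(
    list(
      frequency_probabilities = freq[frequency_categories()],
      key_missing_penalty = key_missing_penalty,
      unmatched_finding_epsilon = unmatched_finding_epsilon,
      top_k = as.integer(top_k),
      rounding_band = as.numeric(rounding_band),
      short_duration_hours = as.numeric(short_duration_hours),
      critical_severity_max = as.integer(critical_severity_max),
      vital_thresholds = tibble::as_tibble(vital_thresholds)
    ),
    class = "triage_config"
  )
}

#' The closed vocabulary of finding frequency categories
#'
#' Ordered from most to least frequent; `key` means required for the
#' diagnosis and shares the `very_common` likelihood.
#'
#' @return Character vector of category names.
#' @export
frequency_categories <- function() {
  c("key", "very_common", "common", "uncommon", "rare")
}

#' Default age-banded vital-sign reference ranges
#'
#' Conventional textbook normal ranges for three coarse age bands
#' (infant < 1 y, child 1-12 y, adult 12+ y). A measured vital outside
#' `[low, high]` generates the corresponding derived finding. The table is
#' plain data so sites can replace it wholesale via [triage_config()].
#'
#' @return A tibble with columns `vital`, `age_lo`, `age_hi` (half-open band
#'   `[age_lo, age_hi)` in years), `low`, `high`, `low_finding`,
#'   `high_finding` (`NA` when no finding is defined for that tail).
#' @export
default_vital_thresholds <- function() {
  tibble::tribble(
    ~vital,             ~age_lo, ~age_hi, ~low, ~high, ~low_finding,  ~high_finding,
    "heart_rate",       0,       1,       100,  160,   "bradycardia", "tachycardia",
    "heart_rate",       1,       12,      70,   120,   "bradycardia", "tachycardia",
    "heart_rate",       12,      Inf,     60,   100,   "bradycardia", "tachycardia",
    "respiratory_rate", 0,       1,       30,   60,    "bradypnea",   "tachypnea",
    "respiratory_rate", 1,       12,      20,   30,    "bradypnea",   "tachypnea",
    "respiratory_rate", 12,      Inf,     12,   20,    "bradypnea",   "tachypnea",
    "systolic_bp",      0,       1,       70,   100,   "hypotension", "hypertension",
    "systolic_bp",      1,       12,      80,   110,   "hypotension", "hypertension",
    "systolic_bp",      12,      Inf,     90,   140,   "hypotension", "hypertension",
    "temperature",      0,       Inf,     36,   38,    "hypothermia", "fever",
    "spo2",             0,       Inf,     92,   100,   "hypoxia",     NA_character_
  )
}

#' Read an engine configuration from a YAML or JSON file
#'
#' Keys present in the file override the corresponding [triage_config()]
#' defaults; unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `triage_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(triage_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$frequency_probabilities)) {
    raw$frequency_probabilities <- unlist(raw$frequency_probabilities)
  }
  if (!is.null(raw$vital_thresholds)) {
    raw$vital_thresholds <- tibble::as_tibble(as.data.frame(raw$vital_thresholds))
  }
  do.call(triage_config, raw)
}

#' @export
print.triage_config <- function(x, ...) {
  cat("<triage_config>\n")
  cat("  frequency_probabilities:",
      paste(names(x$frequency_probabilities),
            format(x$frequency_probabilities, trim = TRUE),
            sep = "=", collapse = ", "), "\n")
  cat("  key_missing_penalty:", x$key_missing_penalty,
      " unmatched_finding_epsilon:", x$unmatched_finding_epsilon, "\n")
  cat("  top_k:", x$top_k,
      " rounding_band: [", x$rounding_band[1], ",", x$rounding_band[2], "]",
      " short_duration_hours:", x$short_duration_hours, "\n")
  cat("  vital_thresholds:", nrow(x$vital_thresholds), "rows\n")
  invisible(x)
}
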