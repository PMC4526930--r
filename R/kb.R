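#' Construct a triage knowledge base
#'
#' A knowledge base (KB) is the curated graph the engine walks: findings
#' (signs, symptoms, vital-sign derangements), diagnoses, and the
#' diagnosis-finding associations that connect them, each association
#' carrying a frequency category, the severity the finding implies for that
#' diagnosis, and optional demographic multipliers on its likelihood.
#' Severity is ordinal 1-5 throughout, 1 being the most severe
#' ("revive/unstable") and 5 the least ("referred").
#'
#' @param findings data frame with columns `id`, `label`, `synonyms`
#'   (list column of character vectors), `severity_severe`, `severity_mild`
#'   (the intrinsic severity range, severe end first, `severe <= mild`).
#' @param diagnoses data frame with columns `id`, `label`,
#'   `baseline_prevalence` (in (0, 1]), `severity_severe`, `severity_mild`,
#'   `critical_tests` (list column of character vectors, possibly empty).
#' @param associations data frame with columns `diagnosis_id`, `finding_id`,
#'   `frequency_category`, `severity_for_diagnosis`, `demographic_modifiers`
#'   (list column of data frames with `age_lo`, `age_hi`, `sex`,
#'   `multiplier`; the age band is half-open `[age_lo, age_hi)` in years).
#' @param version free-form version string recorded with the KB.
#' @param validate validate invariants and error on any violation
#'   (default `TRUE`).
#'
#' @return An object of class `triage_kb`.
#' @seealso [load_kb()], [save_kb()], [validate_kb()], [generate_kb()]
#' @examples
#' kb <- triage_kb(
#'   findings = tibble::tibble(
#'     id = "chest_pain", label = "chest pain", synonyms = list("cp"),
#'     severity_severe = 1, severity_mild = 3
#'   ),
#'   diagnoses = tibble::tibble(
#'     id = "mi", label = "myocardial infarction", baseline_prevalence = 0.01,
#'     severity_severe = 1, severity_mild = 2, critical_tests = list("ecg")
#'   ),
#'   associations = tibble::tibble(
#'     diagnosis_id = "mi", finding_id = "chest_pain",
#'     frequency_category = "very_common", severity_for_diagnosis = 1,
#'     demographic_modifiers = list(NULL)
#'   )
#' )
#' kb
#' @export
triage_kb <- function(findings, diagnoses, associations, version = "1",
                      validate = TRUE) {
  findings <- tibble::as_tibble(findings)
  diagnoses <- tibble::as_tibble(diagnoses)
  associations <- tibble::as_tibble(associations)

  if (!"synonyms" %in% names(findings)) {
    findings$synonyms <- rep(list(character()), nrow(findings))
  }
  if (!"critical_tests" %in% names(diagnoses)) {
    diagnoses$critical_tests <- rep(list(character()), nrow(diagnoses))
  }
  if (!"demographic_modifiers" %in% names(associations)) {
    associations$demographic_modifiers <-
      rep(list(empty_modifiers()), nrow(associations))
  }

  findings <- dplyr::mutate(
    findings,
    id = as.character(.data$id),
    label = as.character(.data$label),
    synonyms = purrr::map(.data$synonyms, ~ as.character(.x %||% character())),
    severity_severe = as.integer(.data$severity_severe),
    severity_mild = as.integer(.data$severity_mild)
  )
  diagnoses <- dplyr::mutate(
    diagnoses,
    id = as.character(.data$id),
    label = as.character(.data$label),
    baseline_prevalence = as.numeric(.data$baseline_prevalence),
    severity_severe = as.integer(.data$severity_severe),
    severity_mild = as.integer(.data$severity_mild),
    critical_tests = purrr::map(.data$critical_tests,
                                ~ as.character(.x %||% character()))
  )
  associations <- dplyr::mutate(
    associations,
    diagnosis_id = as.character(.data$diagnosis_id),
    finding_id = as.character(.data$finding_id),
    frequency_category = as.character(.data$frequency_category),
    severity_for_diagnosis = as.integer(.data$severity_for_diagnosis),
    demographic_modifiers = purrr::map(.data$demographic_modifiers,
                                       as_modifiers)
  )

  kb <- structure(
    list(
      version = as.character(version),
      findings = findings,
      diagnoses = diagnoses,
      associations = associations
    ),
    class = "triage_kb"
  )
  if (validate) {
    v <- validate_kb(kb)
    if (nrow(v) > 0L) {
      abort(c("invalid knowledge base:",
              stats::setNames(v$message, rep("x", nrow(v)))))
    }
  }
  kb
}

empty_modifiers <- function() {
  tibble::tibble(
    age_lo = numeric(), age_hi = numeric(),
    sex = character(), multiplier = numeric()
  )
}

as_modifiers <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(empty_modifiers())
  }
  x <- tibble::as_tibble(x)
  tibble::tibble(
    age_lo = as.numeric(x$age_lo),
    age_hi = as.numeric(x$age_hi),
    sex = as.character(x$sex),
    multiplier = as.numeric(x$multiplier)
  )
}

#' @export
print.triage_kb <- function(x, ...) {
  cat("<triage_kb> version", x$version, "\n")
  cat("  ", nrow(x$diagnoses), "diagnoses, ", nrow(x$findings), "findings, ",
      nrow(x$associations), "associations\n")
  invisible(x)
}

# Canonical label form used for finding lookup: lower case, punctuation and
# repeated whitespace collapsed.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

# Named character vector: normalized label/synonym -> finding id.
finding_lookup <- function(kb) {
  labs <- c(
    stats::setNames(kb$findings$id, normalize_label(kb$findings$label)),
    unlist(purrr::map2(
      kb$findings$synonyms, kb$findings$id,
      function(syn, id) {
        if (length(syn) == 0L) return(character())
        stats::setNames(rep(id, length(syn)), normalize_label(syn))
      }
    ))
  )
  labs[!duplicated(names(labs))]
}

#' Validate a knowledge base
#'
#' Checks every structural invariant — unique ids, ordered severity ranges,
#' prevalence bounds, the closed frequency vocabulary, referential integrity
#' of association endpoints, non-overlapping demographic age bands,
#' unambiguous synonym resolution, and that every diagnosis has at least one
#' association. Validation never throws; it reports.
#'
#' @param kb a `triage_kb`.
#' @return A tibble with columns `record`, `rule`, `message`; zero rows iff
#'   the KB satisfies all invariants.
#' @export
validate_kb <- function(kb) {
  v <- list()
  add <- function(record, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      record = record, rule = rule, message = message
    )
  }

  f <- kb$findings
  d <- kb$diagnoses
  a <- kb$associations

  for (id in unique(f$id[duplicated(f$id)])) {
    add(id, "unique_id", paste0("finding id '", id, "' is duplicated"))
  }
  for (id in unique(d$id[duplicated(d$id)])) {
    add(id, "unique_id", paste0("diagnosis id '", id, "' is duplicated"))
  }

  bad_range <- function(lo, hi) {
    is.na(lo) | is.na(hi) | lo < 1L | hi > 5L | lo > hi
  }
  for (i in which(bad_range(f$severity_severe, f$severity_mild))) {
    add(f$id[i], "severity_range_order",
        paste0("finding '", f$id[i], "' severity range (",
               f$severity_severe[i], ",", f$severity_mild[i],
               ") violates 1 <= severe <= mild <= 5"))
  }
  for (i in which(bad_range(d$severity_severe, d$severity_mild))) {
    add(d$id[i], "severity_range_order",
        paste0("diagnosis '", d$id[i], "' severity range (",
               d$severity_severe[i], ",", d$severity_mild[i],
               ") violates 1 <= severe <= mild <= 5"))
  }
  for (i in which(is.na(d$baseline_prevalence) |
                  d$baseline_prevalence <= 0 | d$baseline_prevalence > 1)) {
    add(d$id[i], "prevalence_bounds",
        paste0("diagnosis '", d$id[i], "' baseline_prevalence ",
               d$baseline_prevalence[i], " outside (0,1]"))
  }

  # synonym/label ambiguity: one normalized label must map to exactly one id
  all_labels <- tibble::tibble(
    key = c(normalize_label(f$label),
            normalize_label(unlist(f$synonyms, use.names = FALSE))),
    id = c(f$id, rep(f$id, lengths(f$synonyms)))
  )
  amb <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(all_labels, .data$key),
                     n_ids = dplyr::n_distinct(.data$id), .groups = "drop"),
    .data$n_ids > 1L
  )
  for (k in amb$key) {
    add(k, "ambiguous_synonym",
        paste0("label '", k, "' resolves to multiple finding ids"))
  }

  if (nrow(a) > 0L) {
    pair <- paste(a$diagnosis_id, a$finding_id, sep = "\r")
    for (i in which(duplicated(pair))) {
      add(paste0(a$diagnosis_id[i], "/", a$finding_id[i]), "unique_association",
          paste0("association (", a$diagnosis_id[i], ", ", a$finding_id[i],
                 ") is duplicated"))
    }
    for (i in which(!a$diagnosis_id %in% d$id)) {
      add(a$diagnosis_id[i], "dangling_reference",
          paste0("association references unknown diagnosis id '",
                 a$diagnosis_id[i], "'"))
    }
    for (i in which(!a$finding_id %in% f$id)) {
      add(a$finding_id[i], "dangling_reference",
          paste0("association references unknown finding id '",
                 a$finding_id[i], "'"))
    }
    for (i in which(!a$frequency_category %in% frequency_categories())) {
      add(paste0(a$diagnosis_id[i], "/", a$finding_id[i]), "frequency_vocabulary",
          paste0("frequency_category '", a$frequency_category[i],
                 "' not in {", paste(frequency_categories(), collapse = ", "), "}"))
    }
    for (i in which(is.na(a$severity_for_diagnosis) |
                    !a$severity_for_diagnosis %in% 1:5)) {
      add(paste0(a$diagnosis_id[i], "/", a$finding_id[i]), "severity_ordinal",
          "severity_for_diagnosis must be an integer in 1..5")
    }
    for (i in seq_len(nrow(a))) {
      m <- a$demographic_modifiers[[i]]
      if (nrow(m) == 0L) next
      rec <- paste0(a$diagnosis_id[i], "/", a$finding_id[i])
      if (any(m$multiplier <= 0 | is.na(m$multiplier))) {
        add(rec, "modifier_multiplier", paste0(
          "association ", rec, " has a non-positive demographic multiplier"))
      }
      if (any(m$age_lo >= m$age_hi, na.rm = TRUE)) {
        add(rec, "modifier_age_band", paste0(
          "association ", rec, " has an empty age band (lo >= hi)"))
      }
      # overlap check within each sex stratum (any overlaps both)
      for (s in unique(m$sex)) {
        ms <- m[m$sex == s | m$sex == "any" | s == "any", , drop = FALSE]
        ms <- ms[order(ms$age_lo), , drop = FALSE]
        if (nrow(ms) > 1L &&
            any(ms$age_lo[-1L] < ms$age_hi[-nrow(ms)], na.rm = TRUE)) {
          add(rec, "modifier_age_overlap", paste0(
            "association ", rec, " has overlapping age bands"))
          break
        }
      }
      if (any(!m$sex %in% c("female", "male", "any"))) {
        add(rec, "modifier_sex_vocabulary", paste0(
          "association ", rec, " has a sex outside {female, male, any}"))
      }
    }
  }

  orphans <- setdiff(d$id, a$diagnosis_id)
  for (id in orphans) {
    add(id, "diagnosis_has_association",
        paste0("diagnosis '", id, "' has no associations"))
  }

  if (length(v) == 0L) {
    tibble::tibble(record = character(), rule = character(),
                   message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Map a frequency category to a representative likelihood
#'
#' Each curated category names a range of presentation frequencies; scoring
#' needs a point value, by default the arithmetic midpoint of the range.
#' `key` (required for diagnosis) shares the `very_common` likelihood: its
#' required-ness is enforced separately through the key-missing penalty in
#' [diagnosis_score()].
#'
#' @param category character vector of categories (see
#'   [frequency_categories()]).
#' @param config a [triage_config()]; supplies the category-to-probability
#'   table.
#' @return Numeric vector of probabilities in (0, 1].
#' @examples
#' frequency_to_probability(c("very_common", "rare"))
#' @export
frequency_to_probability <- function(category, config = triage_config()) {
  bad <- setdiff(unique(category), frequency_categories())
  if (length(bad) > 0L) {
    abort(paste0("unknown frequency category: ", paste(bad, collapse = ", ")))
  }
  unname(config$frequency_probabilities[category])
}

#' Combined demographic multiplier for one association
#'
#' Association likelihoods are modulated by banded demographic multipliers:
#' a modifier applies when the patient's age falls in its half-open band
#' `[age_lo, age_hi)` and its sex matches (or is `any`). The result is the
#' product over all matching modifiers, 1 when none match. Callers clamp the
#' modified likelihood to at most 1.
#'
#' @param modifiers data frame of modifiers (`age_lo`, `age_hi`, `sex`,
#'   `multiplier`), or `NULL`.
#' @param age patient age in years (fractional allowed).
#' @param sex `"female"`, `"male"`, or `"unknown"` (matches only `any`
#'   modifiers).
#' @return A positive scalar factor.
#' @examples
#' u_shaped <- tibble::tibble(
#'   age_lo = c(0, 18, 65), age_hi = c(3, 41, 120),
#'   sex = "any", multiplier = c(2, 0.5, 2)
#' )
#' demographic_multiplier(u_shaped, age = 30, sex = "male")
#' @export
demographic_multiplier <- function(modifiers, age, sex = "unknown") {
  if (age < 0) abort("age must be non-negative")
  m <- as_modifiers(modifiers)
  if (nrow(m) == 0L) return(1)
  hit <- age >= m$age_lo & age < m$age_hi &
    (m$sex == "any" | m$sex == sex)
  if (!any(hit)) return(1)
  prod(m$multiplier[hit])
}

#' Read a knowledge base from JSON
#'
#' The on-disk form is a single JSON object with keys `version`, `findings`,
#' `diagnoses`, `associations`; severity ranges are two-element arrays
#' (severe end first) and demographic modifiers carry `age_band` arrays.
#' The loaded KB is fully validated; any invariant violation (including a
#' dangling association endpoint) is an error naming the offending records.
#'
#' @param path path to a KB JSON file.
#' @param strict reject unknown keys (default); otherwise warn and ignore.
#' @return A `triage_kb`.
#' @seealso [save_kb()]
#' @export
load_kb <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("KB file not found: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)

  check_keys <- function(obj, allowed, where) {
    unknown <- setdiff(names(obj), allowed)
    if (length(unknown) > 0L) {
      msg <- paste0("unknown key(s) in ", where, ": ",
                    paste(unknown, collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
  }
  check_keys(doc, c("version", "findings", "diagnoses", "associations"), "KB")
  need <- function(rec, field, where) {
    if (is.null(rec[[field]])) {
      abort(paste0("record in ", where, " is missing required field '",
                   field, "'",
                   if (!is.null(rec$id)) paste0(" (id '", rec$id, "')")))
    }
    rec[[field]]
  }

  findings <- purrr::map_dfr(doc$findings, function(rec) {
    check_keys(rec, c("id", "label", "synonyms", "intrinsic_severity_range"),
               "findings")
    rng <- need(rec, "intrinsic_severity_range", "findings")
    tibble::tibble(
      id = need(rec, "id", "findings"),
      label = need(rec, "label", "findings"),
      synonyms = list(as.character(unlist(rec$synonyms))),
      severity_severe = rng[[1]],
      severity_mild = rng[[2]]
    )
  })
  diagnoses <- purrr::map_dfr(doc$diagnoses, function(rec) {
    check_keys(rec, c("id", "label", "baseline_prevalence", "severity_range",
                      "critical_tests"), "diagnoses")
    rng <- need(rec, "severity_range", "diagnoses")
    tibble::tibble(
      id = need(rec, "id", "diagnoses"),
      label = need(rec, "label", "diagnoses"),
      baseline_prevalence = need(rec, "baseline_prevalence", "diagnoses"),
      severity_severe = rng[[1]],
      severity_mild = rng[[2]],
      critical_tests = list(as.character(unlist(rec$critical_tests)))
    )
  })
  associations <- purrr::map_dfr(doc$associations, function(rec) {
    check_keys(rec, c("diagnosis_id", "finding_id", "frequency_category",
                      "severity_for_diagnosis", "demographic_modifiers"),
               "associations")
    mods <- purrr::map_dfr(rec$demographic_modifiers, function(m) {
      check_keys(m, c("age_band", "sex", "multiplier"),
                 "demographic_modifiers")
      tibble::tibble(
        age_lo = m$age_band[[1]], age_hi = m$age_band[[2]],
        sex = m$sex %||% "any", multiplier = m$multiplier
      )
    })
    tibble::tibble(
      diagnosis_id = need(rec, "diagnosis_id", "associations"),
      finding_id = need(rec, "finding_id", "associations"),
      frequency_category = need(rec, "frequency_category", "associations"),
      severity_for_diagnosis = need(rec, "severity_for_diagnosis",
                                    "associations"),
      demographic_modifiers = list(mods)
    )
  })

  kb <- triage_kb(findings, diagnoses, associations,
                  version = doc$version %||% "1", validate = FALSE)
  v <- validate_kb(kb)
  if (nrow(v) > 0L) {
    abort(c(paste0("KB at '", path, "' failed validation:"),
            stats::setNames(v$message, rep("x", nrow(v)))))
  }
  kb
}

#' Write a knowledge base to JSON
#'
#' Inverse of [load_kb()]: `load_kb(save_kb(kb, path))` returns a KB equal
#' to `kb`.
#'
#' @param kb a `triage_kb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path) {
  doc <- list(
    version = kb$version,
    findings = purrr::pmap(kb$findings, function(id, label, synonyms,
                                                 severity_severe,
                                                 severity_mild) {
      list(id = id, label = label, synonyms = as.list(synonyms),
           intrinsic_severity_range = c(severity_severe, severity_mild))
    }),
    diagnoses = purrr::pmap(kb$diagnoses, function(id, label,
                                                   baseline_prevalence,
                                                   severity_severe,
                                                   severity_mild,
                                                   critical_tests) {
      list(id = id, label = label, baseline_prevalence = baseline_prevalence,
           severity_range = c(severity_severe, severity_mild),
           critical_tests = as.list(critical_tests))
    }),
    associations = purrr::pmap(kb$associations, function(diagnosis_id,
                                                         finding_id,
                                                         frequency_category,
                                                         severity_for_diagnosis,
                                                         demographic_modifiers) {
      list(
        diagnosis_id = diagnosis_id, finding_id = finding_id,
        frequency_category = frequency_category,
        severity_for_diagnosis = severity_for_diagnosis,
        demographic_modifiers = purrr::pmap(
          demographic_modifiers,
          function(age_lo, age_hi, sex, multiplier) {
            list(age_band = c(age_lo, age_hi), sex = sex,
                 multiplier = multiplier)
          }
        )
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
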