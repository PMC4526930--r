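# Shared fixtures and independent oracles. The oracles deliberately use
# straight-line double loops so they stay independent of the vectorized
# production code they check.

make_case <- function(finding_ids, age = 30, sex = "male",
                      durations = NA_real_, case_id = "t1",
                      raw_labels = finding_ids) {
  structure(
    list(
      case_id = case_id,
      demographics = list(age = age, sex = sex),
      findings = tibble::tibble(
        finding_id = finding_ids,
        raw_label = raw_labels,
        duration_hours = rep_len(durations, length(finding_ids)),
        reported_severity = NA_integer_,
        source = "reported"
      ),
      vitals = list()
    ),
    class = "patient_case"
  )
}

# Three-diagnosis KB small enough that every score is hand-computable.
tiny_kb <- function() {
  triage_kb(
    findings = tibble::tibble(
      id = c("cough", "fever", "rash"),
      label = c("severe cough", "fever", "rash"),
      synonyms = list("bad cough", character(), character()),
      severity_severe = c(2L, 2L, 3L),
      severity_mild = c(4L, 4L, 5L)
    ),
    diagnoses = tibble::tibble(
      id = c("asthma", "flu", "derm"),
      label = c("asthma", "influenza", "dermatitis"),
      baseline_prevalence = c(0.02, 0.05, 0.01),
      severity_severe = c(2L, 2L, 4L),
      severity_mild = c(3L, 4L, 5L),
      critical_tests = list("peak flow", character(), character())
    ),
    associations = tibble::tibble(
      diagnosis_id = c("asthma", "flu", "flu", "derm"),
      finding_id = c("cough", "cough", "fever", "rash"),
      frequency_category = c("very_common", "common", "key", "very_common"),
      severity_for_diagnosis = c(2L, 3L, 3L, 4L),
      demographic_modifiers = list(NULL, NULL, NULL, NULL)
    )
  )
}

# Literal reimplementation of the prevalence-times-likelihood product.
oracle_score <- function(kb, case, diagnosis_id, config = triage_config()) {
  d <- kb$diagnoses[kb$diagnoses$id == diagnosis_id, ]
  assoc <- kb$associations[kb$associations$diagnosis_id == diagnosis_id, ]
  score <- d$baseline_prevalence
  present <- case$findings$finding_id
  for (i in seq_along(present)) {
    fid <- present[i]
    row <- which(assoc$finding_id == fid)
    if (!is.na(fid) && length(row) == 1L) {
      p <- unname(config$frequency_probabilities[[assoc$frequency_category[row]]])
      m <- 1
      mods <- assoc$demographic_modifiers[[row]]
      if (!is.null(mods) && nrow(mods) > 0L) {
        for (j in seq_len(nrow(mods))) {
          if (case$demographics$age >= mods$age_lo[j] &&
              case$demographics$age < mods$age_hi[j] &&
              (mods$sex[j] == "any" ||
                 mods$sex[j] == case$demographics$sex)) {
            m <- m * mods$multiplier[j]
          }
        }
      }
      score <- score * min(1, p * m)
    } else {
      score <- score * config$unmatched_finding_epsilon
    }
  }
  for (i in seq_len(nrow(assoc))) {
    if (assoc$frequency_category[i] == "key" &&
        !assoc$finding_id[i] %in% present[!is.na(present)]) {
      score <- score * config$key_missing_penalty
    }
  }
  score
}

# Literal double-loop weighted kappa.
oracle_kappa <- function(m, scheme) {
  m <- unclass(m)
  k <- nrow(m)
  n <- sum(m)
  r <- rowSums(m)
  cl <- colSums(m)
  po <- 0
  pe <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      w <- switch(scheme,
        linear = 1 - abs(i - j) / (k - 1),
        quadratic = 1 - (abs(i - j) / (k - 1))^2,
        unweighted = as.numeric(i == j)
      )
      po <- po + w * m[i, j] / n
      pe <- pe + w * r[i] * cl[j] / n^2
    }
  }
  (po - pe) / (1 - pe)
}

random_confusion <- function(k = 5) {
  m <- matrix(rpois(k * k, lambda = 3), nrow = k)
  if (sum(m) == 0) m[1, 2] <- 1
  m
}

# Random small KB with demographic modifiers injected into some
# associations (the generator leaves them empty by default).
random_kb_with_modifiers <- function(seed) {
  set.seed(seed)
  kb <- generate_kb(
    n_diagnoses = sample(2:10, 1), n_findings = sample(8:15, 1),
    assoc_per_diagnosis = sample(2:5, 1), seed = seed
  )
  bands <- list(c(0, 18), c(18, 65), c(65, 120))
  kb$associations$demographic_modifiers <- purrr::map(
    seq_len(nrow(kb$associations)),
    function(i) {
      if (runif(1) < 0.4) {
        picks <- sample(3, sample(1:2, 1))
        tibble::tibble(
          age_lo = purrr::map_dbl(bands[picks], 1),
          age_hi = purrr::map_dbl(bands[picks], 2),
          sex = sample(c("any", "female", "male"), length(picks),
                       replace = TRUE),
          multiplier = runif(length(picks), 0.2, 3)
        )
      } else {
        NULL
      }
    }
  )
  triage_kb(kb$findings, kb$diagnoses, kb$associations)
}

random_case_for <- function(kb) {
  n <- sample(1:4, 1)
  ids <- sample(kb$findings$id, n)
  make_case(ids, age = runif(1, 0, 90),
            sex = sample(c("female", "male"), 1))
}
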