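#' Generate a synthetic knowledge base
#'
#' Emulates the statistical structure of a physician-curated KB so the whole
#' engine can be exercised without any proprietary content: baseline
#' prevalences are drawn log-uniformly (diagnosis frequency spans orders of
#' magnitude), each diagnosis gets a severity range centred on a draw from
#' `severity_mix` (the centre +/- 1, clipped to 1..5), its associations get
#' frequency categories from `category_probs`, per-association severities
#' within the diagnosis range, and urgent/emergent diagnoses (severe end
#' `<= 2`) carry a critical-test recommendation with probability `p_crit`.
#' Deterministic given `seed`.
#'
#' @param n_diagnoses number of diagnoses (>= 1).
#' @param n_findings number of findings (>= `assoc_per_diagnosis`).
#' @param assoc_per_diagnosis associations per diagnosis.
#' @param severity_mix probability vector over severities 1..5 for the
#'   range centre (default uniform).
#' @param seed integer seed.
#' @param category_probs named probability vector over
#'   [frequency_categories()]; the default exercises every category while
#'   keeping `key` findings rare, as in curated content.
#' @param p_crit probability that an urgent/emergent diagnosis lists a
#'   critical test.
#' @param prevalence_range range for the log-uniform baseline prevalence.
#' @return A validated `triage_kb`.
#' @seealso [generate_cases()]
#' @examples
#' kb <- generate_kb(5, 12, 3, seed = 1)
#' nrow(validate_kb(kb))  # 0
#' @export
generate_kb <- function(n_diagnoses, n_findings, assoc_per_diagnosis,
                        severity_mix = rep(0.2, 5), seed = 1L,
                        category_probs = c(key = 0.02, very_common = 0.2,
                                           common = 0.4, uncommon = 0.3,
                                           rare = 0.08),
                        p_crit = 0.5,
                        prevalence_range = c(1e-4, 1e-1)) {
  stopifnot(n_diagnoses >= 1, n_findings >= assoc_per_diagnosis,
            assoc_per_diagnosis >= 1,
            length(severity_mix) == 5, all(severity_mix >= 0),
            sum(severity_mix) > 0)
  if (!setequal(names(category_probs), frequency_categories())) {
    abort("category_probs must be named over the frequency vocabulary")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pad <- function(prefix, i, n) {
    sprintf("%s%0*d", prefix, nchar(as.character(n)), i)
  }

  f_centre <- sample(1:5, n_findings, replace = TRUE,
                     prob = severity_mix / sum(severity_mix))
  findings <- tibble::tibble(
    id = pad("f", seq_len(n_findings), n_findings),
    label = paste("finding", pad("", seq_len(n_findings), n_findings)),
    synonyms = purrr::map(seq_len(n_findings),
                          ~ paste0("syn ", pad("", .x, n_findings))),
    severity_severe = pmax(1L, f_centre - 1L),
    severity_mild = pmin(5L, f_centre + 1L)
  )

  d_centre <- sample(1:5, n_diagnoses, replace = TRUE,
                     prob = severity_mix / sum(severity_mix))
  lo <- pmax(1L, d_centre - 1L)
  hi <- pmin(5L, d_centre + 1L)
  prevalence <- exp(runif(n_diagnoses, log(prevalence_range[1]),
                          log(prevalence_range[2])))
  diagnoses <- tibble::tibble(
    id = pad("d", seq_len(n_diagnoses), n_diagnoses),
    label = paste("diagnosis", pad("", seq_len(n_diagnoses), n_diagnoses)),
    baseline_prevalence = prevalence,
    severity_severe = lo,
    severity_mild = hi,
    critical_tests = purrr::map(seq_len(n_diagnoses), function(i) {
      if (lo[i] <= 2L && runif(1) < p_crit) {
        paste0("critical_test_", pad("", i, n_diagnoses))
      } else {
        character()
      }
    })
  )

  associations <- purrr::map_dfr(seq_len(n_diagnoses), function(i) {
    fids <- sample(findings$id, assoc_per_diagnosis)
    tibble::tibble(
      diagnosis_id = diagnoses$id[i],
      finding_id = fids,
      frequency_category = sample(names(category_probs),
                                  assoc_per_diagnosis, replace = TRUE,
                                  prob = category_probs),
      severity_for_diagnosis = lo[i] +
        sample.int(hi[i] - lo[i] + 1L, assoc_per_diagnosis,
                   replace = TRUE) - 1L,
      demographic_modifiers = rep(list(empty_modifiers()),
                                  assoc_per_diagnosis)
    )
  })

  triage_kb(findings, diagnoses, associations,
            version = paste0("synthetic-seed-", seed))
}

#' Simulate patient cases from a knowledge base
#'
#' Each case is drawn from the generative model the engine assumes: a true
#' diagnosis is sampled proportionally to baseline prevalence; each of its
#' associated findings is included independently with its category
#' probability times the demographic multiplier (clamped to 1); spurious
#' unassociated findings are added independently at `extra_finding_rate`;
#' included findings are then dropped at `dropout_rate`; cases that end up
#' empty are resampled so every case has at least one finding. The paired
#' ground truth records the generating diagnosis and its case severity
#' (via [diagnosis_case_severity()]). Deterministic given `seed`.
#'
#' @param kb a `triage_kb`.
#' @param n_cases number of cases.
#' @param noise list with `extra_finding_rate` and `dropout_rate`
#'   (default both 0).
#' @param demographics_model function(n) returning a data frame with `age`,
#'   `sex`; the default draws age uniformly on 0-90 years and sex
#'   female/male with equal probability.
#' @param seed integer seed.
#' @param config a [triage_config()] (category probabilities shared with
#'   the engine).
#' @return A list with `cases` (list of `patient_case`) and `truth`
#'   (tibble `case_id`, `true_diagnosis_id`, `true_severity`).
#' @examples
#' kb <- generate_kb(3, 8, 3, seed = 1)
#' sim <- generate_cases(kb, 5, seed = 2)
#' sim$truth
#' @export
generate_cases <- function(kb, n_cases,
                           noise = list(extra_finding_rate = 0,
                                        dropout_rate = 0),
                           demographics_model = NULL, seed = 1L,
                           config = triage_config()) {
  stopifnot(n_cases >= 1)
  extra <- noise$extra_finding_rate %||% 0
  dropout <- noise$dropout_rate %||% 0
  stopifnot(extra >= 0, extra < 1, dropout >= 0, dropout < 1)
  if (is.null(demographics_model)) {
    demographics_model <- function(n) {
      tibble::tibble(
        age = runif(n, 0, 90),
        sex = sample(c("female", "male"), n, replace = TRUE)
      )
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  demo <- demographics_model(n_cases)
  prev <- kb$diagnoses$baseline_prevalence
  true_ids <- sample(kb$diagnoses$id, n_cases, replace = TRUE,
                     prob = prev / sum(prev))

  all_findings <- kb$findings$id
  cases <- vector("list", n_cases)
  truth <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    did <- true_ids[i]
    assoc <- kb$associations[kb$associations$diagnosis_id == did, ]
    age <- demo$age[i]
    sex <- demo$sex[i]
    repeat {
      p_inc <- pmin(1, frequency_to_probability(assoc$frequency_category,
                                                config) *
                      purrr::map_dbl(assoc$demographic_modifiers,
                                     demographic_multiplier,
                                     age = age, sex = sex))
      present <- assoc$finding_id[runif(nrow(assoc)) < p_inc]
      spurious <- setdiff(all_findings, assoc$finding_id)
      present <- c(present, spurious[runif(length(spurious)) < extra])
      present <- present[runif(length(present)) >= dropout]
      if (length(present) > 0L) break
    }
    case_id <- sprintf("sim_%0*d", nchar(as.character(n_cases)), i)
    case <- structure(
      list(
        case_id = case_id,
        demographics = list(age = age, sex = sex),
        findings = tibble::tibble(
          finding_id = present,
          raw_label = kb$findings$label[match(present, kb$findings$id)],
          duration_hours = NA_real_,
          reported_severity = NA_integer_,
          source = "reported"
        ),
        vitals = list()
      ),
      class = "patient_case"
    )
    cases[[i]] <- case
    truth[[i]] <- tibble::tibble(
      case_id = case_id,
      true_diagnosis_id = did,
      true_severity = diagnosis_case_severity(kb, case, did)
    )
  }
  list(cases = cases, truth = dplyr::bind_rows(truth))
}

#' The published 5x5 validation confusion matrix
#'
#' The cross-tabulation of engine severity (rows) against the five-level
#' reference standard (columns) from the published 73-vignette validation
#' study; shipped so the evaluation harness can be exercised and checked
#' against the printed statistics without the original vignettes.
#'
#' @return A `confusion_matrix` with `n = 73`.
#' @examples
#' m <- table5_fixture()
#' sum(diag(unclass(m)))  # 69 exact matches
#' @export
table5_fixture <- function() {
  m <- matrix(
    c(13, 1, 0, 0, 0,
      0, 26, 0, 0, 0,
      0, 0, 20, 0, 1,
      0, 1, 1, 4, 0,
      0, 0, 0, 0, 6),
    nrow = 5, byrow = TRUE
  )
  as_confusion(m)
}
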