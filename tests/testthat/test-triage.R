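test_that("diagnosis_case_severity takes the most severe matched finding, clamped", {
  kb <- triage_kb(
    findings = tibble::tibble(
      id = c("a", "b", "c"), label = c("a", "b", "c"),
      synonyms = list(character(), character(), character()),
      severity_severe = 1, severity_mild = 5
    ),
    diagnoses = tibble::tibble(
      id = c("d1", "d2"), label = c("d1", "d2"),
      baseline_prevalence = 0.01,
      severity_severe = c(2L, 3L), severity_mild = c(4L, 5L),
      critical_tests = list(character(), character())
    ),
    associations = tibble::tibble(
      diagnosis_id = c("d1", "d1", "d2"),
      finding_id = c("a", "b", "c"),
      frequency_category = "common",
      severity_for_diagnosis = c(3L, 4L, 1L),
      demographic_modifiers = list(NULL, NULL, NULL)
    )
  )
  # min of matched severities {3,4} within range (2,4)
  expect_equal(diagnosis_case_severity(kb, make_case(c("a", "b")), "d1"), 3L)
  # matched severity 1 clamps to the severe end of (3,5)
  expect_equal(diagnosis_case_severity(kb, make_case("c"), "d2"), 3L)
  # no matched finding: rounded midpoint of (3,5)
  expect_equal(diagnosis_case_severity(kb, make_case("a"), "d2"), 4L)
  expect_error(diagnosis_case_severity(kb, make_case("a"), "zzz"),
               "unknown diagnosis")
})

test_that("aggregate_severity is the weighted mean of integer severities", {
  d <- tibble::tibble(diagnosis_id = c("x", "y"), weight = c(0.6, 0.4))
  expect_equal(aggregate_severity(d, c(x = 2, y = 3)), 2.4)
  expect_equal(aggregate_severity(
    tibble::tibble(diagnosis_id = "x", weight = 1), c(x = 5)), 5)
  u <- tibble::tibble(diagnosis_id = letters[1:5], weight = rep(0.2, 5))
  expect_equal(aggregate_severity(u, stats::setNames(1:5, letters[1:5])), 3)
  expect_error(aggregate_severity(d, c(x = 2)), "no severity supplied")
})

test_that("the mid-band rounding rule follows clinical context", {
  # in-band: critical test or short duration rounds toward severity 1
  expect_equal(round_severity(3.5, has_critical_test = TRUE), 3L)
  expect_equal(round_severity(3.5, short_duration = TRUE), 3L)
  expect_equal(round_severity(3.5), 4L)
  # band endpoints are inclusive
  expect_equal(round_severity(2.40, has_critical_test = TRUE), 2L)
  expect_equal(round_severity(2.60), 3L)
  # outside the band: plain nearest integer
  expect_equal(round_severity(2.3), 2L)
  expect_equal(round_severity(2.61), 3L)
  expect_equal(round_severity(4.39, has_critical_test = TRUE), 4L)
  # integers are fixed points under every context
  for (s in 1:5) {
    expect_equal(round_severity(s), s)
    expect_equal(round_severity(s, has_critical_test = TRUE), s)
    expect_equal(round_severity(s, short_duration = TRUE), s)
  }
  # results stay on the scale at the extremes
  expect_equal(round_severity(1.5, has_critical_test = TRUE), 1L)
  expect_equal(round_severity(4.5), 5L)
})

test_that("triage_case reproduces hand-computed severities", {
  # single diagnosis, weight 1, severity 2: no rounding ambiguity
  kb1 <- triage_kb(
    findings = tibble::tibble(id = "f", label = "f",
                              synonyms = list(character()),
                              severity_severe = 1, severity_mild = 5),
    diagnoses = tibble::tibble(id = "d", label = "d",
                               baseline_prevalence = 0.1,
                               severity_severe = 2, severity_mild = 2,
                               critical_tests = list(character())),
    associations = tibble::tibble(diagnosis_id = "d", finding_id = "f",
                                  frequency_category = "very_common",
                                  severity_for_diagnosis = 2,
                                  demographic_modifiers = list(NULL))
  )
  r1 <- triage_case(kb1, make_case("f"))
  expect_equal(r1$fractional_severity, 2)
  expect_equal(r1$final_severity, 2L)
  expect_equal(r1$rounding_trigger, "none")

  # three diagnoses: fractional severity equals the brute-force weighted mean
  kb <- tiny_kb()
  case <- make_case(c("cough", "fever"))
  cfg <- triage_config()
  scores <- purrr::map_dbl(kb$diagnoses$id, oracle_score,
                           kb = kb, case = case, config = cfg)
  sev <- purrr::map_int(kb$diagnoses$id, diagnosis_case_severity,
                        kb = kb, case = case)
  ord <- order(-scores)
  expected_frac <- sum((scores / sum(scores))[ord] * sev[ord])
  r <- triage_case(kb, case)
  expect_equal(r$fractional_severity, expected_frac, tolerance = 1e-12)
  expect_equal(r$final_severity,
               round_severity(expected_frac, has_critical_test = TRUE))
})

test_that("an in-band fractional score is resolved by the critical-test trigger", {
  # two equally weighted diagnoses with severities 3 and 4 put the mean at
  # ~3.5; a third, negligible-weight severity-2 diagnosis carries the
  # critical test that forces rounding toward higher urgency
  mk <- function(critical) triage_kb(
    findings = tibble::tibble(
      id = c("f1", "f2"), label = c("f1", "f2"),
      synonyms = list(character(), character()),
      severity_severe = 1, severity_mild = 5
    ),
    diagnoses = tibble::tibble(
      id = c("da", "db", "dc"), label = c("da", "db", "dc"),
      baseline_prevalence = c(0.01, 0.01, 1e-6),
      severity_severe = c(3L, 4L, 2L), severity_mild = c(3L, 4L, 2L),
      critical_tests = list(character(), character(),
                            if (critical) "ecg" else character())
    ),
    associations = tibble::tibble(
      diagnosis_id = c("da", "db", "dc"),
      finding_id = c("f1", "f1", "f2"),
      frequency_category = c("very_common", "very_common", "uncommon"),
      severity_for_diagnosis = c(3L, 4L, 2L),
      demographic_modifiers = list(NULL, NULL, NULL)
    )
  )
  case <- make_case("f1")

  with_crit <- triage_case(mk(TRUE), case)
  expect_equal(with_crit$fractional_severity, 3.5, tolerance = 1e-3)
  expect_equal(with_crit$rounding_trigger, "critical_test_or_short_duration")
  expect_equal(with_crit$final_severity, 3L)

  without <- triage_case(mk(FALSE), case)
  expect_equal(without$rounding_trigger, "no_critical_long_duration")
  expect_equal(without$final_severity, 4L)

  # a short symptom duration triggers the same upgrade
  short <- triage_case(mk(FALSE), make_case("f1", durations = 6))
  expect_equal(short$rounding_trigger, "critical_test_or_short_duration")
  expect_equal(short$final_severity, 3L)
})

test_that("triage results are deterministic and stay on the 1-5 scale", {
  set.seed(303)
  kb <- generate_kb(10, 20, 4, seed = 5)
  for (rep in 1:10) {
    case <- random_case_for(kb)
    r1 <- triage_case(kb, case)
    r2 <- triage_case(kb, case)
    expect_identical(tidy(r1), tidy(r2))
    expect_true(r1$fractional_severity >= 1 && r1$fractional_severity <= 5)
    expect_true(r1$final_severity %in% 1:5)
    expect_lt(abs(r1$final_severity - r1$fractional_severity), 1)
  }
})

test_that("adding a severity-1 diagnosis's hallmark finding never raises severity", {
  set.seed(404)
  for (rep in 1:8) {
    kb <- generate_kb(sample(3:8, 1), 12, 3, seed = 4000 + rep)
    # graft a dedicated severity-1 diagnosis with its own very_common finding
    kb$findings <- dplyr::bind_rows(kb$findings, tibble::tibble(
      id = "red_flag", label = "red flag sign", synonyms = list(character()),
      severity_severe = 1L, severity_mild = 1L
    ))
    kb$diagnoses <- dplyr::bind_rows(kb$diagnoses, tibble::tibble(
      id = "crash", label = "crash dx", baseline_prevalence = 0.05,
      severity_severe = 1L, severity_mild = 1L,
      critical_tests = list(character())
    ))
    kb$associations <- dplyr::bind_rows(kb$associations, tibble::tibble(
      diagnosis_id = "crash", finding_id = "red_flag",
      frequency_category = "very_common", severity_for_diagnosis = 1L,
      demographic_modifiers = list(edtriage:::empty_modifiers())
    ))
    kb <- triage_kb(kb$findings, kb$diagnoses, kb$associations)
    case <- random_case_for(kb)
    case$findings <- case$findings[case$findings$finding_id != "red_flag", ]
    if (nrow(case$findings) == 0L) next
    before <- triage_case(kb, case)$fractional_severity
    augmented <- case
    augmented$findings <- dplyr::bind_rows(
      augmented$findings,
      tibble::tibble(finding_id = "red_flag", raw_label = "red flag sign",
                     duration_hours = NA_real_,
                     reported_severity = NA_integer_, source = "reported")
    )
    after <- triage_case(kb, augmented)$fractional_severity
    expect_lte(after, before + 1e-9)
  }
})
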