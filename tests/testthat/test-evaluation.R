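test_that("confusion matrices tabulate pairs and reject bad input", {
  m <- build_confusion(tibble::tibble(rater_a = c(1, 2), rater_b = c(1, 1)))
  expect_equal(attr(m, "n"), 2L)
  expect_equal(unclass(m)[1, 1], 1L)
  expect_equal(unclass(m)[2, 1], 1L)
  expect_equal(sum(m), 2L)

  expect_error(build_confusion(tibble::tibble(rater_a = integer(),
                                              rater_b = integer())),
               "at least one")
  expect_error(
    build_confusion(tibble::tibble(case_id = "v9", rater_a = 6, rater_b = 1)),
    "out of range.*v9"
  )
})

test_that("the packaged validation matrix carries the published counts", {
  m <- table5_fixture()
  expect_equal(sum(m), 73L)
  expect_equal(sum(diag(unclass(m))), 69L)
  expect_equal(unname(colSums(unclass(m))), c(13, 28, 21, 4, 7))
  expect_equal(unname(rowSums(unclass(m))), c(14, 26, 21, 6, 6))
  # expanding to pairs and re-tabulating is the identity
  expect_equal(unclass(build_confusion(confusion_to_pairs(m))),
               unclass(m))
})

test_that("weighted kappa reproduces the published agreement statistics", {
  m <- table5_fixture()
  lin <- weighted_kappa(m, "linear")
  # frozen from the closed form: po = 71.5/73, pe = 3699/5329
  expect_equal(lin$po_weighted, 71.5 / 73, tolerance = 1e-12)
  expect_equal(lin$pe_weighted, 3699 / 5329, tolerance = 1e-12)
  expect_equal(lin$kappa, 1520.5 / 1630, tolerance = 1e-12)
  expect_equal(round(lin$kappa, 3), 0.933)
  expect_equal(lin$band, "almost perfect")

  quad <- weighted_kappa(m, "quadratic")
  expect_equal(quad$po_weighted, 72.375 / 73, tolerance = 1e-12)
  expect_equal(quad$pe_weighted, 4469 / 5329, tolerance = 1e-12)
  expect_equal(round(quad$kappa, 3), 0.947)
})

test_that("kappa limits: perfect diagonals give 1, independence gives 0", {
  diag_m <- diag(c(3, 5, 2, 8, 1))
  for (scheme in c("linear", "quadratic", "unweighted")) {
    expect_equal(weighted_kappa(diag_m, scheme)$kappa, 1)
  }
  r <- c(2, 3, 1, 4, 5)
  indep <- outer(r, rev(r))
  for (scheme in c("linear", "quadratic", "unweighted")) {
    expect_equal(weighted_kappa(indep, scheme)$kappa, 0, tolerance = 1e-12)
  }
  expect_error(weighted_kappa(diag(c(10, 0, 0, 0, 0))), "undefined")
})

test_that("weighted kappa matches the double-loop oracle on random matrices", {
  set.seed(505)
  for (rep in 1:200) {
    m <- random_confusion()
    scheme <- sample(c("linear", "quadratic", "unweighted"), 1)
    got <- tryCatch(weighted_kappa(m, scheme)$kappa, error = function(e) NA)
    want <- oracle_kappa(m, scheme)
    if (is.na(got)) {
      expect_true(!is.finite(want) || abs(1 - want) < 1e-12)
    } else {
      expect_lt(abs(got - want), 1e-12)
    }
  }
})

test_that("weighted kappa is invariant under transposition", {
  set.seed(606)
  for (rep in 1:25) {
    m <- random_confusion()
    for (scheme in c("linear", "quadratic")) {
      expect_equal(weighted_kappa(t(m), scheme)$kappa,
                   weighted_kappa(m, scheme)$kappa, tolerance = 1e-12)
    }
  }
})

test_that("widening a disagreement never increases linear-weighted agreement", {
  set.seed(707)
  for (rep in 1:25) {
    m <- random_confusion()
    m[2, 3] <- m[2, 3] + 5 # ensure mass at distance 1
    po1 <- weighted_kappa(m, "linear")$po_weighted
    m2 <- m
    m2[2, 3] <- m2[2, 3] - 1
    m2[2, 4] <- m2[2, 4] + 1 # same row total, distance 1 -> 2
    po2 <- weighted_kappa(m2, "linear")$po_weighted
    expect_lte(po2, po1 + 1e-12)
  }
})

test_that("match_fraction is the diagonal share", {
  expect_equal(match_fraction(table5_fixture()), 69 / 73)
  expect_equal(match_fraction(diag(1:5)), 1)
  offdiag <- matrix(0, 5, 5)
  offdiag[cbind(1:5, c(2:5, 1))] <- 2 # every count off the diagonal
  expect_equal(match_fraction(offdiag), 0)
})

test_that("subgroup matrices keep the full ordinal shape", {
  m <- table5_fixture()
  sub <- subgroup_matrix(m, reference_levels = c(1, 2))
  expect_equal(sum(sub), 41L)
  expect_equal(dim(unclass(sub)), c(5L, 5L))
  expect_equal(unclass(sub)[1, 1], 13L)
  expect_equal(unclass(sub)[1, 2], 1L)
  expect_equal(unclass(sub)[2, 2], 26L)
  expect_equal(unclass(sub)[4, 2], 1L)
  expect_equal(sum(unclass(sub)[, 3:5]), 0L)
  expect_equal(sum(diag(unclass(sub))), 39L)

  expect_equal(unclass(subgroup_matrix(m, 1:5)), unclass(m))

  level5 <- subgroup_matrix(m, 5)
  expect_equal(sum(level5), 7L)
  expect_equal(unclass(level5)[3, 5], 1L)
  expect_equal(unclass(level5)[5, 5], 6L)

  expect_error(subgroup_matrix(m, integer()), "non-empty")
})

test_that("the urgent subgroup reproduces the published kappa", {
  sub <- subgroup_matrix(table5_fixture(), reference_levels = c(1, 2))
  lin <- weighted_kappa(sub, "linear")
  expect_equal(lin$po_weighted, 40.25 / 41, tolerance = 1e-12)
  expect_equal(lin$pe_weighted, 1474.75 / 1681, tolerance = 1e-12)
  expect_equal(round(lin$kappa, 3), 0.851)
})

test_that("kappa interpretation bands follow the conventional cut-points", {
  expect_equal(interpret_kappa(0.93), "almost perfect")
  expect_equal(interpret_kappa(0.45), "moderate")
  expect_equal(interpret_kappa(-0.1), "no agreement")
  expect_equal(
    interpret_kappa(c(0, 0.20, 0.21, 0.40, 0.60, 0.61, 0.80, 0.81, 1)),
    c("slight", "slight", "fair", "fair", "moderate", "substantial",
      "substantial", "almost perfect", "almost perfect")
  )
  expect_error(interpret_kappa(1.2), "exceed")
})

test_that("the bootstrap interval is seeded, stable, and contains the estimate", {
  pairs <- confusion_to_pairs(table5_fixture())
  b1 <- kappa_bootstrap_ci(pairs, "linear", B = 2000, seed = 9)
  b1b <- kappa_bootstrap_ci(pairs, "linear", B = 2000, seed = 9)
  expect_identical(b1$ci, b1b$ci)
  expect_true(b1$ci[1] <= b1$kappa && b1$kappa <= b1$ci[2])
  expect_equal(round(b1$kappa, 3), 0.933)

  b2 <- kappa_bootstrap_ci(pairs, "linear", B = 4000, seed = 9)
  expect_lt(max(abs(b1$ci - b2$ci)), 0.02)

  degenerate <- tibble::tibble(rater_a = rep(2, 10), rater_b = rep(2, 10))
  expect_error(kappa_bootstrap_ci(degenerate, "linear", B = 200, seed = 1),
               "undefined")
  expect_error(kappa_bootstrap_ci(pairs, "linear", B = 50), "at least 100")
})

test_that("agreement_report assembles both schemes and the subgroup block", {
  rep_ <- agreement_report(table5_fixture())
  expect_equal(rep_$n, 73L)
  expect_equal(rep_$matched, 69L)
  expect_equal(round(rep_$kappa_linear$kappa, 3), 0.933)
  expect_equal(round(rep_$kappa_quadratic$kappa, 3), 0.947)
  expect_equal(rep_$subgroup$n, 41L)
  expect_equal(rep_$subgroup$matched, 39L)
  expect_equal(round(rep_$subgroup$kappa_linear$kappa, 3), 0.851)

  td <- tidy(rep_)
  expect_equal(nrow(td), 4L)
  expect_setequal(unique(td$block), c("overall", "reference_1_2"))

  out <- capture.output(print(rep_))
  expect_match(paste(out, collapse = "\n"), "0.933")
})

test_that("tidiers return well-formed tibbles", {
  lin <- weighted_kappa(table5_fixture(), "linear")
  td <- tidy(lin)
  expect_equal(nrow(td), 1L)
  expect_equal(td$kappa, lin$kappa)
  expect_true(is.na(td$conf.low))
  expect_equal(glance(lin)$band, "almost perfect")

  tm <- tidy(table5_fixture())
  expect_equal(nrow(tm), 25L)
  expect_equal(sum(tm$count), 73L)
  expect_equal(tm$count[tm$engine == 2 & tm$reference == 2], 26L)
})
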