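#' Build a 5x5 confusion matrix from paired ordinal scores
#'
#' Rows index the engine's (rater A) level, columns the reference
#' standard's (rater B, e.g. the five-level acuity scale it is validated
#' against); the full `k x k` shape is always retained so ordinal distances
#' are preserved even when levels are unobserved.
#'
#' @param pairs data frame with columns `rater_a` and `rater_b` (integers in
#'   `1..k`), optionally `case_id` (used in error messages).
#' @param k number of ordinal levels (default 5).
#' @return A `k x k` integer matrix of class `confusion_matrix` with
#'   attribute `n`.
#' @seealso [weighted_kappa()], [match_fraction()], [subgroup_matrix()]
#' @examples
#' build_confusion(tibble::tibble(rater_a = c(1, 2), rater_b = c(1, 1)))
#' @export
build_confusion <- function(pairs, k = 5L) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0L) abort("at least one score pair is required (n >= 1)")
  a <- as.integer(pairs$rater_a)
  b <- as.integer(pairs$rater_b)
  bad <- which(is.na(a) | is.na(b) | a < 1L | a > k | b < 1L | b > k)
  if (length(bad) > 0L) {
    ids <- if ("case_id" %in% names(pairs)) pairs$case_id[bad] else bad
    abort(paste0("score out of range 1..", k, " for case(s): ",
                 paste(utils::head(ids, 5L), collapse = ", ")))
  }
  counts <- as.matrix(table(factor(a, levels = 1:k), factor(b, levels = 1:k)))
  dimnames(counts) <- list(engine = 1:k, reference = 1:k)
  structure(counts, n = sum(counts), class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(x, k = 5L) {
  if (inherits(x, "confusion_matrix")) return(x)
  if (is.data.frame(x) && all(c("rater_a", "rater_b") %in% names(x))) {
    return(build_confusion(x, k = k))
  }
  m <- as.matrix(x)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  dimnames(m) <- list(engine = seq_len(nrow(m)), reference = seq_len(ncol(m)))
  structure(m, n = sum(m), class = c("confusion_matrix", "matrix"))
}

#' Expand a confusion matrix back into score pairs
#'
#' @param matrix a `confusion_matrix` (or plain square matrix of counts).
#' @return A tibble with columns `case_id`, `rater_a`, `rater_b`, one row
#'   per counted pair, in row-major cell order.
#' @export
confusion_to_pairs <- function(matrix) {
  m <- as_confusion(matrix)
  k <- nrow(m)
  cells <- tidyr::expand_grid(rater_a = 1:k, rater_b = 1:k)
  cells$count <- purrr::map2_int(cells$rater_a, cells$rater_b,
                                 ~ as.integer(m[.x, .y]))
  out <- tidyr::uncount(cells, weights = .data$count)
  out$case_id <- paste0("case_", seq_len(nrow(out)))
  out[, c("case_id", "rater_a", "rater_b")]
}

kappa_weights <- function(k, scheme = c("linear", "quadratic", "unweighted")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(1:k, 1:k, "-"))
  switch(scheme,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2,
    unweighted = (d == 0) * 1
  )
}

#' Weighted Cohen's kappa for two ordinal raters
#'
#' Chance-corrected agreement with partial credit for near misses:
#' `kappa = (po - pe) / (1 - pe)` with observed weighted agreement
#' `po = sum(w * counts) / n` and expected `pe = sum(w * r %o% c) / n^2`,
#' where the weights are `w_ij = 1 - |i-j|/(k-1)` (linear),
#' `1 - (|i-j|/(k-1))^2` (quadratic), or the identity indicator
#' (unweighted). `k` is fixed by the scale (5 here), not by the observed
#' categories, so subgroup matrices with empty columns keep the full
#' ordinal geometry.
#'
#' @param matrix a `confusion_matrix`, a plain square count matrix, or a
#'   pairs data frame (`rater_a`, `rater_b`).
#' @param scheme `"linear"`, `"quadratic"`, or `"unweighted"`.
#' @return An object of class `kappa_result`: list with `kappa`, `scheme`,
#'   `po_weighted`, `pe_weighted`, `n`, `band` (agreement label), `ci`
#'   (`NULL` until [kappa_bootstrap_ci()] is attached), `ci_method`.
#' @examples
#' weighted_kappa(table5_fixture(), scheme = "linear")
#' @export
weighted_kappa <- function(matrix, scheme = c("linear", "quadratic",
                                              "unweighted")) {
  scheme <- match.arg(scheme)
  m <- as_confusion(matrix)
  n <- sum(m)
  if (n < 1) abort("confusion matrix must contain at least one pair")
  k <- nrow(m)
  w <- kappa_weights(k, scheme)
  po <- sum(w * m) / n
  r <- rowSums(m)
  cl <- colSums(m)
  pe <- sum(w * outer(r, cl)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    abort("kappa undefined: expected agreement is 1 (all mass in one category)")
  }
  kappa <- (po - pe) / (1 - pe)
  structure(
    list(
      kappa = kappa, scheme = scheme,
      po_weighted = po, pe_weighted = pe,
      n = as.integer(n),
      band = interpret_kappa(kappa),
      ci = NULL, ci_method = "none"
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Weighted kappa (", x$scheme, "): ",
      format(round(x$kappa, 3), nsmall = 3), sep = "")
  if (!is.null(x$ci)) {
    cat(" (95% CI ", format(round(x$ci[1], 3), nsmall = 3), "-",
        format(round(x$ci[2], 3), nsmall = 3), ", ", x$ci_method, ")",
        sep = "")
  }
  cat("\n  n =", x$n, " po =", format(round(x$po_weighted, 4), nsmall = 4),
      " pe =", format(round(x$pe_weighted, 4), nsmall = 4), "\n")
  cat("  agreement:", x$band, "\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for weighted kappa
#'
#' Case-level resampling with replacement: pairs are resampled `B` times,
#' kappa recomputed on each resample, and the `alpha/2` and `1 - alpha/2`
#' percentiles returned. Resamples on which kappa is undefined (all mass in
#' one category for both raters) are skipped and counted; a warning is
#' raised when more than 1% are skipped. Deterministic given `seed`.
#'
#' @param pairs data frame with `rater_a`, `rater_b`.
#' @param scheme weight scheme, as in [weighted_kappa()].
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed for the resampling stream.
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @param k number of ordinal levels.
#' @return A `kappa_result` (point estimate on the full data) with `ci` set
#'   to the percentile interval and `ci_method = "bootstrap"`; the number of
#'   skipped resamples is attached as attribute `skipped`.
#' @export
kappa_bootstrap_ci <- function(pairs, scheme = "linear", B = 2000L,
                               seed = 1L, alpha = 0.05, k = 5L) {
  if (B < 100L) abort("B must be at least 100")
  pairs <- tibble::as_tibble(pairs)
  point <- weighted_kappa(build_confusion(pairs, k = k), scheme = scheme)
  n <- nrow(pairs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  stats <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- build_confusion(pairs[idx, ], k = k)
    stats[b] <- tryCatch(weighted_kappa(m, scheme = scheme)$kappa,
                         error = function(e) NA_real_)
  }
  skipped <- sum(is.na(stats))
  if (skipped > 0.01 * B) {
    warn(paste0(skipped, " of ", B,
                " bootstrap resamples had undefined kappa and were skipped"))
  }
  ci <- unname(quantile(stats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  point$ci <- ci
  point$ci_method <- "bootstrap"
  attr(point, "skipped") <- skipped
  point
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fraction of exactly matching score pairs
#'
#' The trace of the confusion matrix over its total — the proportion of
#' cases on which the two raters agree exactly.
#'
#' @param matrix a `confusion_matrix` or coercible input.
#' @return Fraction in `[0, 1]`.
#' @examples
#' match_fraction(table5_fixture())
#' @export
match_fraction <- function(matrix) {
  m <- as_confusion(matrix)
  sum(diag(unclass(m))) / sum(m)
}

#' Confusion matrix restricted to reference-level subgroups
#'
#' Keeps only pairs whose *reference* (rater B) score is in
#' `reference_levels`, but retains the full `k x k` shape — columns outside
#' the subgroup are simply zero — so that kappa on the subgroup still uses
#' the full five-level ordinal distance.
#'
#' @param pairs data frame with `rater_a`, `rater_b` (or a
#'   `confusion_matrix`, which is expanded first).
#' @param reference_levels non-empty set of reference levels to keep.
#' @param k number of ordinal levels.
#' @return A `confusion_matrix`.
#' @examples
#' subgroup_matrix(table5_fixture(), reference_levels = c(1, 2))
#' @export
subgroup_matrix <- function(pairs, reference_levels, k = 5L) {
  if (length(reference_levels) == 0L) {
    abort("reference_levels must be non-empty")
  }
  if (!is.data.frame(pairs)) pairs <- confusion_to_pairs(pairs)
  kept <- pairs[pairs$rater_b %in% reference_levels, , drop = FALSE]
  build_confusion(kept, k = k)
}

#' Interpret a kappa value as a conventional agreement band
#'
#' Standard ordinal-agreement labels: below 0 no agreement; 0-0.20 slight;
#' 0.21-0.40 fair; 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.0
#' almost perfect. Interior boundaries belong to the lower band (0.60 is
#' "moderate").
#'
#' @param kappa numeric vector of kappa values (each `<= 1`).
#' @return Character vector of band labels.
#' @examples
#' interpret_kappa(c(0.93, 0.45, -0.1))
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa > 1 + 1e-12)) abort("kappa cannot exceed 1")
  cut_label <- function(x) {
    if (x < 0) "no agreement"
    else if (x <= 0.20) "slight"
    else if (x <= 0.40) "fair"
    else if (x <= 0.60) "moderate"
    else if (x <= 0.80) "substantial"
    else "almost perfect"
  }
  vapply(kappa, cut_label, character(1))
}

#' Full agreement report between engine and reference scores
#'
#' Computes the confusion matrix, exact-match statistics, weighted kappa
#' under both the linear and quadratic schemes (both are reported because
#' the two can differ materially on the same matrix), optional bootstrap
#' CIs, and a reference-level subgroup block.
#'
#' @param pairs data frame with `rater_a`, `rater_b` (and optionally
#'   `case_id`), or a `confusion_matrix`.
#' @param subgroup_levels reference levels for the subgroup block (default
#'   the two most urgent, `c(1, 2)`); `NULL` to skip.
#' @param boot number of bootstrap resamples for CIs, or `NULL` for none.
#' @param seed seed for the bootstrap stream.
#' @return A list of class `agreement_report` with elements `matrix`, `n`,
#'   `matched`, `match_fraction`, `kappa_linear`, `kappa_quadratic`, and
#'   (unless skipped) `subgroup` (same structure, minus the nested
#'   subgroup).
#' @examples
#' agreement_report(table5_fixture())
#' @export
agreement_report <- function(pairs, subgroup_levels = c(1, 2), boot = NULL,
                             seed = 1L) {
  if (!is.data.frame(pairs)) pairs <- confusion_to_pairs(pairs)
  m <- build_confusion(pairs)
  block <- function(pairs, m) {
    kl <- weighted_kappa(m, "linear")
    kq <- weighted_kappa(m, "quadratic")
    if (!is.null(boot)) {
      kl <- kappa_bootstrap_ci(pairs, "linear", B = boot, seed = seed)
      kq <- kappa_bootstrap_ci(pairs, "quadratic", B = boot, seed = seed)
    }
    list(
      matrix = m, n = sum(m), matched = sum(diag(unclass(m))),
      match_fraction = match_fraction(m),
      kappa_linear = kl, kappa_quadratic = kq
    )
  }
  out <- block(pairs, m)
  if (!is.null(subgroup_levels)) {
    sub_pairs <- pairs[pairs$rater_b %in% subgroup_levels, , drop = FALSE]
    out$subgroup <- c(list(reference_levels = subgroup_levels),
                      block(sub_pairs, build_confusion(sub_pairs)))
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  fmt3 <- function(v) format(round(v, 3), nsmall = 3)
  cat("Agreement report\n")
  cat("  n =", x$n, " matched =", x$matched,
      " (", fmt3(100 * x$match_fraction), "% )\n")
  cat("  kappa (linear):   ", fmt3(x$kappa_linear$kappa),
      " [", x$kappa_linear$band, "]\n", sep = "")
  cat("  kappa (quadratic):", fmt3(x$kappa_quadratic$kappa),
      " [", x$kappa_quadratic$band, "]\n", sep = "")
  if (!is.null(x$subgroup)) {
    s <- x$subgroup
    cat("  subgroup (reference levels ",
        paste(s$reference_levels, collapse = ","), "): n = ", s$n,
        ", matched = ", s$matched,
        ", kappa linear = ", fmt3(s$kappa_linear$kappa),
        ", quadratic = ", fmt3(s$kappa_quadratic$kappa), "\n", sep = "")
  }
  invisible(x)
}

#' Read a square confusion matrix from CSV
#'
#' Plain CSV of integer counts, rows = engine level, no header.
#'
#' @param path path to the CSV file.
#' @return A `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  as_confusion(m)
}

#' Read score pairs from CSV
#'
#' Expected columns: `case_id, engine_score, reference_score` (header
#' required).
#'
#' @param path path to the CSV file.
#' @return A tibble with `case_id`, `rater_a`, `rater_b`.
#' @export
read_pairs_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("engine_score", "reference_score") %in% names(df))) {
    abort("pairs CSV must have columns case_id, engine_score, reference_score")
  }
  tibble::tibble(
    case_id = as.character(df$case_id %||% seq_len(nrow(df))),
    rater_a = as.integer(df$engine_score),
    rater_b = as.integer(df$reference_score)
  )
}
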