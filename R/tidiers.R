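#' Tidy a kappa result
#'
#' @param x a `kappa_result`.
#' @param ... unused.
#' @return One-row tibble with `scheme`, `kappa`, `po_weighted`,
#'   `pe_weighted`, `n`, `band`, `conf.low`, `conf.high`, `ci_method`.
#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    kappa = x$kappa,
    po_weighted = x$po_weighted,
    pe_weighted = x$pe_weighted,
    n = x$n,
    band = x$band,
    conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
    conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2],
    ci_method = x$ci_method
  )
}

#' @rdname tidy.kappa_result
#' @method glance kappa_result
#' @export
glance.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, n = x$n, scheme = x$scheme, band = x$band)
}

#' Tidy a confusion matrix into long form
#'
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @return Tibble with `engine`, `reference`, `count` (one row per cell).
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  k <- nrow(x)
  tibble::tibble(
    engine = rep(1:k, times = k),
    reference = rep(1:k, each = k),
    count = as.integer(unclass(x)[cbind(rep(1:k, times = k),
                                        rep(1:k, each = k))])
  )
}

#' Tidy a triage result
#'
#' @param x a `triage_result`.
#' @param ... unused.
#' @return One-row tibble with `case_id`, `fractional_severity`,
#'   `final_severity`, `rounding_trigger`.
#' @method tidy triage_result
#' @export
tidy.triage_result <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id,
    fractional_severity = x$fractional_severity,
    final_severity = x$final_severity,
    rounding_trigger = x$rounding_trigger
  )
}

#' @rdname tidy.triage_result
#' @method glance triage_result
#' @export
glance.triage_result <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id,
    final_severity = x$final_severity,
    n_differential = nrow(x$differential),
    top_diagnosis = x$differential$diagnosis_id[1]
  )
}

#' Tidy an agreement report
#'
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return Tibble with one row per (block, scheme) combination.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  one <- function(b, label) {
    dplyr::mutate(
      dplyr::bind_rows(tidy(b$kappa_linear), tidy(b$kappa_quadratic)),
      block = label, matched = b$matched, match_fraction = b$match_fraction
    )
  }
  out <- one(x, "overall")
  if (!is.null(x$subgroup)) {
    out <- dplyr::bind_rows(
      out,
      one(x$subgroup,
          paste0("reference_",
                 paste(x$subgroup$reference_levels, collapse = "_")))
    )
  }
  dplyr::relocate(out, "block")
}
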