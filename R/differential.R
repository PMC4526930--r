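#' Score one diagnosis for a case
#'
#' The engine's likelihood model is a naive-Bayes-style product: the
#' diagnosis's baseline prevalence times, for each case finding, the
#' likelihood of that finding given the diagnosis. An associated finding
#' contributes `min(1, p(category) * demographic_multiplier)`; a finding
#' with no association to the diagnosis contributes the small epsilon
#' `config$unmatched_finding_epsilon`. Finally, each *key* association of
#' the diagnosis whose finding is absent from the case multiplies the score
#' by `config$key_missing_penalty` — a key finding is required for the
#' diagnosis, so its absence is strong (but soft) evidence against it.
#' Unresolved case findings (unknown to the whole KB) contribute epsilon
#' uniformly, so they rescale every score and leave the ranking unchanged.
#'
#' @param kb a `triage_kb`.
#' @param case a `patient_case`.
#' @param diagnosis_id id of a diagnosis in `kb`.
#' @param config a [triage_config()].
#' @return Non-negative scalar score.
#' @examples
#' kb <- generate_kb(3, 6, 2, seed = 1)
#' case <- generate_cases(kb, 1, seed = 2)$cases[[1]]
#' diagnosis_score(kb, case, kb$diagnoses$id[1])
#' @export
diagnosis_score <- function(kb, case, diagnosis_id,
                            config = triage_config()) {
  if (!diagnosis_id %in% kb$diagnoses$id) {
    abort(paste0("unknown diagnosis id: ", diagnosis_id))
  }
  d <- kb$diagnoses[kb$diagnoses$id == diagnosis_id, ]
  assoc <- kb$associations[kb$associations$diagnosis_id == diagnosis_id, ]
  case_ids <- case$findings$finding_id # NA for unresolved labels

  lik <- purrr::map_dbl(case_ids, function(fid) {
    if (!is.na(fid) && fid %in% assoc$finding_id) {
      a <- assoc[assoc$finding_id == fid, ][1L, ]
      p <- frequency_to_probability(a$frequency_category, config)
      m <- demographic_multiplier(a$demographic_modifiers[[1L]],
                                  age = case$demographics$age,
                                  sex = case$demographics$sex)
      min(1, p * m)
    } else {
      config$unmatched_finding_epsilon
    }
  })

  key_missing <- sum(
    assoc$frequency_category == "key" &
      !assoc$finding_id %in% case_ids[!is.na(case_ids)]
  )

  d$baseline_prevalence * prod(lik) *
    config$key_missing_penalty^key_missing
}

#' Build the weighted differential diagnosis for a case
#'
#' Every diagnosis in the KB is scored with [diagnosis_score()], ranked by
#' raw score (ties broken by higher baseline prevalence, then lexicographic
#' id, so results are identical across runs and platforms), truncated to the
#' top `K`, and the retained raw scores are normalized into weights summing
#' to 1.
#'
#' @param kb a `triage_kb` with at least one diagnosis.
#' @param case a `patient_case`.
#' @param K differential cut; defaults to `config$top_k` (100).
#' @param config a [triage_config()].
#' @return A tibble of class `triage_differential` with columns `rank`,
#'   `diagnosis_id`, `raw_score`, `weight`, plus attributes `case_id` and
#'   `K`.
#' @export
build_differential <- function(kb, case, K = config$top_k,
                               config = triage_config()) {
  if (nrow(kb$diagnoses) == 0L) abort("knowledge base has no diagnoses")
  scores <- tibble::tibble(
    diagnosis_id = kb$diagnoses$id,
    raw_score = purrr::map_dbl(kb$diagnoses$id, diagnosis_score,
                               kb = kb, case = case, config = config),
    baseline_prevalence = kb$diagnoses$baseline_prevalence
  )
  if (all(scores$raw_score == 0)) {
    abort("degenerate case: all diagnosis scores are zero, cannot normalize")
  }
  out <- dplyr::arrange(scores, dplyr::desc(.data$raw_score),
                        dplyr::desc(.data$baseline_prevalence),
                        .data$diagnosis_id)
  out <- utils::head(out, as.integer(K))
  out <- dplyr::transmute(
    out,
    rank = dplyr::row_number(),
    diagnosis_id = .data$diagnosis_id,
    raw_score = .data$raw_score,
    weight = .data$raw_score / sum(.data$raw_score)
  )
  structure(out,
            class = c("triage_differential", class(out)),
            case_id = case$case_id, K = as.integer(K))
}

#' Write a differential list as TSV
#'
#' @param differential a `triage_differential`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(differential, path) {
  utils::write.table(
    as.data.frame(differential)[, c("rank", "diagnosis_id", "raw_score",
                                    "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
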