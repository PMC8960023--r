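#' Run the full structuring pipeline on a corpus
#'
#' Retrieval (SNOMED malignancy filter), text cleaning and multi-pass
#' extraction, harmonisation into analysis categories with molecular
#' subtyping, and the eligibility/deduplication flow, returning the
#' analysis-ready cohort plus a combined exclusion log covering both
#' stages.
#'
#' @param reports Corpus data frame (see [read_corpus()]).
#' @param rulesets Extraction rule sets, default [default_rulesets()].
#' @return List: `cohort` (analysis-ready patient records), `exclusions`
#'   (`report_id`, `reason`), `extraction` (raw per-report captures).
#' @export
run_pipeline <- function(reports, rulesets = default_rulesets()) {
  ret <- retrieve_malignant(reports)
  extraction <- extract_corpus(ret$kept, rulesets)
  records <- harmonize_records(extraction, ret$kept)
  elig <- apply_eligibility(records)
  exclusions <- rbind(ret$excluded, elig$exclusions)
  list(cohort = elig$cohort, exclusions = exclusions, extraction = extraction)
}

#' @keywords internal
"_PACKAGE"
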