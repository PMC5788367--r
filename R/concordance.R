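OUTCOMES <- c(names(COW_VARIANTS), "any")

.check_outcome <- function(outcome) {
  if (!(is.character(outcome) && length(outcome) == 1L &&
        outcome %in% OUTCOMES))
    stop("outcome must be one of: ", paste(OUTCOMES, collapse = ", "),
         call. = FALSE)
  outcome
}

#' Is a relative concordant with the reference proband for an outcome?
#'
#' For a single-variant outcome the relative is concordant when they carry
#' that variant; the outcome must be one the reference proband carries
#' (concordance columns exist only for the proband's own variants). For the
#' `"any"` outcome the relative is concordant when the two profiles share
#' at least one variant — sharing, not set equality, so a relative carrying
#' a strict subset of the proband's variants is concordant.
#'
#' @param reference_profile Character vector, the reference proband's
#'   variant profile.
#' @param fdr_profile Character vector, the relative's profile.
#' @param outcome One of `"classical"`, `"a1_asymmetry"`,
#'   `"incomplete_pcom"`, `"fetal_pc"`, `"any"`.
#' @return Logical scalar.
#' @export
#' @examples
#' fdr_concordant(c("incomplete_pcom", "a1_asymmetry"),
#'                "incomplete_pcom", "any")
fdr_concordant <- function(reference_profile, fdr_profile, outcome) {
  .check_outcome(outcome)
  ref <- profile_to_mask(reference_profile)
  fdr <- profile_to_mask(fdr_profile)
  if (outcome == "any") return(bitwAnd(ref, fdr) > 0L)
  bit <- COW_VARIANTS[[outcome]]
  if (bitwAnd(ref, bit) == 0L)
    stop("outcome '", outcome, "' is not carried by the reference proband",
         call. = FALSE)
  bitwAnd(fdr, bit) > 0L
}

#' Events/trials concordance of a family against a reference proband
#'
#' Counts, among the evaluated family's imaged first-degree relatives, how
#' many share the outcome with the reference proband. When the reference
#' proband belongs to a different (index) family, the evaluated family's
#' own proband must not be included among `fdr_profiles`: the comparison
#' proband's configuration differs from the index proband's by
#' construction, and counting it would bias the concordance downward.
#'
#' @inheritParams fdr_concordant
#' @param fdr_profiles Non-empty list of the family's FDR profiles.
#' @return A list of class `cow_count` with `events` and `trials`.
#' @export
family_concordance <- function(reference_profile, fdr_profiles, outcome) {
  if (!length(fdr_profiles))
    stop("fdr_profiles must be non-empty", call. = FALSE)
  events <- sum(vapply(fdr_profiles, function(p)
    fdr_concordant(reference_profile, p, outcome), TRUE))
  structure(list(events = events, trials = length(fdr_profiles)),
            class = "cow_count")
}

#' @export
print.cow_count <- function(x, ...) {
  cat(x$events, "/", x$trials, "\n", sep = "")
  invisible(x)
}

#' Pooled concordance proportion over families
#'
#' The FDR-weighted pooled ratio: total concordant relatives over total
#' evaluated relatives, matching the events/trials data entering the
#' conditional logistic model. Set `per_family_mean = TRUE` for the
#' unweighted mean of per-family proportions instead.
#'
#' @param counts Non-empty list of `cow_count` objects (or of
#'   `list(events=, trials=)` pairs).
#' @param per_family_mean Average per-family proportions instead of pooling
#'   counts. Default `FALSE`.
#' @return Proportion in \[0, 1\].
#' @export
pooled_concordance <- function(counts, per_family_mean = FALSE) {
  if (!length(counts)) stop("counts must be non-empty", call. = FALSE)
  ev <- vapply(counts, function(x) as.numeric(x$events), 1)
  tr <- vapply(counts, function(x) as.numeric(x$trials), 1)
  stopifnot(all(tr >= 1), all(ev >= 0), all(ev <= tr))
  if (per_family_mean) mean(ev / tr) else sum(ev) / sum(tr)
}
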