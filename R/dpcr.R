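#' Mutant allele fraction of a digital-PCR assay
#'
#' MAF (%) = 100 * mutant / (mutant + wild-type) copies.
#'
#' @param mutant,wildtype non-negative copy counts, not both zero.
#' @return MAF percentage; `NA` (undefined) when both counts are zero.
#' @export
maf <- function(mutant, wildtype) {
  if (any(mutant < 0) || any(wildtype < 0))
    stop("copy counts must be non-negative", call. = FALSE)
  total <- mutant + wildtype
  ifelse(total == 0, NA_real_, 100 * mutant / total)
}

#' ctDNA positivity call of a digital-PCR assay
#'
#' A serum sample is ctDNA-positive when one or more mutant alleles are
#' detected in the assay and negative when none are.
#'
#' @param mutant non-negative mutant copy count(s).
#' @return `"positive"` or `"negative"` per assay.
#' @export
ctdna_call <- function(mutant) {
  if (any(mutant < 0)) stop("mutant count must be non-negative", call. = FALSE)
  ifelse(mutant >= 1, "positive", "negative")
}

#' Per-patient ctDNA call across several hot-spot assays
#'
#' When a patient is assayed for several mutations (e.g. the PIK3CA hot
#' spots H1047R, E545K, E542K), the patient is ctDNA-positive if any single
#' assay is positive.
#'
#' @param calls character vector of per-assay `"positive"`/`"negative"`
#'   calls (from [ctdna_call()]).
#' @return Single `"positive"` or `"negative"` patient-level call.
#' @export
ctdna_call_patient <- function(calls) {
  stopifnot(length(calls) >= 1L, all(calls %in% c("positive", "negative")))
  if (any(calls == "positive")) "positive" else "negative"
}

#' Annotate a digital-PCR result table with MAF and calls
#'
#' @param x data frame with columns `sample_id`, `assay`, `mutant_copies`,
#'   `wildtype_copies` (the tab-delimited dPCR exchange layout).
#' @return The input with `maf_percent` and `call` columns appended.
#' @export
dpcr_annotate <- function(x) {
  need <- c("sample_id", "assay", "mutant_copies", "wildtype_copies")
  if (!all(need %in% names(x)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(x)), collapse = ", ")),
         call. = FALSE)
  x$maf_percent <- maf(x$mutant_copies, x$wildtype_copies)
  x$call <- ctdna_call(x$mutant_copies)
  x
}
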