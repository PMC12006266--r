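#' Hypergeometric gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list against a
#' background universe. The raw p-value is the upper-tail hypergeometric
#' probability P(X >= count); in `"ease"` mode (the conservative score used
#' by DAVID) the observed count is reduced by one before the tail is taken,
#' so an EASE p is never smaller than the standard one. Both raw p-values
#' are reported; Bonferroni and Benjamini-Hochberg adjustments are applied
#' to the selected mode.
#'
#' @param query character vector of gene identifiers; members outside the
#'   background are dropped with a warning.
#' @param terms gene sets: a `"gmt"` object from [read_gmt()] or a named
#'   list of character vectors.
#' @param background character vector of background identifiers; default is
#'   the union of all term members.
#' @param mode `"ease"` (default) or `"standard"`.
#' @return Data frame sorted by the selected raw p ascending, one row per
#'   term: `term_id`, `term_name`, `count`, `list_total`, `pop_hits`,
#'   `pop_total`, `percent`, `fold_enrichment`, `p_standard`, `p_ease`,
#'   `p_raw`, `p_bonferroni`, `p_bh`.
#' @export
hypergeom_enrich <- function(query, terms, background = NULL,
                             mode = c("ease", "standard")) {
  mode <- match.arg(mode)
  if (inherits(terms, "gmt")) {
    descriptions <- terms$descriptions
    terms <- terms$terms
  } else {
    descriptions <- stats::setNames(names(terms), names(terms))
  }
  if (length(terms) == 0L) stop("no gene sets supplied", call. = FALSE)
  if (is.null(background)) background <- unique(unlist(terms))
  background <- unique(as.character(background))
  if (length(query) == 0L || length(background) == 0L)
    stop("query and background must be non-empty", call. = FALSE)
  query <- unique(as.character(query))
  outside <- setdiff(query, background)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(outside)))
    query <- intersect(query, background)
  }
  if (length(query) == 0L)
    stop("no query genes remain within the background", call. = FALSE)
  list_total <- length(query)
  pop_total <- length(background)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(unique(terms[[id]]), background)
    pop_hits <- length(members)
    count <- length(intersect(query, members))
    p_std <- stats::phyper(count - 1, pop_hits, pop_total - pop_hits,
                           list_total, lower.tail = FALSE)
    p_ease <- stats::phyper(count - 2, pop_hits, pop_total - pop_hits,
                            list_total, lower.tail = FALSE)
    fe <- if (pop_hits > 0)
      (count / list_total) / (pop_hits / pop_total) else NA_real_
    data.frame(term_id = id, term_name = unname(descriptions[id]),
               count = count, list_total = list_total,
               pop_hits = pop_hits, pop_total = pop_total,
               percent = 100 * count / list_total,
               fold_enrichment = fe,
               p_standard = p_std, p_ease = p_ease,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_raw <- if (mode == "ease") out$p_ease else out$p_standard
  out$p_bonferroni <- bonferroni_adjust(out$p_raw)
  out$p_bh <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni multiple-testing adjustment
#'
#' `min(1, m * p)` for m tests; wraps [stats::p.adjust()].
#'
#' @param p_values numeric p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' Step-up BH with monotonicity enforcement; wraps [stats::p.adjust()].
#'
#' @param p_values numeric p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}
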