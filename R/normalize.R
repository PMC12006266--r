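#' Log2 transform of non-negative intensities
#'
#' Element-wise `log2(x + 1)`, the variance-stabilizing transform applied
#' before normalization when data arrive on the linear intensity scale.
#'
#' @param values numeric vector/matrix of non-negative intensities.
#' @return Object of the same shape on the log2 scale.
#' @export
log_transform <- function(values) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("log_transform requires finite non-negative values", call. = FALSE)
  log2(values + 1)
}

#' Quantile normalization
#'
#' Forces every column (sample) of a matrix onto a common distribution: the
#' value at each rank is replaced by the mean, across columns, of the values
#' at that rank. Tied values within a column receive the mean of the
#' rank-wise means over their tied ranks, making the transform deterministic.
#' Row and column names are preserved; within-column rank order is preserved.
#'
#' @param x numeric matrix (probes in rows, samples in columns), all finite.
#' @return Quantile-normalized matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) stop("matrix must be all finite", call. = FALSE)
  if (ncol(x) < 2L) {
    warning("quantile_normalize: fewer than 2 samples, returned unchanged")
    return(x)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # ties: average the rank-wise means over the tied ranks
    out[, j] <- stats::ave(assigned, col, FUN = mean)
  }
  out
}

#' Tukey median polish of a two-way table
#'
#' Additive decomposition value = overall + row effect + column effect +
#' residual by alternately sweeping row and column medians (rows first), the
#' summarization step of RMA. Wraps [stats::medpolish()].
#'
#' @param table numeric matrix (or object coercible to one), non-empty.
#' @param tol positive convergence tolerance on the total absolute residual.
#' @param max_iter maximum number of sweeps.
#' @return List with `overall` (scalar), `row_effects`, `col_effects` and
#'   `residuals`; their sum reconstructs the input exactly.
#' @export
median_polish <- function(table, tol = 1e-6, max_iter = 10L) {
  table <- as.matrix(table)
  if (length(table) == 0L) stop("median_polish: empty table", call. = FALSE)
  if (!is.numeric(table) || any(!is.finite(table)))
    stop("median_polish requires a finite numeric table", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  # max_iter caps the sweeps by contract; medpolish's non-convergence
  # warning would misreport that as a failure
  mp <- withCallingHandlers(
    stats::medpolish(table, eps = tol, maxiter = max_iter,
                     trace.iter = FALSE, na.rm = FALSE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(overall = mp$overall,
       row_effects = as.numeric(mp$row),
       col_effects = as.numeric(mp$col),
       residuals = unname(as.matrix(mp$residuals)))
}

#' Simplified RMA summarization of probe-level data
#'
#' Per-cohort stand-in for the RMA pipeline on summarized data: probe-level
#' intensities are log2-transformed, quantile-normalized across samples, and
#' each probeset is collapsed to one expression value per sample by median
#' polish (expression = overall + column effect). The exponential/Gaussian
#' background-correction step of full RMA is deliberately omitted; it
#' requires raw array-image data that summarized studies do not carry.
#'
#' @param probe_level either the list returned by [simulate_probe_level()]
#'   or a probe-by-sample matrix of strictly positive linear-scale
#'   intensities (use `probeset` to group its rows).
#' @param probeset factor/character mapping probe rows to probesets;
#'   defaults to `probe_level$probeset` for simulator output.
#' @param normalize logical; apply quantile normalization before
#'   summarization (default TRUE). Disable to obtain the pure additive-model
#'   summarization, e.g. when data were normalized upstream.
#' @return Probeset-by-sample matrix of log2 expression values.
#' @export
rma_summarize <- function(probe_level, probeset = NULL, normalize = TRUE) {
  if (is.list(probe_level) && !is.null(probe_level$intensity)) {
    if (is.null(probeset)) probeset <- probe_level$probeset
    probe_level <- probe_level$intensity
  }
  stopifnot(is.matrix(probe_level))
  if (is.null(probeset) || length(probeset) != nrow(probe_level))
    stop("probeset grouping must map every probe row", call. = FALSE)
  probeset <- factor(probeset, levels = unique(as.character(probeset)))
  if (any(probe_level <= 0))
    stop("probe-level intensities must be strictly positive", call. = FALSE)
  y <- log2(probe_level)
  if (normalize && ncol(y) >= 2L) y <- quantile_normalize(y)
  counts <- table(probeset)
  if (any(counts == 0L))
    stop(sprintf("empty probeset: %s",
                 paste(names(counts)[counts == 0L], collapse = ", ")),
         call. = FALSE)
  out <- matrix(NA_real_, nrow = nlevels(probeset), ncol = ncol(y),
                dimnames = list(levels(probeset), colnames(y)))
  idx <- split(seq_len(nrow(y)), probeset)
  for (ps in names(idx)) {
    block <- y[idx[[ps]], , drop = FALSE]
    if (nrow(block) == 1L) {
      out[ps, ] <- block[1L, ]
    } else {
      mp <- median_polish(block, tol = 1e-6, max_iter = 10L)
      out[ps, ] <- mp$overall + mp$col_effects
    }
  }
  out
}
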