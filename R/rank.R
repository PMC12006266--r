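#' Hedges-corrected standardized mean difference
#'
#' Effect size g = J * (mean_pos - mean_neg) / s_pooled with the small-sample
#' correction J = 1 - 3 / (4 (n_pos + n_neg - 2) - 1), and sampling variance
#' (n_pos + n_neg) / (n_pos n_neg) + g^2 / (2 (n_pos + n_neg)). This is the
#' per-cohort effect fed into the random-effects meta-analysis that ranks
#' probes.
#'
#' @param pos_values,neg_values numeric vectors (each of length >= 2) of
#'   expression values in the ctDNA-positive and ctDNA-negative group.
#' @return Object of class `"effect_estimate"`: `g`, `variance`, `n_pos`,
#'   `n_neg` and a `zero_sd` flag. When the pooled SD is zero, `g` is signed
#'   infinite, `variance` is `NA` and `zero_sd` is TRUE; such probes are
#'   excluded downstream.
#' @export
hedges_g <- function(pos_values, neg_values) {
  n1 <- length(pos_values); n0 <- length(neg_values)
  if (n1 < 2L || n0 < 2L)
    stop("hedges_g requires at least 2 values per group", call. = FALSE)
  m1 <- mean(pos_values); m0 <- mean(neg_values)
  sp2 <- ((n1 - 1) * stats::var(pos_values) +
          (n0 - 1) * stats::var(neg_values)) / (n1 + n0 - 2)
  J <- 1 - 3 / (4 * (n1 + n0 - 2) - 1)
  if (sp2 <= 0) {
    g <- sign(m1 - m0) * Inf
    est <- list(g = g, variance = NA_real_, n_pos = n1, n_neg = n0,
                zero_sd = TRUE)
  } else {
    g <- J * (m1 - m0) / sqrt(sp2)
    v <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
    est <- list(g = g, variance = v, n_pos = n1, n_neg = n0, zero_sd = FALSE)
  }
  structure(est, class = "effect_estimate")
}

# Vectorized Hedges g over all rows of a probe-by-sample matrix.
# Returns a data.frame with g, variance and zero_sd per probe.
hedges_g_rows <- function(x, labels) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(x[, pos, drop = FALSE])
  m0 <- rowMeans(x[, !pos, drop = FALSE])
  v1 <- rowSums((x[, pos, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((x[, !pos, drop = FALSE] - m0)^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  J <- 1 - 3 / (4 * (n1 + n0 - 2) - 1)
  zero <- sp2 <= 0
  g <- ifelse(zero, sign(m1 - m0) * Inf, J * (m1 - m0) / sqrt(pmax(sp2, .Machine$double.xmin)))
  v <- ifelse(zero, NA_real_, (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0)))
  data.frame(g = g, variance = v, zero_sd = zero, row.names = rownames(x))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Combines per-cohort effect estimates with the closed-form
#' DerSimonian-Laird estimator of the between-cohort variance tau^2:
#' fixed-effect weights w = 1/v give the heterogeneity statistic
#' Q = sum w (g - g_FE)^2; tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w));
#' random-effects weights w* = 1/(v + tau^2) give the combined effect, its
#' standard error (sum w*)^(-1/2), z = combined/se and a two-sided normal p.
#'
#' @param estimates list of [hedges_g()] results (or of lists with `g` and
#'   `variance`); all variances must be positive.
#' @param model `"DL"` (random effects, default) or `"FE"` (fixed-effect
#'   inverse variance, i.e. tau^2 forced to 0).
#' @return Object of class `"meta_result"`: `combined_effect`, `se`, `z`,
#'   `p`, `tau2`, `Q`, `k`.
#' @export
meta_dl <- function(estimates, model = c("DL", "FE")) {
  model <- match.arg(model)
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  g <- vapply(estimates, function(e) e$g, numeric(1))
  v <- vapply(estimates, function(e) e$variance, numeric(1))
  if (any(!is.finite(g)) || any(!is.finite(v)) || any(v <= 0))
    stop("all effects must be finite with positive variance", call. = FALSE)
  res <- meta_dl_rows(matrix(g, nrow = 1), matrix(v, nrow = 1), model = model)
  structure(list(combined_effect = res$combined_effect, se = res$se,
                 z = res$z, p = res$p, tau2 = res$tau2, Q = res$Q,
                 k = length(g)),
            class = "meta_result")
}

# Vectorized DL meta-analysis: G and V are probe-by-cohort matrices.
meta_dl_rows <- function(G, V, model = "DL") {
  k <- ncol(G)
  w <- 1 / V
  sw <- rowSums(w)
  g_fe <- rowSums(w * G) / sw
  Q <- rowSums(w * (G - g_fe)^2)
  if (model == "DL" && k > 1L) {
    denom <- sw - rowSums(w^2) / sw
    tau2 <- pmax(0, (Q - (k - 1)) / denom)
  } else {
    tau2 <- numeric(nrow(G))
  }
  wr <- 1 / (V + tau2)
  swr <- rowSums(wr)
  combined <- rowSums(wr * G) / swr
  se <- 1 / sqrt(swr)
  z <- combined / se
  data.frame(combined_effect = combined, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, Q = Q,
             row.names = rownames(G))
}

#' Meta-analytic candidate-probe ranking
#'
#' For every probe, computes a Hedges-g effect (ctDNA-positive vs -negative)
#' in each training cohort, combines the cohorts by DerSimonian-Laird
#' random-effects meta-analysis, and retains probes with two-sided p below
#' `alpha` (default 0.010), sorted by p ascending with ties broken by
#' |combined effect| descending then probe ID. Probes with zero pooled SD in
#' any cohort are dropped with a warning.
#'
#' @param training_cohorts list of `"cohort_study"` objects sharing the same
#'   probe set; every cohort needs >= 2 samples in each ctDNA class.
#' @param alpha candidate threshold on the meta-analytic p-value.
#' @param meta_model `"DL"` or `"FE"`, see [meta_dl()].
#' @return Object of class `"probe_ranking"`: `candidates` (data frame of
#'   retained probes with per-cohort g, combined_effect, tau2, Q, z, p,
#'   rank), `all` (the same statistics for every probe tested) and `alpha`.
#' @export
rank_candidate_probes <- function(training_cohorts, alpha = 0.010,
                                  meta_model = c("DL", "FE")) {
  meta_model <- match.arg(meta_model)
  if (length(training_cohorts) < 1L)
    stop("at least one training cohort is required", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  probe_ids <- rownames(training_cohorts[[1]]$expr)
  per_cohort <- lapply(training_cohorts, function(co) {
    z <- co$annotations$ctdna_status
    if (sum(z == 1L) < 2L || sum(z == 0L) < 2L)
      stop(sprintf("cohort '%s' has fewer than 2 samples in a ctDNA class",
                   co$cohort_label), call. = FALSE)
    if (!identical(rownames(co$expr), probe_ids))
      stop("cohorts must share an identical probe set", call. = FALSE)
    hedges_g_rows(co$expr, z)
  })
  G <- do.call(cbind, lapply(per_cohort, `[[`, "g"))
  V <- do.call(cbind, lapply(per_cohort, `[[`, "variance"))
  rownames(G) <- rownames(V) <- probe_ids
  bad <- Reduce(`|`, lapply(per_cohort, `[[`, "zero_sd"))
  if (any(bad)) {
    warning(sprintf("%d probe(s) with zero pooled SD dropped from ranking",
                    sum(bad)))
    G <- G[!bad, , drop = FALSE]; V <- V[!bad, , drop = FALSE]
  }
  meta <- meta_dl_rows(G, V, model = meta_model)
  colnames(G) <- sprintf("g_%s", vapply(training_cohorts, `[[`, "",
                                        "cohort_label"))
  tab <- data.frame(probe_id = rownames(G), G, meta, row.names = NULL,
                    stringsAsFactors = FALSE)
  ord <- order(tab$p, -abs(tab$combined_effect), tab$probe_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  candidates <- tab[tab$p < alpha, , drop = FALSE]
  if (nrow(candidates) > 0L) candidates$rank <- seq_len(nrow(candidates))
  structure(list(candidates = candidates, all = tab, alpha = alpha,
                 meta_model = meta_model),
            class = "probe_ranking")
}

#' @export
print.probe_ranking <- function(x, ...) {
  cat(sprintf("probe_ranking: %d candidate probes (p < %g) of %d tested [%s]\n",
              nrow(x$candidates), x$alpha, nrow(x$all), x$meta_model))
  invisible(x)
}
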