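#' Build a 2x2 contingency table of classifier calls vs ctDNA truth
#'
#' @param calls binary 0/1 classifier calls (1 = predicted positive).
#' @param truth binary 0/1 actual ctDNA detection status.
#' @return Object of class `"contingency_table"` with integer counts `tp`
#'   (call 1, truth 1), `fp` (call 1, truth 0), `fn` (call 0, truth 1) and
#'   `tn` (call 0, truth 0).
#' @export
contingency_table <- function(calls, truth) {
  calls <- as.integer(calls); truth <- as.integer(truth)
  if (length(calls) != length(truth) || length(calls) < 1L)
    stop("calls and truth must have equal length >= 1", call. = FALSE)
  if (!all(calls %in% 0:1) || !all(truth %in% 0:1))
    stop("calls and truth must be binary 0/1", call. = FALSE)
  structure(list(tp = sum(calls == 1L & truth == 1L),
                 fp = sum(calls == 1L & truth == 0L),
                 fn = sum(calls == 0L & truth == 1L),
                 tn = sum(calls == 0L & truth == 0L)),
            class = "contingency_table")
}

#' Diagnostic metrics of a 2x2 table
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value, all as percentages. Metrics whose denominator is zero (e.g. PPV
#' with no positive calls) are returned as `NA` rather than 0.
#'
#' @param ct a [contingency_table()] or a list with `tp`, `fp`, `fn`, `tn`.
#' @return Object of class `"diagnostic_metrics"`: `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` in [0, 100] (full precision;
#'   the print method rounds to one decimal).
#' @export
diagnostic_metrics <- function(ct) {
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  if (n < 1L) stop("empty contingency table", call. = FALSE)
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(accuracy = 100 * (ct$tp + ct$tn) / n,
                 sensitivity = frac(ct$tp, ct$tp + ct$fn),
                 specificity = frac(ct$tn, ct$tn + ct$fp),
                 ppv = frac(ct$tp, ct$tp + ct$fp),
                 npv = frac(ct$tn, ct$tn + ct$fn)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("%-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else
                  format(round(x[[m]], 1), nsmall = 1)))
  invisible(x)
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of counts with all row and column margins > 0.
#' @return List: `statistic` (chi-square with 1 df) and `p`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("pearson_chi2 requires all margins > 0", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test of a 2x2 table (two-sided)
#'
#' Two-sided p: the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table.
#'
#' @param table 2x2 matrix of non-negative counts, total >= 1.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0), sum(table) >= 1)
  stats::fisher.test(table)$p.value
}

#' Odds ratio with Woolf (log-normal) 95\% confidence interval
#'
#' For a 2x2 table whose first row is the reference exposure level, second
#' row the index level, and columns the ctDNA-negative / ctDNA-positive
#' outcome, returns the sample odds ratio of the index vs reference level,
#' OR = (d/c) / (b/a), with the Woolf interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) and a Wald p-value. Any
#' zero cell makes the maximum-likelihood OR degenerate; such tables are
#' returned with `separation = TRUE` and `NA` in place of the OR and CI.
#'
#' @param table 2x2 matrix of counts (rows: reference, index exposure;
#'   columns: outcome negative, positive).
#' @return Object of class `"association_result"`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `test_name`, `separation`.
#' @export
odds_ratio_woolf <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(table == 0)) {
    return(structure(list(odds_ratio = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          test_name = "woolf", separation = TRUE),
                     class = "association_result"))
  }
  or <- (d / c) / (b / a)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 test_name = "woolf", separation = FALSE),
            class = "association_result")
}

#' Logistic regression of ctDNA status on covariates
#'
#' Maximum-likelihood logistic fit (one column = univariate analysis, several
#' = multivariate). Per covariate: odds ratio, Wald 95\% CI, Wald and
#' likelihood-ratio p-values. Complete or quasi-complete separation (a
#' covariate perfectly predicting the outcome) makes the ML odds ratio
#' diverge; it is detected from fitted probabilities pinned at 0/1 together
#' with an exploding coefficient, and reported as a `separation` flag with
#' `NA` odds ratio rather than an astronomically large pseudo-number.
#'
#' @param covariates data frame (or matrix) of numeric/binary covariates.
#' @param outcome binary 0/1 outcome with both classes present;
#'   `length(outcome)` must exceed the number of covariates.
#' @return Data frame, one row per covariate: `term`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_wald`, `p_lrt`, `separation`.
#' @export
logistic_fit <- function(covariates, outcome) {
  covariates <- as.data.frame(covariates)
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L)
    stop("outcome must contain both classes", call. = FALSE)
  if (length(outcome) <= ncol(covariates))
    stop("need more samples than covariates", call. = FALSE)
  dat <- cbind(.outcome = outcome, covariates)
  fit <- suppressWarnings(stats::glm(.outcome ~ ., data = dat,
                                     family = stats::binomial()))
  sm <- summary(fit)$coefficients
  probs <- stats::fitted(fit)
  pinned <- any(probs < 1e-8 | probs > 1 - 1e-8)
  lrt <- tryCatch(suppressWarnings(stats::drop1(fit, test = "Chisq")),
                  error = function(e) NULL)
  out <- lapply(names(covariates), function(term) {
    row <- sm[rownames(sm) == term, , drop = FALSE]
    if (nrow(row) == 0L)  # dropped (e.g. constant covariate)
      return(data.frame(term = term, odds_ratio = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_wald = NA_real_,
                        p_lrt = NA_real_, separation = FALSE))
    beta <- row[1, 1]; se <- row[1, 2]
    sep <- pinned && (abs(beta) > 10 || se > 50)
    p_lrt <- if (!is.null(lrt) && term %in% rownames(lrt))
      lrt[term, "Pr(>Chi)"] else NA_real_
    data.frame(term = term,
               odds_ratio = if (sep) NA_real_ else exp(beta),
               ci_low = if (sep) NA_real_ else exp(beta - 1.96 * se),
               ci_high = if (sep) NA_real_ else exp(beta + 1.96 * se),
               p_wald = if (sep) NA_real_ else row[1, 4],
               p_lrt = p_lrt,
               separation = sep)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Leaf ordering of hierarchically clustered rows and columns
#'
#' Average-linkage agglomerative clustering of the rows and of the columns of
#' an expression matrix, as used to arrange clustered heat maps. Distances
#' are Euclidean or 1 - Pearson correlation.
#'
#' @param x numeric matrix with >= 2 rows and columns (fewer: identity
#'   order is returned for that dimension).
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage agglomeration method; only `"average"` is offered.
#' @return List with integer vectors `rows` and `cols` (leaf orders).
#' @export
cluster_order <- function(x, distance = c("euclidean", "correlation"),
                          linkage = "average") {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, "average")
  stopifnot(is.matrix(x))
  dfun <- function(m) {
    if (distance == "euclidean") stats::dist(m)
    else stats::as.dist(1 - stats::cor(t(m)))
  }
  ord <- function(m) {
    if (nrow(m) < 2L) return(seq_len(nrow(m)))
    stats::hclust(dfun(m), method = linkage)$order
  }
  list(rows = ord(x), cols = ord(t(x)))
}
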