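#' SVM configuration
#'
#' Hyperparameters of the linear support-vector machine used throughout the
#' wrapper selection: linear kernel, soft-margin cost, and class weighting
#' (`"balanced"` reweights classes inversely to their frequency, guarding
#' against the strong class imbalance of ctDNA studies).
#'
#' @param kernel only `"linear"` is supported.
#' @param cost positive soft-margin cost.
#' @param class_weight `"balanced"` (default) or `"uniform"`.
#' @return Object of class `"svm_config"`.
#' @export
svm_config <- function(kernel = "linear", cost = 1.0,
                       class_weight = c("balanced", "uniform")) {
  kernel <- match.arg(kernel)
  class_weight <- match.arg(class_weight)
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  structure(list(kernel = kernel, cost = cost, class_weight = class_weight),
            class = "svm_config")
}

#' Per-cohort probe standardization
#'
#' Centers every probe to mean 0 and scales to SD 1 within a cohort, the
#' minimal cross-cohort alignment needed before a classifier trained on one
#' set of cohorts is applied to another processed with different reagents.
#' Constant (zero-SD) probes are set to 0 and flagged.
#'
#' @param x probe-by-sample numeric matrix with >= 2 samples.
#' @return List: `values` (standardized matrix), `center`, `scale` (per-probe
#'   parameters; scale is 1 for flagged probes) and logical `zero_sd`.
#' @export
standardize_per_cohort <- function(x) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("standardization needs >= 2 samples", call. = FALSE)
  ctr <- rowMeans(x)
  sds <- sqrt(rowSums((x - ctr)^2) / (ncol(x) - 1))
  zero <- sds <= 0
  scl <- ifelse(zero, 1, sds)
  vals <- (x - ctr) / scl
  vals[zero, ] <- 0
  list(values = vals, center = ctr, scale = scl, zero_sd = zero)
}

fit_linear_svm <- function(x, y, svm) {
  y <- factor(y, levels = c(0L, 1L))
  cw <- if (svm$class_weight == "balanced") {
    n <- length(y)
    tab <- table(y)
    stats::setNames(n / (2 * as.numeric(tab)), names(tab))
  } else NULL
  e1071::svm(x = x, y = y, type = "C-classification", kernel = "linear",
             cost = svm$cost, scale = FALSE, class.weights = cw)
}

# Extract (w, b) such that f(x) = x %*% w + b is positive for class "1".
linear_rule <- function(fit, x_train) {
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(x_train %*% w) + b
  pred <- stats::predict(fit, x_train)
  agree <- mean((f > 0) == (pred == "1"))
  if (is.finite(agree) && agree < 0.5) { w <- -w; b <- -b }
  list(weights = w, intercept = b)
}

#' Leave-one-out cross-validated SVM accuracy
#'
#' For each sample, fits the SVM on the remaining n - 1 samples and predicts
#' the held-out one. Feature standardization (center/scale) is refit inside
#' every fold so that no information leaks from the held-out sample. A fold
#' whose training part degenerates to a single class predicts that class.
#'
#' @param features sample-by-probe numeric matrix (n >= 3).
#' @param labels binary 0/1 vector with both classes present.
#' @param svm an [svm_config()].
#' @return List: `accuracy` (fraction of correct held-out predictions) and
#'   `predictions` (integer 0/1 per sample).
#' @export
loocv_accuracy <- function(features, labels, svm = svm_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- as.integer(labels)
  if (n < 3L) stop("LOOCV needs at least 3 samples", call. = FALSE)
  if (length(labels) != n) stop("labels must match rows", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  preds <- integer(n)
  for (i in seq_len(n)) {
    xtr <- features[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2L) {
      preds[i] <- ytr[1L]
      next
    }
    ctr <- colMeans(xtr)
    sds <- apply(xtr, 2L, stats::sd)
    sds[sds <= 0] <- 1
    xtr_s <- sweep(sweep(xtr, 2L, ctr), 2L, sds, "/")
    xte_s <- (features[i, ] - ctr) / sds
    fit <- fit_linear_svm(xtr_s, ytr, svm)
    preds[i] <- as.integer(as.character(
      stats::predict(fit, matrix(xte_s, nrow = 1L))))
  }
  list(accuracy = mean(preds == labels), predictions = preds)
}

# Pool per-cohort-standardized expression of several cohorts into a
# sample-by-probe matrix plus a label vector.
pool_training <- function(cohorts) {
  mats <- lapply(cohorts, function(co) t(standardize_per_cohort(co$expr)$values))
  x <- do.call(rbind, mats)
  labels <- unlist(lapply(cohorts, function(co) co$annotations$ctdna_status),
                   use.names = FALSE)
  rownames(x) <- unlist(lapply(cohorts,
                               function(co) co$annotations$sample_id),
                        use.names = FALSE)
  list(x = x, labels = as.integer(labels))
}

#' Sequential forward feature selection of the ctDNA classifier
#'
#' Greedy wrapper selection over the meta-analytically ranked candidate
#' probes: candidates are visited in rank order, each is tentatively added to
#' the current probe set, the LOOCV accuracy of the linear SVM on the pooled
#' (per-cohort standardized) training samples is computed, and the candidate
#' is kept only if accuracy strictly increases. Selection stops when LOOCV
#' accuracy reaches 1, candidates are exhausted, or `max_probes` have been
#' accepted. The final decision rule is refit on all training samples with
#' the accepted probes.
#'
#' @param ranking a [rank_candidate_probes()] result with >= 1 candidate.
#' @param training_cohorts list of `"cohort_study"` objects pooled for
#'   selection; must jointly contain both ctDNA classes.
#' @param svm an [svm_config()].
#' @param max_probes maximum number of probes accepted (default unlimited).
#' @return Object of class `"ctdna_classifier"`: `selected_probe_ids`,
#'   `standardization` (pooled per-probe center/scale applied after
#'   per-cohort standardization), `decision_rule` (linear weights +
#'   intercept, NULL when no probe was accepted), `loocv_trace` (data frame:
#'   probe_id, accepted, accuracy), `loocv_accuracy`, `training_accuracy`,
#'   `majority_class` and the `svm` configuration.
#' @export
sequential_forward_select <- function(ranking, training_cohorts,
                                      svm = svm_config(), max_probes = Inf) {
  if (!inherits(ranking, "probe_ranking") || nrow(ranking$candidates) == 0L)
    stop("ranking must contain at least one candidate probe", call. = FALSE)
  pooled <- pool_training(training_cohorts)
  labels <- pooled$labels
  if (length(unique(labels)) < 2L)
    stop("pooled training samples must contain both classes", call. = FALSE)
  majority <- as.integer(mean(labels) >= 0.5)
  best_acc <- mean(labels == majority)  # no-feature baseline
  selected <- character(0)
  trace <- list()
  for (probe in ranking$candidates$probe_id) {
    if (length(selected) >= max_probes || best_acc >= 1) break
    acc <- loocv_accuracy(pooled$x[, c(selected, probe), drop = FALSE],
                          labels, svm)$accuracy
    accepted <- acc > best_acc
    trace[[length(trace) + 1L]] <- data.frame(
      probe_id = probe, accepted = accepted,
      accuracy = if (accepted) acc else best_acc,
      stringsAsFactors = FALSE)
    if (accepted) {
      selected <- c(selected, probe)
      best_acc <- acc
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(probe_id = character(0), accepted = logical(0),
               accuracy = numeric(0))
  acc_steps <- trace$accuracy[trace$accepted]
  stopifnot(!is.unsorted(acc_steps, strictly = TRUE))

  if (length(selected) > 0L) {
    xsel <- pooled$x[, selected, drop = FALSE]
    ctr <- colMeans(xsel)
    sds <- apply(xsel, 2L, stats::sd)
    sds[sds <= 0] <- 1
    xs <- sweep(sweep(xsel, 2L, ctr), 2L, sds, "/")
    fit <- fit_linear_svm(xs, labels, svm)
    rule <- linear_rule(fit, xs)
    names(rule$weights) <- selected
    fitted_calls <- as.integer(drop(xs %*% rule$weights) + rule$intercept > 0)
    standardization <- list(center = ctr, scale = sds)
  } else {
    rule <- NULL
    fitted_calls <- rep(majority, length(labels))
    standardization <- NULL
  }
  structure(list(selected_probe_ids = selected,
                 standardization = standardization,
                 decision_rule = rule,
                 loocv_trace = trace,
                 loocv_accuracy = best_acc,
                 training_accuracy = mean(fitted_calls == labels),
                 training_calls = stats::setNames(fitted_calls,
                                                  rownames(pooled$x)),
                 majority_class = majority,
                 svm = svm),
            class = "ctdna_classifier")
}

#' @export
print.ctdna_classifier <- function(x, ...) {
  cat(sprintf(paste0("ctdna_classifier: %d probes selected, LOOCV accuracy ",
                     "%.3f, training accuracy %.3f\n"),
              length(x$selected_probe_ids), x$loocv_accuracy,
              x$training_accuracy))
  invisible(x)
}

#' Apply the classifier to a cohort
#'
#' The new cohort is standardized with its own per-cohort parameters (each
#' probe centered/scaled within the cohort), the training-time pooled
#' standardization is applied to the selected probes, and the linear decision
#' rule is evaluated; a sample is called positive when the decision value is
#' strictly greater than 0 (exact ties resolve to the negative, majority,
#' call).
#'
#' @param object a `"ctdna_classifier"`.
#' @param cohort a `"cohort_study"` or a probe-by-sample matrix containing
#'   every selected probe.
#' @param ... unused.
#' @return Named integer vector of 0/1 calls (1 = predicted ctDNA-positive)
#'   with the numeric decision values as attribute `"decision"`.
#' @export
predict.ctdna_classifier <- function(object, cohort, ...) {
  expr <- if (inherits(cohort, "cohort_study")) cohort$expr else cohort
  stopifnot(is.matrix(expr))
  if (is.null(object$decision_rule)) {
    calls <- rep(object$majority_class, ncol(expr))
    names(calls) <- colnames(expr)
    attr(calls, "decision") <- rep(0, ncol(expr))
    return(calls)
  }
  sel <- object$selected_probe_ids
  missing <- setdiff(sel, rownames(expr))
  if (length(missing) > 0L)
    stop(sprintf("cohort is missing selected probe(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  std <- standardize_per_cohort(expr)
  x <- t(std$values)[, sel, drop = FALSE]
  x <- sweep(sweep(x, 2L, object$standardization$center), 2L,
             object$standardization$scale, "/")
  f <- drop(x %*% object$decision_rule$weights) + object$decision_rule$intercept
  calls <- stats::setNames(as.integer(f > 0), colnames(expr))
  attr(calls, "decision") <- f
  calls
}
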