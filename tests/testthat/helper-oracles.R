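# Independent reference implementations used to cross-check the package.
# Each oracle is coded directly from the defining formula, not from the
# package's own code path.

# DerSimonian-Laird random-effects combination, scalar form.
oracle_dl <- function(g, v) {
  w <- 1 / v
  gfe <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gfe)^2)
  k <- length(g)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wr <- 1 / (v + tau2)
  comb <- sum(wr * g) / sum(wr)
  se <- 1 / sqrt(sum(wr))
  z <- comb / se
  list(combined = comb, se = se, z = z, p = 2 * pnorm(-abs(z)),
       tau2 = tau2, Q = Q)
}

# Quantile normalization by explicit sort / average / reassign (no ties).
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- ref
  out
}

# Median polish by explicit alternating sweeps, absolute-change stopping.
oracle_median_polish <- function(x, tol = 1e-10, max_iter = 100) {
  overall <- 0
  r <- numeric(nrow(x)); cc <- numeric(ncol(x))
  res <- x
  prev <- sum(abs(res))
  for (it in seq_len(max_iter)) {
    rm <- apply(res, 1, median)
    r <- r + rm; res <- res - rm
    cm_r <- median(cc)
    overall <- overall + cm_r; cc <- cc - cm_r
    cm <- apply(res, 2, median)
    cc <- cc + cm; res <- sweep(res, 2, cm)
    rm_c <- median(r)
    overall <- overall + rm_c; r <- r - rm_c
    cur <- sum(abs(res))
    if (abs(prev - cur) <= tol) break
    prev <- cur
  }
  list(overall = overall, row_effects = r, col_effects = cc, residuals = res)
}

# Two-sided Fisher exact p by full enumeration over tables with fixed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank chi-square via explicit O-E / hypergeometric-variance sums.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# Upper-tail hypergeometric P(X >= k) by direct summation.
oracle_hyper_upper <- function(k, pop_hits, pop_total, draws) {
  kk <- k:min(pop_hits, draws)
  if (k > min(pop_hits, draws)) return(0)
  sum(dhyper(kk, pop_hits, pop_total - pop_hits, draws))
}

# Naive LOOCV: refit an e1071 linear SVM per fold with manual scaling.
oracle_loocv <- function(x, y, cost = 1, balanced = TRUE) {
  n <- nrow(x)
  preds <- integer(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    ctr <- colMeans(xtr); s <- apply(xtr, 2, sd); s[s <= 0] <- 1
    xs <- scale(xtr, center = ctr, scale = s)
    cw <- if (balanced) {
      tb <- table(factor(ytr, levels = c(0, 1)))
      setNames(length(ytr) / (2 * as.numeric(tb)), names(tb))
    } else NULL
    fit <- e1071::svm(x = xs, y = factor(ytr, levels = c(0, 1)),
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE, class.weights = cw)
    xt <- matrix((x[i, ] - ctr) / s, nrow = 1)
    preds[i] <- as.integer(as.character(predict(fit, xt)))
  }
  list(accuracy = mean(preds == y), predictions = preds)
}

# Small default-shaped simulation for fast tests.
small_config <- function(seed = 1, ...) {
  simulation_config(n_probes = 300, n_de_probes = 12, n_up = 7,
                    seed = seed, ...)
}
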