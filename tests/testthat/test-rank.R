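test_that("hedges_g matches the hand-computed arithmetic example", {
  est <- hedges_g(c(2, 3, 4), c(0, 1, 2))
  expect_equal(est$g, 1.6)
  expect_equal(est$variance, 6 / 9 + 1.6^2 / 12)
  expect_identical(est$n_pos, 3L)
  expect_identical(est$n_neg, 3L)
})

test_that("hedges_g is antisymmetric and null on identical groups", {
  set.seed(1)
  a <- rnorm(8); b <- rnorm(6, 1)
  e1 <- hedges_g(a, b); e2 <- hedges_g(b, a)
  expect_equal(e1$g, -e2$g)
  expect_equal(e1$variance, e2$variance)
  e0 <- hedges_g(a, a)
  expect_equal(e0$g, 0)
  expect_equal(e0$variance, (8 + 8) / (8 * 8))
})

test_that("hedges_g guards group sizes and zero pooled SD", {
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
  est <- hedges_g(c(2, 2, 2), c(1, 1, 1))
  expect_true(est$zero_sd)
  expect_true(is.infinite(est$g))
})

test_that("vectorized per-probe effects equal the scalar computation", {
  set.seed(2)
  x <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("p", 1:10), NULL))
  z <- rep(c(1L, 0L), c(5L, 7L))
  rows <- ctdnasig:::hedges_g_rows(x, z)
  for (i in 1:10) {
    e <- hedges_g(x[i, z == 1], x[i, z == 0])
    expect_equal(rows$g[i], e$g)
    expect_equal(rows$variance[i], e$variance)
  }
})

test_that("meta_dl degenerate cases: k=1 and identical estimates", {
  e <- list(g = 0.7, variance = 0.09)
  m1 <- meta_dl(list(e))
  expect_equal(m1$combined_effect, 0.7)
  expect_equal(m1$se, 0.3)
  expect_equal(m1$tau2, 0)
  expect_equal(m1$Q, 0)
  expect_equal(m1$p, 2 * pnorm(-abs(0.7 / 0.3)))

  m2 <- meta_dl(list(e, e))
  expect_equal(m2$tau2, 0)
  expect_equal(m2$combined_effect, 0.7)
  expect_equal(m2$se, sqrt(0.09 / 2))
})

test_that("meta_dl agrees with an independent DL implementation", {
  g <- c(1.0, 0.2); v <- c(0.2, 0.2)
  m <- meta_dl(list(list(g = g[1], variance = v[1]),
                    list(g = g[2], variance = v[2])))
  o <- oracle_dl(g, v)
  expect_equal(m$combined_effect, o$combined, tolerance = 1e-10)
  expect_equal(m$tau2, o$tau2, tolerance = 1e-10)
  expect_equal(m$p, o$p, tolerance = 1e-10)
  expect_equal(m$Q, o$Q, tolerance = 1e-10)

  set.seed(3)
  for (i in 1:10) {
    g <- rnorm(3); v <- runif(3, 0.05, 0.5)
    m <- meta_dl(lapply(1:3, function(j) list(g = g[j], variance = v[j])))
    o <- oracle_dl(g, v)
    expect_equal(m$combined_effect, o$combined, tolerance = 1e-10)
    expect_equal(m$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(m$se, o$se, tolerance = 1e-10)
  }
})

test_that("meta_dl agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(4)
  g <- rnorm(4, 0.5); v <- runif(4, 0.05, 0.4)
  m <- meta_dl(lapply(1:4, function(j) list(g = g[j], variance = v[j])))
  rma <- suppressWarnings(metafor::rma(yi = g, vi = v, method = "DL"))
  expect_equal(m$combined_effect, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(m$tau2, rma$tau2, tolerance = 1e-8)
  expect_equal(m$se, rma$se, tolerance = 1e-8)
  expect_equal(m$p, rma$pval, tolerance = 1e-8)
})

test_that("meta_dl rejects empty and degenerate inputs", {
  expect_error(meta_dl(list()), "no estimates")
  expect_error(meta_dl(list(list(g = 1, variance = 0))), "positive variance")
})

test_that("candidate ranking retains p < alpha, sorted with stated tie-breaks", {
  sim <- simulate_study(small_config(seed = 7, effect_size = 2.5))
  rk <- rank_candidate_probes(sim$cohorts[1:2])
  expect_s3_class(rk, "probe_ranking")
  expect_true(all(rk$candidates$p < 0.010))
  expect_false(is.unsorted(rk$candidates$p))
  expect_identical(rk$candidates$rank, seq_len(nrow(rk$candidates)))
  # default threshold
  expect_equal(rk$alpha, 0.010)
  # probes not retained all have p >= alpha
  rest <- setdiff(rk$all$probe_id, rk$candidates$probe_id)
  expect_true(all(rk$all$p[rk$all$probe_id %in% rest] >= 0.010))
})

test_that("ranking is invariant to sample and probe order", {
  sim <- simulate_study(small_config(seed = 8, effect_size = 2))
  cohorts <- sim$cohorts[1:2]
  rk1 <- rank_candidate_probes(cohorts)
  shuffled <- lapply(cohorts, function(co) {
    set.seed(99)
    ps <- sample(nrow(co$expr)); ss <- sample(ncol(co$expr))
    ctdnasig:::new_cohort_study(co$expr[ps, ss],
                                co$annotations[ss, , drop = FALSE],
                                co$cohort_label)
  })
  # realign probe order across cohorts (they must share the probe set)
  probe_order <- rownames(shuffled[[1]]$expr)
  shuffled[[2]]$expr <- shuffled[[2]]$expr[probe_order, ]
  rk2 <- rank_candidate_probes(shuffled)
  expect_identical(rk1$candidates$probe_id, rk2$candidates$probe_id)
  expect_equal(rk1$candidates$p, rk2$candidates$p)
})

test_that("lowering alpha never adds candidate probes", {
  sim <- simulate_study(small_config(seed = 9, effect_size = 2))
  rk_hi <- rank_candidate_probes(sim$cohorts[1:2], alpha = 0.05)
  rk_lo <- rank_candidate_probes(sim$cohorts[1:2], alpha = 0.010)
  rk_lower <- rank_candidate_probes(sim$cohorts[1:2], alpha = 0.001)
  expect_true(all(rk_lo$candidates$probe_id %in% rk_hi$candidates$probe_id))
  expect_true(all(rk_lower$candidates$probe_id %in% rk_lo$candidates$probe_id))
})

test_that("ranking errors on undersized classes and drops constant probes", {
  sim <- simulate_study(simulation_config(cohort_sizes = c(10, 6, 4),
                                          ctdna_positive_counts = c(3, 1, 1),
                                          n_probes = 50, n_de_probes = 0,
                                          n_up = 0, seed = 10))
  expect_error(rank_candidate_probes(sim$cohorts[1:2]), "cohort_2")
  co <- sim$cohorts[[1]]
  co$expr[5, ] <- 4  # constant probe
  expect_warning(rk <- rank_candidate_probes(list(co)), "zero pooled SD")
  expect_false(rownames(sim$cohorts[[1]]$expr)[5] %in% rk$all$probe_id)
})

test_that("planted probes dominate the top of the ranking", {
  # 20 strongly differential probes among nulls, default cohort sizes
  top_frac <- vapply(1:5, function(s) {
    sim <- simulate_study(simulation_config(n_probes = 520, n_de_probes = 20,
                                            n_up = 10, effect_size = 2,
                                            seed = s))
    rk <- rank_candidate_probes(sim$cohorts[1:2], meta_model = "FE")
    mean(sim$truth$de_probe_ids %in%
           rk$candidates$probe_id[seq_len(min(30, nrow(rk$candidates)))])
  }, numeric(1))
  expect_gte(median(top_frac), 0.9)
})
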