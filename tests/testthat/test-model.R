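test_that("per-cohort standardization centers, scales and is idempotent", {
  set.seed(1)
  x <- matrix(rnorm(8 * 10, mean = 6, sd = 2), 8, 10,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:10)))
  s <- standardize_per_cohort(x)
  expect_lt(max(abs(rowMeans(s$values))), 1e-12)
  expect_equal(apply(s$values, 1, sd), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  s2 <- standardize_per_cohort(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
})

test_that("constant probes standardize to zero and are flagged", {
  x <- rbind(const = rep(3, 6), live = rnorm(6))
  s <- standardize_per_cohort(x)
  expect_true(s$zero_sd["const"])
  expect_false(s$zero_sd["live"])
  expect_equal(unname(s$values["const", ]), rep(0, 6))
})

test_that("LOOCV is perfect on widely separated classes", {
  set.seed(2)
  y <- rep(c(0L, 1L), each = 5)
  x <- matrix(rnorm(10, mean = ifelse(y == 1, 10, -10), sd = 0.1), ncol = 1)
  res <- loocv_accuracy(x, y)
  expect_equal(res$accuracy, 1.0)
  expect_identical(res$predictions, y)
})

test_that("LOOCV equals a naive fold-by-fold refit", {
  set.seed(3)
  x <- matrix(rnorm(8 * 3), 8, 3)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L)
  mine <- loocv_accuracy(x, y)
  ref <- oracle_loocv(x, y)
  expect_identical(mine$predictions, ref$predictions)
  expect_equal(mine$accuracy, ref$accuracy)
  # and with uniform class weights
  mine_u <- loocv_accuracy(x, y, svm_config(class_weight = "uniform"))
  ref_u <- oracle_loocv(x, y, balanced = FALSE)
  expect_identical(mine_u$predictions, ref_u$predictions)
})

test_that("null-feature LOOCV accuracy tracks the majority fraction", {
  acc <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(20 * 3), 20, 3)
    loocv_accuracy(x, rep(c(0L, 1L), each = 10))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
})

test_that("LOOCV input contracts are enforced", {
  x <- matrix(rnorm(6), ncol = 2)
  expect_error(loocv_accuracy(x, c(1L, 1L, 1L)), "both classes")
  expect_error(loocv_accuracy(x[1:2, , drop = FALSE], c(0L, 1L)),
               "at least 3")
})

test_that("forward selection stops at a single perfectly separating probe", {
  sim <- simulate_study(small_config(seed = 4, effect_size = 0))
  cohorts <- sim$cohorts[1:2]
  # plant one huge-margin probe
  for (i in 1:2) {
    z <- cohorts[[i]]$annotations$ctdna_status
    cohorts[[i]]$expr["probe_00001", ] <- ifelse(z == 1, 50, -50) +
      rnorm(length(z), sd = 0.01)
  }
  rk <- rank_candidate_probes(cohorts)
  expect_identical(rk$candidates$probe_id[1], "probe_00001")
  m <- sequential_forward_select(rk, cohorts)
  expect_identical(m$selected_probe_ids, "probe_00001")
  expect_equal(m$loocv_accuracy, 1.0)
  expect_equal(m$training_accuracy, 1.0)
})

test_that("accepted-step LOOCV accuracies increase strictly", {
  sim <- simulate_study(small_config(seed = 5, effect_size = 1.2))
  rk <- rank_candidate_probes(sim$cohorts[1:2], alpha = 0.05)
  m <- sequential_forward_select(rk, sim$cohorts[1:2])
  steps <- m$loocv_trace$accuracy[m$loocv_trace$accepted]
  if (length(steps) > 1) expect_true(all(diff(steps) > 0))
  expect_true(all(m$selected_probe_ids %in% rk$candidates$probe_id))
  # acceptance order follows candidate rank order
  expect_identical(m$selected_probe_ids,
                   rk$candidates$probe_id[rk$candidates$probe_id %in%
                                            m$selected_probe_ids])
})

test_that("forward selection equals an exhaustive greedy reimplementation", {
  sim <- simulate_study(simulation_config(cohort_sizes = c(16, 8, 4),
                                          ctdna_positive_counts = c(6, 3, 1),
                                          n_probes = 40, n_de_probes = 4,
                                          n_up = 2, effect_size = 1.8,
                                          seed = 6))
  cohorts <- sim$cohorts[1:2]
  rk <- rank_candidate_probes(cohorts, alpha = 0.2)
  m <- sequential_forward_select(rk, cohorts)

  # independent greedy pass over the same candidate order
  pool_x <- do.call(rbind, lapply(cohorts, function(co)
    scale(t(co$expr))))
  labels <- unlist(lapply(cohorts, function(co) co$annotations$ctdna_status))
  maj <- as.integer(mean(labels) >= 0.5)
  best <- mean(labels == maj); sel <- character(0)
  for (pr in rk$candidates$probe_id) {
    if (best >= 1) break
    acc <- oracle_loocv(pool_x[, c(sel, pr), drop = FALSE], labels)$accuracy
    if (acc > best) { best <- acc; sel <- c(sel, pr) }
  }
  expect_identical(m$selected_probe_ids, sel)
  expect_equal(m$loocv_accuracy, best)
})

test_that("max_probes = 0 degrades to the majority-class rule", {
  sim <- simulate_study(small_config(seed = 7))
  rk <- rank_candidate_probes(sim$cohorts[1:2])
  m <- sequential_forward_select(rk, sim$cohorts[1:2], max_probes = 0)
  expect_length(m$selected_probe_ids, 0L)
  expect_null(m$decision_rule)
  calls <- predict(m, sim$cohorts[[3]])
  expect_true(all(calls == m$majority_class))
})

test_that("selection is deterministic given data and configuration", {
  sim <- simulate_study(small_config(seed = 8, effect_size = 2))
  rk <- rank_candidate_probes(sim$cohorts[1:2])
  m1 <- sequential_forward_select(rk, sim$cohorts[1:2])
  m2 <- sequential_forward_select(rk, sim$cohorts[1:2])
  expect_identical(m1$selected_probe_ids, m2$selected_probe_ids)
  expect_equal(m1$decision_rule, m2$decision_rule)
})

test_that("prediction on the training cohort equals the fitted calls", {
  sim <- simulate_study(simulation_config(cohort_sizes = c(20, 8),
                                          ctdna_positive_counts = c(7, 1),
                                          n_probes = 200, n_de_probes = 8,
                                          n_up = 4, effect_size = 2.5,
                                          seed = 9))
  train <- sim$cohorts[1]  # single training cohort
  rk <- rank_candidate_probes(train, alpha = 0.05)
  m <- sequential_forward_select(rk, train)
  calls <- predict(m, sim$cohorts[[1]])
  expect_identical(as.integer(calls), as.integer(m$training_calls))
})

test_that("negating the decision rule flips every non-tied call", {
  sim <- simulate_study(small_config(seed = 10, effect_size = 2))
  rk <- rank_candidate_probes(sim$cohorts[1:2])
  m <- sequential_forward_select(rk, sim$cohorts[1:2])
  flipped <- m
  flipped$decision_rule$weights <- -m$decision_rule$weights
  flipped$decision_rule$intercept <- -m$decision_rule$intercept
  c1 <- predict(m, sim$cohorts[[3]])
  c2 <- predict(flipped, sim$cohorts[[3]])
  d <- attr(c1, "decision")
  expect_identical(unname(c2[d != 0]), unname(1L - c1[d != 0]))
})

test_that("prediction errors when selected probes are missing", {
  sim <- simulate_study(small_config(seed = 11, effect_size = 2))
  rk <- rank_candidate_probes(sim$cohorts[1:2])
  m <- sequential_forward_select(rk, sim$cohorts[1:2])
  val <- sim$cohorts[[3]]$expr
  val <- val[setdiff(rownames(val), m$selected_probe_ids[1]), ]
  expect_error(predict(m, val), m$selected_probe_ids[1])
})

test_that("validation calls beat chance on planted synthetic cohorts", {
  youden <- vapply(1:5, function(s) {
    sim <- simulate_study(simulation_config(seed = s, effect_size = 2,
                                            n_probes = 1000,
                                            n_de_probes = 30, n_up = 18))
    rk <- rank_candidate_probes(sim$cohorts[1:2], meta_model = "FE")
    m <- sequential_forward_select(rk, sim$cohorts[1:2])
    calls <- predict(m, sim$cohorts[[3]])
    truth <- sim$cohorts[[3]]$annotations$ctdna_status
    met <- diagnostic_metrics(contingency_table(calls, truth))
    (met$sensitivity + met$specificity) / 100
  }, numeric(1))
  expect_gt(median(youden), 1)
})
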