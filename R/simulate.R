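#' Configuration for the multi-cohort study simulator
#'
#' Defines the shape of a simulated ctDNA-detectability expression study:
#' three Affymetrix-style cohorts (two training, one validation) with known
#' planted differential probes, per-cohort batch shifts, clinicopathological
#' covariates and right-censored recurrence-free survival.
#'
#' @param cohort_sizes integer vector of samples per cohort.
#' @param ctdna_positive_counts integer vector, ctDNA-positive samples per
#'   cohort; each entry must not exceed the matching cohort size.
#' @param n_probes total number of probes simulated.
#' @param n_de_probes number of truly differential probes (\eqn{\le} n_probes).
#' @param n_up number of differential probes up-regulated in ctDNA-positive
#'   samples; the remaining n_de_probes - n_up are down-regulated.
#' @param effect_size planted standardized mean difference (log2 units per
#'   residual SD) between ctDNA-positive and ctDNA-negative samples.
#' @param batch_shift_sd SD of the per-cohort additive offset (log2 units).
#' @param noise_sd residual SD of log2 intensities.
#' @param probes_per_probeset probes per probeset for the probe-level
#'   simulator ([simulate_probe_level()]).
#' @param survival_hazard_ratio recurrence hazard multiplier for
#'   ctDNA-positive samples.
#' @param baseline_hazard exponential baseline recurrence hazard per month
#'   for ctDNA-negative samples.
#' @param censoring_rate fraction in [0, 1): probability of additional early
#'   drop-out censoring on top of uniform administrative censoring.
#' @param followup_range administrative follow-up window in months; each
#'   subject's administrative censoring time is uniform on this interval.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical simulations.
#'
#' @return An object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(cohort_sizes = c(25L, 10L, 13L),
                              ctdna_positive_counts = c(7L, 3L, 1L),
                              n_probes = 5000L,
                              n_de_probes = 126L,
                              n_up = 70L,
                              effect_size = 1.5,
                              batch_shift_sd = 0.5,
                              noise_sd = 1.0,
                              probes_per_probeset = 11L,
                              survival_hazard_ratio = 3.0,
                              baseline_hazard = 0.0015,
                              censoring_rate = 0.1,
                              followup_range = c(10, 147),
                              seed = 1L) {
  cfg <- list(
    cohort_sizes = as.integer(cohort_sizes),
    ctdna_positive_counts = as.integer(ctdna_positive_counts),
    n_probes = as.integer(n_probes),
    n_de_probes = as.integer(n_de_probes),
    n_up = as.integer(n_up),
    effect_size = as.numeric(effect_size),
    batch_shift_sd = as.numeric(batch_shift_sd),
    noise_sd = as.numeric(noise_sd),
    probes_per_probeset = as.integer(probes_per_probeset),
    survival_hazard_ratio = as.numeric(survival_hazard_ratio),
    baseline_hazard = as.numeric(baseline_hazard),
    censoring_rate = as.numeric(censoring_rate),
    followup_range = as.numeric(followup_range),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$cohort_sizes) < 1L || any(cfg$cohort_sizes < 1L))
    stop("cohort_sizes must be positive integers", call. = FALSE)
  if (length(cfg$ctdna_positive_counts) != length(cfg$cohort_sizes))
    stop("ctdna_positive_counts must have one entry per cohort", call. = FALSE)
  if (any(cfg$ctdna_positive_counts < 0L) ||
      any(cfg$ctdna_positive_counts > cfg$cohort_sizes))
    stop("each ctdna_positive_counts[i] must lie in [0, cohort_sizes[i]]",
         call. = FALSE)
  if (cfg$n_probes < 1L) stop("n_probes must be positive", call. = FALSE)
  if (cfg$n_de_probes < 0L || cfg$n_de_probes > cfg$n_probes)
    stop("n_de_probes must lie in [0, n_probes]", call. = FALSE)
  if (cfg$n_up < 0L || cfg$n_up > cfg$n_de_probes)
    stop("n_up must lie in [0, n_de_probes]", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$batch_shift_sd < 0)
    stop("noise_sd and batch_shift_sd must be non-negative", call. = FALSE)
  if (cfg$probes_per_probeset < 1L)
    stop("probes_per_probeset must be >= 1", call. = FALSE)
  if (cfg$survival_hazard_ratio <= 0 || cfg$baseline_hazard <= 0)
    stop("hazard parameters must be positive", call. = FALSE)
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)", call. = FALSE)
  if (length(cfg$followup_range) != 2L || any(cfg$followup_range <= 0) ||
      diff(cfg$followup_range) < 0)
    stop("followup_range must be an increasing pair of positive months",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate a multi-cohort ctDNA-detectability expression study
#'
#' Draws log2 expression for each cohort under the additive model
#' intensity = probe baseline + cohort offset + group effect + Gaussian noise,
#' where the group effect (effect_size * noise_sd, signed by the planted
#' direction) is added to ctDNA-positive samples on the differential probes
#' only, in the same direction in every cohort. Per-sample annotations carry
#' binary clinicopathological covariates (frequencies emulating an early
#' breast-cancer surgical series) and recurrence-free survival drawn from an
#' exponential proportional-hazards model with uniform administrative
#' censoring.
#'
#' @param config a [simulation_config()].
#'
#' @return A list with components:
#'   \describe{
#'     \item{cohorts}{list of `"cohort_study"` objects, each holding `expr`
#'       (probe-by-sample log2 matrix), `annotations` (data frame with
#'       sample_id, cohort, ctdna_status, covariates, rfs_months, rfs_event)
#'       and `cohort_label`.}
#'     \item{truth}{`"synthetic_truth"` object: de_probe_ids, directions
#'       ("up"/"down" named by probe), true_effect (signed standardized
#'       effects), cohort_offsets, survival_params.}
#'   }
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_probes = 200, n_de_probes = 10,
#'                                         n_up = 6, seed = 7))
#' dim(sim$cohorts[[1]]$expr)
#' head(sim$truth$de_probe_ids)
simulate_study <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n_cohorts <- length(config$cohort_sizes)
  probe_ids <- sprintf("probe_%05d", seq_len(config$n_probes))
  baseline <- stats::runif(config$n_probes, min = 4, max = 12)
  names(baseline) <- probe_ids

  de_ids <- if (config$n_de_probes > 0L)
    sort(sample(probe_ids, config$n_de_probes)) else character(0)
  dir_sign <- integer(0)
  if (config$n_de_probes > 0L) {
    dir_sign <- rep(-1L, config$n_de_probes)
    dir_sign[sample(config$n_de_probes, config$n_up)] <- 1L
  }
  effect <- stats::setNames(numeric(config$n_probes), probe_ids)
  effect[de_ids] <- dir_sign * config$effect_size
  cohort_offsets <- stats::rnorm(n_cohorts, mean = 0, sd = config$batch_shift_sd)
  names(cohort_offsets) <- sprintf("cohort_%d", seq_len(n_cohorts))

  cohorts <- vector("list", n_cohorts)
  for (k in seq_len(n_cohorts)) {
    n <- config$cohort_sizes[k]
    n_pos <- config$ctdna_positive_counts[k]
    label <- sprintf("cohort_%d", k)
    sample_ids <- sprintf("C%d_S%02d", k, seq_len(n))
    z <- integer(n)
    if (n_pos > 0L) z[sample(n, n_pos)] <- 1L
    mean_mat <- baseline + cohort_offsets[k] +
      outer(effect * config$noise_sd, z)
    expr <- mean_mat + matrix(stats::rnorm(config$n_probes * n,
                                           sd = config$noise_sd),
                              nrow = config$n_probes)
    dimnames(expr) <- list(probe_ids, sample_ids)
    ann <- data.frame(
      sample_id = sample_ids,
      cohort = label,
      ctdna_status = z,
      age_over50 = stats::rbinom(n, 1L, 12 / 35),
      tumor_gt20mm = stats::rbinom(n, 1L, 18 / 35),
      grade3 = stats::rbinom(n, 1L, 5 / 35),
      er_pos = stats::rbinom(n, 1L, 29 / 35),
      pr_pos = stats::rbinom(n, 1L, 24 / 34),
      her2_pos = stats::rbinom(n, 1L, 6 / 35),
      node_pos = stats::rbinom(n, 1L, 24 / 35),
      stringsAsFactors = FALSE
    )
    surv <- simulate_rfs(z, config)
    ann$rfs_months <- surv$time
    ann$rfs_event <- surv$event
    cohorts[[k]] <- new_cohort_study(expr, ann, label)
  }

  truth <- structure(list(
    de_probe_ids = de_ids,
    directions = stats::setNames(ifelse(dir_sign > 0, "up", "down"), de_ids),
    true_effect = effect[de_ids],
    cohort_offsets = cohort_offsets,
    survival_params = list(baseline_hazard = config$baseline_hazard,
                           hazard_ratio = config$survival_hazard_ratio)
  ), class = "synthetic_truth")

  list(cohorts = cohorts, truth = truth)
}

# Exponential PH recurrence times; administrative censoring uniform over the
# follow-up window, plus optional early drop-out with probability censoring_rate.
simulate_rfs <- function(z, config) {
  n <- length(z)
  rate <- config$baseline_hazard * config$survival_hazard_ratio^z
  t_event <- stats::rexp(n, rate = rate)
  c_admin <- stats::runif(n, config$followup_range[1], config$followup_range[2])
  dropout <- stats::runif(n) < config$censoring_rate
  c_drop <- ifelse(dropout, stats::runif(n, 0, c_admin), Inf)
  cens <- pmin(c_admin, c_drop)
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

new_cohort_study <- function(expr, annotations, cohort_label) {
  stopifnot(is.matrix(expr), ncol(expr) == nrow(annotations))
  structure(list(expr = expr, annotations = annotations,
                 cohort_label = cohort_label),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("cohort_study '%s': %d probes x %d samples (%d ctDNA+)\n",
              x$cohort_label, nrow(x$expr), ncol(x$expr),
              sum(x$annotations$ctdna_status)))
  invisible(x)
}

#' Simulate probe-level intensities grouped by probeset
#'
#' Fixture generator for the RMA-style summarization stage. Each probeset has
#' a per-sample log2 signal (probeset baseline plus per-sample biological
#' variation), shared by all its probes; individual probes add a fixed
#' affinity offset and Gaussian noise. Intensities are returned on the linear
#' scale (2^log2-value), the scale at which [rma_summarize()] ingests them.
#'
#' @param config a [simulation_config()]; `n_probes` is interpreted as the
#'   number of probesets and `cohort_sizes[1]` as the number of samples.
#' @param affinity_sd SD of the per-probe affinity offsets (log2 units); 0
#'   makes every probe of a probeset identical up to noise.
#'
#' @return List with `intensity` (probe-by-sample linear-scale matrix, rows
#'   named "<probeset>_pNN"), `probeset` (factor mapping rows to probesets)
#'   and `signal` (the true probeset-by-sample log2 signal, for validation).
#' @export
simulate_probe_level <- function(config = simulation_config(), affinity_sd = 0.5) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n_ps <- config$n_probes
  ppp <- config$probes_per_probeset
  n <- config$cohort_sizes[1]
  ps_ids <- sprintf("ps_%04d", seq_len(n_ps))
  sample_ids <- sprintf("S%02d", seq_len(n))
  baseline <- stats::runif(n_ps, 6, 10)
  signal <- baseline + matrix(stats::rnorm(n_ps * n), nrow = n_ps)
  dimnames(signal) <- list(ps_ids, sample_ids)
  probeset <- factor(rep(ps_ids, each = ppp), levels = ps_ids)
  affinity <- stats::rnorm(n_ps * ppp, sd = affinity_sd)
  log2_val <- signal[as.integer(probeset), , drop = FALSE] + affinity +
    matrix(stats::rnorm(n_ps * ppp * n, sd = config$noise_sd), nrow = n_ps * ppp)
  rownames(log2_val) <- sprintf("%s_p%02d", rep(ps_ids, each = ppp),
                                rep(seq_len(ppp), times = n_ps))
  colnames(log2_val) <- sample_ids
  list(intensity = 2^log2_val, probeset = probeset, signal = signal)
}

#' Simulate a digital-PCR partition readout
#'
#' Independent Poisson draws of mutant and wild-type template copies, the
#' counting model underlying chip-based digital PCR.
#'
#' @param n_mutant_expected,n_wildtype_expected non-negative expected copies.
#' @param seed optional integer seed.
#' @return List with integer `mutant_copies` and `wildtype_copies`.
#' @export
simulate_dpcr <- function(n_mutant_expected, n_wildtype_expected, seed = NULL) {
  if (n_mutant_expected < 0 || n_wildtype_expected < 0)
    stop("expected copy numbers must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  list(mutant_copies = stats::rpois(1L, n_mutant_expected),
       wildtype_copies = stats::rpois(1L, n_wildtype_expected))
}
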