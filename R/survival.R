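#' Kaplan-Meier product-limit curve
#'
#' Recurrence-free-survival estimate S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i). Ties between events and censorings at the same time
#' follow the standard convention: events precede censoring, so subjects
#' censored at t remain at risk for events at t. Wraps
#' [survival::survfit()]; Greenwood standard errors are retained.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicator (1 = recurrence, 0 = censored).
#' @return Object of class `"km_curve"`: `time` (distinct observed times,
#'   ascending), `surv`, `n_risk`, `n_event`, `std_err` and `n`.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("km_curve needs >= 1 record", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.integer(event)
  stopifnot(length(event) == length(time), all(event %in% 0:1))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log")
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, std_err = sf$std.err,
                 n = length(time)),
            class = "km_curve")
}

#' Survival probability at a time point
#'
#' Right-continuous step-function evaluation of a Kaplan-Meier curve.
#'
#' @param curve a [km_curve()].
#' @param t non-negative time(s) in months.
#' @return Survival probability at each `t` (1 before the first observed
#'   time; the last value beyond the final time).
#' @export
rfs_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1.0 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test between two survival groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over distinct event times, referred to chi-square with 1 df. Wraps
#' [survival::survdiff()].
#'
#' @param time_a,event_a follow-up times and 0/1 event indicators, group A.
#' @param time_b,event_b the same for group B.
#' @return List: `chi2` and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) < 1L || length(time_b) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(event_a) + sum(event_b) < 1L)
    stop("log-rank test needs at least one event", call. = FALSE)
  time <- c(time_a, time_b)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.integer(c(event_a, event_b))
  group <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}
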