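#' Weibull survival parameters
#'
#' Parametrises the survival function `S(t) = exp(-(t/scale)^shape)` with
#' time in months; `shape = 1` is the exponential (constant-hazard) special
#' case.
#'
#' @param shape Shape parameter, > 0.
#' @param scale Scale parameter in months, > 0.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(shape, scale) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0",
                                            call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0",
                                            call. = FALSE)
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  med <- x$scale * log(2)^(1 / x$shape)
  cat(sprintf("Weibull survival: shape %.4g, scale %.4g months (median %.3g months)\n",
              x$shape, x$scale, med))
  invisible(x)
}

#' Weibull survival function
#'
#' @param params A [weibull_params()].
#' @param t Time(s) in months, >= 0.
#' @return `exp(-(t/scale)^shape)`, in \[0, 1\]; vectorised over `t`.
#' @export
#' @examples
#' weibull_survival(weibull_params(1, 13.1 / log(2)), 13.1) # 0.5
weibull_survival <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp(-(t / params$scale)^params$shape)
}

#' Calibrate a Weibull curve to a median survival time
#'
#' Fixes the scale so the survival function crosses 0.5 exactly at the
#' given median: `scale = median / log(2)^(1/shape)`.
#'
#' @param median Median survival in months, > 0.
#' @param shape Weibull shape, > 0 (default 1, exponential).
#' @return A [weibull_params()] with `S(median) = 0.5`.
#' @export
weibull_from_median <- function(median, shape = 1) {
  if (!is.finite(median) || median <= 0) stop("median must be > 0",
                                              call. = FALSE)
  weibull_params(shape, median / log(2)^(1 / shape))
}

#' Rescale a Weibull curve by a hazard ratio
#'
#' Multiplies the cumulative hazard by `hr`, keeping the shape:
#' `scale' = scale * hr^(-1/shape)`. Used for scenario analysis (deriving
#' one arm's curve from the other via the trial hazard ratio); the default
#' calibration uses per-arm medians instead.
#'
#' @param params A [weibull_params()].
#' @param hr Hazard ratio, > 0.
#' @return Rescaled [weibull_params()].
#' @export
apply_hazard_ratio <- function(params, hr) {
  stopifnot(inherits(params, "weibull_params"))
  if (!is.finite(hr) || hr <= 0) stop("hr must be > 0", call. = FALSE)
  weibull_params(params$shape, params$scale * hr^(-1 / params$shape))
}

#' Fit a Weibull curve to a Kaplan-Meier estimate
#'
#' Least-squares fit on the complementary log-log scale:
#' `log(-log S(t)) = shape * log t - shape * log scale`, over points with
#' `0 < S < 1` and `t > 0`.
#'
#' @param km A `km_curve` (see [km_estimate()]) or any data.frame with
#'   columns `time` and `survival`.
#' @return A [weibull_params()].
#' @export
fit_weibull_to_km <- function(km) {
  stopifnot(is.data.frame(km), all(c("time", "survival") %in% names(km)))
  use <- km$survival > 0 & km$survival < 1 & km$time > 0
  if (sum(use) < 2 || length(unique(km$time[use])) < 2) {
    stop("need at least 2 Kaplan-Meier points with 0 < S < 1 to fit",
         call. = FALSE)
  }
  y <- log(-log(km$survival[use]))
  x <- log(km$time[use])
  fit <- stats::lm(y ~ x)
  shape <- unname(stats::coef(fit)[2])
  scale <- exp(-unname(stats::coef(fit)[1]) / shape)
  weibull_params(shape, scale)
}

#' Per-cycle transition probability out of a survival curve
#'
#' Conditional probability of leaving the state during cycle `k`:
#' `1 - S(k*u) / S((k-1)*u)` with `u` the cycle length in months. If the
#' curve has already vanished at the cycle start the state is treated as
#' absorbing (probability 1).
#'
#' @param params A [weibull_params()].
#' @param k Cycle index (>= 1); vectorised.
#' @param cycle_months Cycle length in months.
#' @return Probability in \[0, 1\]. For shape 1 it is identical for every
#'   `k` (memorylessness).
#' @export
cycle_transition_prob <- function(params, k, cycle_months) {
  if (any(k < 1)) stop("cycle index k must be >= 1", call. = FALSE)
  s_prev <- weibull_survival(params, (k - 1) * cycle_months)
  s_now <- weibull_survival(params, k * cycle_months)
  p <- ifelse(s_prev <= 0, 1, 1 - s_now / s_prev)
  pmin(pmax(p, 0), 1)
}

#' Per-cycle transition schedule for one arm
#'
#' Expands a progression-free survival curve into the per-cycle exit
#' probabilities the cohort engine consumes, together with the direct
#' PFS -> death probability and the constant per-cycle post-progression
#' mortality.
#'
#' @param pfs_params A [weibull_params()] for the PFS curve.
#' @param structure A [model_structure()].
#' @param p_dp_death Constant per-cycle probability of death in the
#'   progressed-disease state.
#' @param p_pfs_death Per-cycle probability of a direct PFS -> death
#'   transition (must not exceed the total exit probability in any cycle).
#' @return An object of class `transition_schedule`: list with vector
#'   `p_pfs_exit` (length `n_cycles`), scalar `p_pfs_death`, scalar
#'   `p_dp_death`.
#' @export
transition_schedule <- function(pfs_params, structure, p_dp_death,
                                p_pfs_death = 0) {
  stopifnot(inherits(structure, "model_structure"))
  if (p_dp_death < 0 || p_dp_death > 1) {
    stop("p_dp_death must be in [0, 1]", call. = FALSE)
  }
  k <- seq_len(structure$n_cycles)
  p_exit <- cycle_transition_prob(pfs_params, k, structure$cycle_months)
  if (p_pfs_death < 0 || any(p_pfs_death > p_exit)) {
    stop("p_pfs_death must be in [0, min p_pfs_exit]", call. = FALSE)
  }
  out <- list(p_pfs_exit = p_exit, p_pfs_death = p_pfs_death,
              p_dp_death = p_dp_death, pfs_params = pfs_params)
  class(out) <- "transition_schedule"
  out
}

#' Calibrate post-progression mortality to a discounted life-year target
#'
#' Finds the constant per-cycle probability of death in the progressed
#' state such that the cohort trace accumulates a given amount of
#' discounted progressed-disease person-time. Discounted DP person-time is
#' strictly decreasing in the mortality probability, so the root is found
#' by bisection on \[0, 1\] (tolerance 1e-8 on the probability, at most 60
#' iterations; deterministic).
#'
#' @param target_dp_ly Target discounted DP life-years, > 0.
#' @param pfs_schedule A [transition_schedule()] providing the PFS inflow
#'   (its `p_dp_death` is ignored).
#' @param structure A [model_structure()].
#' @param tol Bisection tolerance on the probability.
#' @return The calibrated per-cycle probability, with attribute
#'   `achieved_dp_ly`.
#' @export
calibrate_dp_mortality <- function(target_dp_ly, pfs_schedule, structure,
                                   tol = 1e-8) {
  stopifnot(inherits(pfs_schedule, "transition_schedule"),
            inherits(structure, "model_structure"))
  if (target_dp_ly <= 0) stop("target_dp_ly must be > 0", call. = FALSE)
  dp_ly_at <- function(p) {
    sched <- pfs_schedule
    sched$p_dp_death <- p
    summarize_occupancy(build_trace(sched, structure), structure)$ly_dp
  }
  max_ly <- dp_ly_at(0)
  if (target_dp_ly > max_ly + 1e-12) {
    stop(sprintf(paste0("target DP life-years (%.6f) unreachable within the",
                        " horizon even with zero mortality (maximum %.6f)"),
                 target_dp_ly, max_ly), call. = FALSE)
  }
  lo <- 0; hi <- 1
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    if (dp_ly_at(mid) > target_dp_ly) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  p <- (lo + hi) / 2
  attr(p, "achieved_dp_ly") <- dp_ly_at(p)
  p
}
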