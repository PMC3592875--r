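#' Generate pseudo individual-patient PFS data
#'
#' Emulates a two-arm progression-free-survival dataset: event times are
#' drawn per arm by inverse-transform sampling from a Weibull curve
#' (`t = scale * (-log U)^(1/shape)`), with administrative censoring at a
#' fixed follow-up time. Defaults calibrate the arms to the trial medians
#' of 13.1 (erlotinib) and 4.6 (CG) months with exponential curves; arm
#' sizes and follow-up are generator choices, not trial facts (the source
#' prints no arm-level counts usable here).
#'
#' @param params_by_arm Named list of [weibull_params()] per arm.
#' @param n_per_arm Patients per arm (default 500).
#' @param censor_time Administrative censoring time in months (default 24).
#' @param seed Integer seed; same seed, same table.
#' @return A data.frame of class `pseudo_ipd`: `id`, `arm`, `time_months`
#'   (> 0), `event` (1 event, 0 censored). Attributes `true_params`,
#'   `censor_time`, `seed` allow bit-exact regeneration.
#' @export
generate_ipd <- function(params_by_arm = list(
                           erlotinib = weibull_from_median(13.1),
                           cg = weibull_from_median(4.6)),
                         n_per_arm = 500, censor_time = 24, seed = NULL) {
  stopifnot(length(params_by_arm) >= 1, !is.null(names(params_by_arm)))
  if (n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  if (censor_time <= 0) stop("censor_time must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(params_by_arm), function(arm) {
    p <- params_by_arm[[arm]]
    stopifnot(inherits(p, "weibull_params"))
    u <- stats::runif(n_per_arm)
    t <- p$scale * (-log(u))^(1 / p$shape)
    data.frame(arm = arm,
               time_months = pmin(t, censor_time),
               event = as.integer(t < censor_time),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  class(out) <- c("pseudo_ipd", "data.frame")
  attr(out, "true_params") <- params_by_arm
  attr(out, "censor_time") <- censor_time
  attr(out, "seed") <- seed
  out
}

#' Kaplan-Meier estimate for one arm
#'
#' Product-limit estimator via [survival::survfit()]: at each distinct
#' event time the survival estimate multiplies by `1 - d/n_at_risk`;
#' censored times reduce the risk set only.
#'
#' @param ipd A [generate_ipd()] table (or any data.frame with columns
#'   `arm`, `time_months`, `event`).
#' @param arm Which arm to estimate.
#' @return A data.frame of class `km_curve`: `time`, `survival`, `n_risk`,
#'   `n_event`, at every distinct observed time. If the arm has no events
#'   the (flat) curve is returned with a warning and attribute
#'   `no_events = TRUE`.
#' @export
km_estimate <- function(ipd, arm) {
  stopifnot(is.data.frame(ipd),
            all(c("arm", "time_months", "event") %in% names(ipd)))
  sub <- ipd[ipd$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for arm '", arm, "'", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1, data = sub)
  out <- data.frame(time = fit$time, survival = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  class(out) <- c("km_curve", "data.frame")
  if (sum(sub$event) == 0) {
    warning("arm '", arm, "' has no events; Kaplan-Meier curve is flat 1.0",
            call. = FALSE)
    attr(out, "no_events") <- TRUE
  }
  out
}

#' Export pseudo-IPD / Kaplan-Meier tables as CSV
#'
#' @param x A `pseudo_ipd` or `km_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
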