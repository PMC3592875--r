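#' Discount factor at a given cycle
#'
#' `(1 + r)^(-t_k)` with `t_k = k * cycle_length_days / days_per_year`.
#'
#' @param k Cycle index (>= 0); vectorised.
#' @param structure A [model_structure()].
#' @return Dimensionless discount factor(s); 1 at `k = 0` or zero rate.
#' @export
discount_factor <- function(k, structure) {
  stopifnot(inherits(structure, "model_structure"))
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  (1 + structure$discount_rate_annual)^(-(k * structure$cycle_years))
}

#' Build the three-state cohort trace
#'
#' Runs the cohort through the progression-free (PFS) -> progressed (DP) ->
#' dead chain cycle by cycle. The whole cohort starts in PFS. Per cycle `k`:
#' PFS retains `1 - p_pfs_exit(k)`; exits split between direct death
#' (`p_pfs_death`) and progression; progressors join the DP at-risk pool at
#' the start of the NEXT cycle (they incur no DP mortality in their entry
#' cycle); DP loses the constant `p_dp_death`; death absorbs the remainder.
#'
#' @param schedule A [transition_schedule()].
#' @param structure A [model_structure()].
#' @return An object of class `cohort_trace`: a data.frame with one row per
#'   cycle `k = 0 .. n_cycles` and columns `cycle`, `t_years`, `pfs`, `dp`,
#'   `death`, `discount`. Occupancies sum to 1 in every row.
#' @export
build_trace <- function(schedule, structure) {
  stopifnot(inherits(schedule, "transition_schedule"),
            inherits(structure, "model_structure"))
  n <- structure$n_cycles
  p_exit <- schedule$p_pfs_exit
  if (length(p_exit) == 1) p_exit <- rep(p_exit, n)
  if (length(p_exit) != n) {
    stop("schedule p_pfs_exit must cover all ", n, " cycles", call. = FALSE)
  }
  if (any(p_exit < 0 | p_exit > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  pfs <- dp <- death <- numeric(n + 1)
  pfs[1] <- 1
  for (k in seq_len(n)) {
    inflow <- pfs[k] * (p_exit[k] - schedule$p_pfs_death)
    pfs[k + 1] <- pfs[k] * (1 - p_exit[k])
    dp[k + 1] <- dp[k] * (1 - schedule$p_dp_death) + inflow
    death[k + 1] <- 1 - pfs[k + 1] - dp[k + 1]
  }
  out <- data.frame(cycle = 0:n,
                    t_years = (0:n) * structure$cycle_years,
                    pfs = pfs, dp = dp, death = death,
                    discount = discount_factor(0:n, structure))
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Summarise discounted state occupancy of a cohort trace
#'
#' Person-time counts end-of-cycle state membership (cycles `k >= 1`, no
#' half-cycle correction): `ly_state = sum_k occ_k * d_k * cycle_years`.
#' The median PFS is the linearly interpolated time at which PFS occupancy
#' crosses 0.5, in months; `NA` if never reached within the horizon.
#'
#' @param trace A [build_trace()] result.
#' @param structure A [model_structure()].
#' @return An object of class `occupancy_summary`: list with `ly_pfs`,
#'   `ly_dp`, `ly_total` (discounted years) and `median_pfs` (months).
#' @export
summarize_occupancy <- function(trace, structure) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(structure, "model_structure"))
  cy <- structure$cycle_years
  w <- trace$discount[-1] * cy
  ly_pfs <- sum(trace$pfs[-1] * w)
  ly_dp <- sum(trace$dp[-1] * w)
  out <- list(ly_pfs = ly_pfs, ly_dp = ly_dp, ly_total = ly_pfs + ly_dp,
              median_pfs = trace_median_months(trace$pfs, structure))
  class(out) <- "occupancy_summary"
  out
}

# Linear interpolation of the cycle at which an occupancy vector (indexed
# from cycle 0) crosses 0.5, converted to months. NA if never reached.
trace_median_months <- function(occ, structure) {
  below <- which(occ < 0.5)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]                         # first cycle index (1-based) below 0.5
  if (i == 1) return(0)                 # starts below 0.5 (degenerate)
  k_hi <- i - 1                         # cycle number after crossing
  frac <- (occ[i - 1] - 0.5) / (occ[i - 1] - occ[i])
  (k_hi - 1 + frac) * structure$cycle_months
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("Discounted occupancy: PFS %.3f y, DP %.3f y, total %.3f y; median PFS %s months\n",
              x$ly_pfs, x$ly_dp, x$ly_total,
              if (is.na(x$median_pfs)) "not reached"
              else sprintf("%.2f", x$median_pfs)))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' Columns: cycle, t_years, pfs, dp, death, discount_factor.
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  out <- trace
  names(out)[names(out) == "discount"] <- "discount_factor"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
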