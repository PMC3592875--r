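#' Per-cycle PFS cost under erlotinib
#'
#' Cycles 1-7 incur the erlotinib treatment cost; from cycle 8 the drug is
#' donated and only the (optional) blood-test cost remains while the
#' patient stays progression-free.
#'
#' @param k Cycle index (>= 1); vectorised.
#' @param params A [cost_params()].
#' @return USD per cycle.
#' @export
#' @examples
#' erlotinib_pfs_cost(3, cost_params()) # 1971.1 + 3.53
#' erlotinib_pfs_cost(8, cost_params()) # 3.53
erlotinib_pfs_cost <- function(k, params) {
  stopifnot(inherits(params, "cost_params"))
  if (any(k < 1)) stop("cycle index k must be >= 1", call. = FALSE)
  drug <- ifelse(k <= 7, params$erl_tt_per_cycle,
                 params$erl_after_donation_per_cycle)
  bt <- if (params$include_blood_tests) params$blood_test_erl_per_cycle else 0
  drug + bt
}

#' Per-cycle PFS cost under CG chemotherapy
#'
#' Cycles 1-4 incur the chemotherapy treatment cost (plus the optional
#' blood-test cost); from cycle 5 patients still progression-free switch to
#' best supportive care, assumed all-inclusive unless `cg_bsc_blood_tests`
#' is set.
#'
#' @inheritParams erlotinib_pfs_cost
#' @return USD per cycle.
#' @export
#' @examples
#' cg_pfs_cost(2, cost_params()) # 1599.41 + 10.59 = 1610
#' cg_pfs_cost(5, cost_params()) # 1415.4
cg_pfs_cost <- function(k, params) {
  stopifnot(inherits(params, "cost_params"))
  if (any(k < 1)) stop("cycle index k must be >= 1", call. = FALSE)
  bt <- if (params$include_blood_tests) params$blood_test_cg_per_cycle else 0
  bt_bsc <- if (params$include_blood_tests && params$cg_bsc_blood_tests) {
    params$blood_test_cg_per_cycle
  } else 0
  ifelse(k <= 4, params$cg_tt_per_cycle + bt,
         params$cg_bsc_per_cycle + bt_bsc)
}

#' Expected one-off adverse-event management cost
#'
#' `sum(rate_i * unit_cost_i)` over the profile's events, charged once at
#' model entry (undiscounted). Zero for the erlotinib arm, whose trial
#' adverse-event rates are all zero.
#'
#' @param profile An [adverse_event_profile()].
#' @return USD.
#' @export
#' @examples
#' mae_one_off_cost(adverse_event_profile()) # 1620.951
mae_one_off_cost <- function(profile) {
  stopifnot(inherits(profile, "adverse_event_profile"))
  sum(profile$events$rate * profile$events$unit_cost)
}

#' Erlotinib per-cycle price rebuilt from the weekly unit price
#'
#' Cross-check of the configured per-cycle erlotinib cost against
#' 3 x the weekly (7 x 150 mg) acquisition price, assuming no wastage.
#'
#' @param params A [cost_params()].
#' @param tolerance Flag threshold in USD (default 1).
#' @return USD, with logical attribute `cross_check_failed` set when the
#'   rebuilt price differs from `erl_tt_per_cycle` by more than `tolerance`.
#' @export
erlotinib_cycle_price_from_units <- function(params, tolerance = 1) {
  stopifnot(inherits(params, "cost_params"))
  price <- 3 * params$erl_unit_price_per_week
  attr(price, "cross_check_failed") <-
    abs(price - params$erl_tt_per_cycle) > tolerance
  price
}

#' Cycle-indexed cost schedule for one strategy
#'
#' Expands the unit costs into per-cycle PFS and DP cost vectors over the
#' model horizon plus the one-off adverse-event charge. The DP cost is
#' applied per cycle (`dp_cost_basis = "cycle"`, default) or prorated from
#' a monthly figure (`"month"`).
#'
#' @param strategy `"erlotinib"` or `"cg"`.
#' @param params A [cost_params()].
#' @param ae_profile [adverse_event_profile()] for the strategy (the CG
#'   profile for `"cg"`, all-zero for `"erlotinib"`).
#' @param structure A [model_structure()].
#' @return An object of class `cost_schedule`: list with `strategy`,
#'   vectors `pfs_cost` and `dp_cost` (length `n_cycles`), and scalar
#'   `one_off_cost`.
#' @export
cost_schedule <- function(strategy = c("erlotinib", "cg"), params,
                          ae_profile, structure) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "cost_params"),
            inherits(ae_profile, "adverse_event_profile"),
            inherits(structure, "model_structure"))
  k <- seq_len(structure$n_cycles)
  pfs_cost <- if (strategy == "erlotinib") {
    erlotinib_pfs_cost(k, params)
  } else {
    cg_pfs_cost(k, params)
  }
  dp_per_cycle <- if (params$dp_cost_basis == "cycle") {
    params$dp_cost_per_cycle
  } else {
    params$dp_cost_per_cycle * structure$cycle_months
  }
  out <- list(strategy = strategy, pfs_cost = pfs_cost,
              dp_cost = rep(dp_per_cycle, structure$n_cycles),
              one_off_cost = mae_one_off_cost(ae_profile))
  class(out) <- "cost_schedule"
  out
}

#' Export a cost schedule as CSV
#'
#' Columns: cycle, strategy, pfs_cost, dp_cost.
#'
#' @param schedule A `cost_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "cost_schedule"))
  utils::write.csv(
    data.frame(cycle = seq_along(schedule$pfs_cost),
               strategy = schedule$strategy,
               pfs_cost = schedule$pfs_cost,
               dp_cost = schedule$dp_cost),
    path, row.names = FALSE)
  invisible(path)
}
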