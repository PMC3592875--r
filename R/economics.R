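#' Per-strategy economic result
#'
#' Container for discounted life-years, QALYs and costs decomposed by
#' health state. Built by [evaluate_strategy()] (from a cohort trace) or
#' [econ_from_occupancy()] (from given occupancies and cost components).
#'
#' @param strategy `"erlotinib"` or `"cg"`.
#' @param ly_pfs,ly_dp Discounted life-years by state.
#' @param qaly_pfs,qaly_dp Discounted QALYs by state.
#' @param cost_pfs,cost_dp,cost_mae Discounted costs (USD) by component.
#' @param mae_folded If TRUE, `cost_mae` is already contained in `cost_pfs`
#'   and is not added again to the total.
#' @return An object of class `econ_result` with derived `ly_total`,
#'   `qaly_total`, `cost_total`.
#' @export
econ_result <- function(strategy, ly_pfs, ly_dp, qaly_pfs, qaly_dp,
                        cost_pfs, cost_dp, cost_mae = 0,
                        mae_folded = FALSE) {
  out <- list(strategy = strategy,
              ly_pfs = ly_pfs, ly_dp = ly_dp, ly_total = ly_pfs + ly_dp,
              qaly_pfs = qaly_pfs, qaly_dp = qaly_dp,
              qaly_total = qaly_pfs + qaly_dp,
              cost_pfs = cost_pfs, cost_dp = cost_dp, cost_mae = cost_mae,
              cost_total = cost_pfs + cost_dp +
                if (mae_folded) 0 else cost_mae,
              mae_folded = mae_folded)
  if (out$qaly_total > out$ly_total + 1e-9) {
    stop("QALYs cannot exceed life-years (utilities bounded by 1)",
         call. = FALSE)
  }
  class(out) <- "econ_result"
  out
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("%-10s LY %.2f (PFS %.2f, DP %.2f) | QALY %.2f | cost $%.2f (2010 USD)\n",
              x$strategy, x$ly_total, x$ly_pfs, x$ly_dp, x$qaly_total,
              x$cost_total))
  invisible(x)
}

#' Evaluate one strategy over a cohort trace
#'
#' Accumulates discounted person-time, QALYs (person-time weighted by the
#' strategy's state utilities) and costs (occupancy- and discount-weighted
#' sums of the cycle-indexed cost schedule, plus the one-off adverse-event
#' charge at model entry).
#'
#' @param trace A [build_trace()] result.
#' @param utilities A [utility_set()].
#' @param schedule A [cost_schedule()].
#' @param structure A [model_structure()].
#' @return An [econ_result()].
#' @export
evaluate_strategy <- function(trace, utilities, schedule, structure) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(utilities, "utility_set"),
            inherits(schedule, "cost_schedule"),
            inherits(structure, "model_structure"))
  if (length(schedule$pfs_cost) != structure$n_cycles ||
      nrow(trace) != structure$n_cycles + 1) {
    stop("trace, schedule and structure disagree on cycle count",
         call. = FALSE)
  }
  occ <- summarize_occupancy(trace, structure)
  u_pfs <- if (schedule$strategy == "erlotinib") {
    utilities$u_pfs_erlotinib
  } else {
    utilities$u_pfs_cg
  }
  d <- trace$discount[-1]
  res <- econ_result(
    strategy = schedule$strategy,
    ly_pfs = occ$ly_pfs, ly_dp = occ$ly_dp,
    qaly_pfs = occ$ly_pfs * u_pfs, qaly_dp = occ$ly_dp * utilities$u_dp,
    cost_pfs = sum(trace$pfs[-1] * d * schedule$pfs_cost),
    cost_dp = sum(trace$dp[-1] * d * schedule$dp_cost),
    cost_mae = schedule$one_off_cost
  )
  res$median_pfs <- occ$median_pfs
  res
}

#' Build an economic result from given occupancies and cost components
#'
#' Direct recomposition used for anchored evaluation and worked-example
#' checks: QALYs are occupancy x utility; costs are passed through.
#'
#' @param strategy `"erlotinib"` or `"cg"`.
#' @param ly_pfs,ly_dp Discounted life-years by state.
#' @param utilities A [utility_set()].
#' @param cost_pfs,cost_dp,cost_mae Cost components (USD).
#' @param mae_folded See [econ_result()].
#' @return An [econ_result()].
#' @export
#' @examples
#' u <- utility_set()
#' econ_from_occupancy("erlotinib", 1.27, 1.23, u,
#'                     14772.04, 25335.91)$qaly_total # 1.4036
econ_from_occupancy <- function(strategy, ly_pfs, ly_dp, utilities,
                                cost_pfs = 0, cost_dp = 0, cost_mae = 0,
                                mae_folded = FALSE) {
  stopifnot(inherits(utilities, "utility_set"))
  u_pfs <- if (strategy == "erlotinib") {
    utilities$u_pfs_erlotinib
  } else {
    utilities$u_pfs_cg
  }
  econ_result(strategy, ly_pfs, ly_dp,
              qaly_pfs = ly_pfs * u_pfs, qaly_dp = ly_dp * utilities$u_dp,
              cost_pfs = cost_pfs, cost_dp = cost_dp, cost_mae = cost_mae,
              mae_folded = mae_folded)
}

#' Incremental cost-effectiveness statistics
#'
#' Deltas are `b - a`; the caller fixes the orientation (the package
#' convention elsewhere is CG minus erlotinib). A strategy is dominant when
#' it is both cheaper and more effective, making the ratio meaningless;
#' `delta_qaly = 0` with nonzero cost yields a signed infinite ICER
#' sentinel rather than an error.
#'
#' @param a,b Two [econ_result()]s from the same model structure.
#' @return An object of class `incremental_result`: `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer_per_qaly`, `icer_per_ly`, `dominance`
#'   (one of `"none"`, `"a-dominant"`, `"b-dominant"`).
#' @export
#' @examples
#' u <- utility_set()
#' erl <- econ_from_occupancy("erlotinib", 1.27, 1.23, u, 14772.04, 25335.91)
#' cg <- econ_from_occupancy("cg", 0.43, 3.65, u, 13060.35, 75166.95)
#' icer(erl, cg)
icer <- function(a, b) {
  stopifnot(inherits(a, "econ_result"), inherits(b, "econ_result"))
  dc <- b$cost_total - a$cost_total
  dq <- b$qaly_total - a$qaly_total
  dl <- b$ly_total - a$ly_total
  dominance <- if (dc < 0 && dq > 0) {
    "b-dominant"
  } else if (dc > 0 && dq < 0) {
    "a-dominant"
  } else {
    "none"
  }
  ratio <- function(num, den) {
    if (dominance != "none") return(NA_real_)
    if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
    num / den
  }
  out <- list(comparison = paste(b$strategy, "vs", a$strategy),
              delta_cost = dc, delta_qaly = dq, delta_ly = dl,
              icer_per_qaly = ratio(dc, dq), icer_per_ly = ratio(dc, dl),
              dominance = dominance)
  class(out) <- "incremental_result"
  out
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental (%s): dCost $%.2f, dQALY %.4f, dLY %.4f\n",
              x$comparison, x$delta_cost, x$delta_qaly, x$delta_ly))
  if (x$dominance == "none") {
    cat(sprintf("  ICER: $%.2f/QALY, $%.2f/LY (2010 USD)\n",
                x$icer_per_qaly, x$icer_per_ly))
  } else {
    cat("  dominance:", x$dominance, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * qaly_total - cost_total`. At the willingness-to-pay equal to the
#' ICER between two strategies their net benefits are equal.
#'
#' @param result An [econ_result()].
#' @param wtp Willingness-to-pay in USD/QALY, >= 0.
#' @return USD; vectorised over `wtp`.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "econ_result"))
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * result$qaly_total - result$cost_total
}
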