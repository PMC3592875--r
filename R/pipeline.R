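# Deterministic pipelines: full trace-based calibration/evaluation, and the
# anchored evaluator the sensitivity analyses run on.

#' Calibrate the survival machinery for both arms
#'
#' Builds each arm's progression-free survival curve (exponential by
#' default, calibrated to the arm's own trial median; optionally derived
#' from the CG curve via the hazard ratio), expands it into per-cycle
#' transition probabilities, and back-calibrates the constant per-cycle
#' post-progression mortality so the discounted progressed-disease
#' person-time hits each arm's reported target.
#'
#' @param bundle A `param_bundle` (see [default_params()]).
#' @return An object of class `model_calibration`: per-arm list with
#'   `pfs_params`, `p_dp_death`, `schedule`, `trace` and `occupancy`.
#' @export
#' @examples
#' cal <- calibrate_model(default_params())
#' cal$arms$erlotinib$occupancy$median_pfs # about 13.1 months
calibrate_model <- function(bundle) {
  validate_bundle(bundle)
  sv <- bundle$survival
  st <- bundle$structure
  cg_pfs <- weibull_from_median(sv$median_pfs_cg, sv$weibull_shape)
  erl_pfs <- if (isTRUE(sv$use_hazard_ratio)) {
    apply_hazard_ratio(cg_pfs, sv$hazard_ratio_erl_vs_cg)
  } else {
    weibull_from_median(sv$median_pfs_erl, sv$weibull_shape)
  }
  calibrate_arm <- function(pfs_params, target_dp_ly) {
    sched0 <- transition_schedule(pfs_params, st, p_dp_death = 0,
                                  p_pfs_death = sv$p_pfs_death)
    p_dp <- calibrate_dp_mortality(target_dp_ly, sched0, st)
    sched <- transition_schedule(pfs_params, st, p_dp_death = as.numeric(p_dp),
                                 p_pfs_death = sv$p_pfs_death)
    trace <- build_trace(sched, st)
    list(pfs_params = pfs_params, p_dp_death = as.numeric(p_dp),
         schedule = sched, trace = trace,
         occupancy = summarize_occupancy(trace, st))
  }
  out <- list(arms = list(erlotinib = calibrate_arm(erl_pfs,
                                                    sv$target_dp_ly_erl),
                          cg = calibrate_arm(cg_pfs, sv$target_dp_ly_cg)),
              structure = st)
  class(out) <- "model_calibration"
  out
}

#' @export
print.model_calibration <- function(x, ...) {
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("%-10s shape %.3g scale %.4g mo | p(DP death)/cycle %.5f | median PFS %.2f mo\n",
                arm, a$pfs_params$shape, a$pfs_params$scale, a$p_dp_death,
                a$occupancy$median_pfs))
  }
  invisible(x)
}

#' Run the base case from the full trace pipeline
#'
#' Calibration, cohort traces, cost schedules and economics for both
#' strategies, plus the model-vs-trial median PFS validation. Incremental
#' results are reported in both orientations to avoid sign confusion; the
#' primary orientation is CG minus erlotinib.
#'
#' @param bundle A `param_bundle`.
#' @return An object of class `base_case_result`: `results` (per-strategy
#'   [econ_result()]), `incremental` (CG vs erlotinib), `incremental_rev`,
#'   `medians` (trial vs model, months), `calibration`.
#' @export
base_case <- function(bundle) {
  validate_bundle(bundle)
  cal <- calibrate_model(bundle)
  st <- bundle$structure
  sched_erl <- cost_schedule("erlotinib", bundle$costs, no_adverse_events(),
                             st)
  sched_cg <- cost_schedule("cg", bundle$costs, bundle$adverse_events, st)
  erl <- evaluate_strategy(cal$arms$erlotinib$trace, bundle$utilities,
                           sched_erl, st)
  cg <- evaluate_strategy(cal$arms$cg$trace, bundle$utilities, sched_cg, st)
  out <- list(
    results = list(erlotinib = erl, cg = cg),
    incremental = icer(erl, cg),
    incremental_rev = icer(cg, erl),
    medians = data.frame(
      arm = c("erlotinib", "cg"),
      trial_median_months = c(bundle$survival$median_pfs_erl,
                              bundle$survival$median_pfs_cg),
      model_median_months = c(cal$arms$erlotinib$occupancy$median_pfs,
                              cal$arms$cg$occupancy$median_pfs)
    ),
    calibration = cal
  )
  class(out) <- "base_case_result"
  out
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("Base case (trace pipeline, 2010 USD)\n")
  print(x$results$erlotinib)
  print(x$results$cg)
  print(x$incremental)
  cat("Median PFS, model vs trial (months):\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}

# Apply sensitivity-analysis overrides (named by ParameterSpec role) to a
# bundle. Roles: cost_params fields, utility fields, "ae_rate:<event>",
# "ae_cost:<event>", "discount_rate_annual".
apply_overrides <- function(bundle, overrides) {
  if (length(overrides) == 0) return(bundle)
  stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
  for (role in names(overrides)) {
    value <- overrides[[role]]
    if (role %in% names(bundle$costs)) {
      bundle$costs[[role]] <- value
    } else if (role %in% c("u_pfs_erlotinib", "u_pfs_cg", "u_dp")) {
      bundle$utilities[[role]] <- value
    } else if (grepl("^ae_(rate|cost):", role)) {
      field <- if (startsWith(role, "ae_rate:")) "rate" else "unit_cost"
      event <- sub("^ae_(rate|cost):", "", role)
      hit <- bundle$adverse_events$events$name == event
      if (!any(hit)) stop("unknown adverse event: ", event, call. = FALSE)
      bundle$adverse_events$events[hit, field] <- value
    } else if (role == "discount_rate_annual") {
      s <- bundle$structure
      bundle$structure <- model_structure(
        cycle_length_days = s$cycle_length_days,
        horizon_years = s$horizon_years,
        discount_rate_annual = value,
        days_per_month = s$days_per_month,
        days_per_year = s$days_per_year)
    } else {
      stop("override role does not bind to a model input: ", role,
           call. = FALSE)
    }
  }
  bundle
}

# Trace-pipeline state components per arm at a given discount rate, with
# post-progression mortality held at its base-rate calibration. Used to
# rescale the anchored components when the discount rate is varied one-way.
trace_components <- function(bundle, cal, rate) {
  s <- bundle$structure
  st <- model_structure(cycle_length_days = s$cycle_length_days,
                        horizon_years = s$horizon_years,
                        discount_rate_annual = rate,
                        days_per_month = s$days_per_month,
                        days_per_year = s$days_per_year)
  comp <- function(arm, strategy, ae) {
    sched <- transition_schedule(cal$arms[[arm]]$pfs_params, st,
                                 p_dp_death = cal$arms[[arm]]$p_dp_death,
                                 p_pfs_death = bundle$survival$p_pfs_death)
    res <- evaluate_strategy(build_trace(sched, st), bundle$utilities,
                             cost_schedule(strategy, bundle$costs, ae, st),
                             st)
    c(ly_pfs = res$ly_pfs, ly_dp = res$ly_dp, cost_pfs = res$cost_pfs,
      cost_dp = res$cost_dp)
  }
  list(erlotinib = comp("erlotinib", "erlotinib", no_adverse_events()),
       cg = comp("cg", "cg", bundle$adverse_events))
}

#' Anchored deterministic evaluator
#'
#' Returns a closure that re-evaluates both strategies under parameter
#' overrides, anchored to the reported base-case occupancies and cost
#' totals (see [base_case_anchors()]): effects are anchor occupancies times
#' the (possibly overridden) utilities; each anchored cost component is
#' scaled multiplicatively in its unit costs, with component shares taken
#' from the calibrated cohort trace; the adverse-event charge is recomputed
#' exactly. At base values the evaluator reproduces the anchors. A
#' discount-rate override rescales every component by the ratio of
#' trace-pipeline components at the new versus the base rate. This is the
#' pipeline the tornado and probabilistic sensitivity analyses run on; the
#' rationale is discussed in the methods vignette.
#'
#' @param bundle A `param_bundle`.
#' @return A function `f(overrides = list())` (overrides named by
#'   ParameterSpec role) returning a list with per-strategy
#'   [econ_result()]s (`erlotinib`, `cg`) and `incremental`
#'   (CG minus erlotinib).
#' @export
#' @examples
#' ev <- anchored_evaluator(default_params())
#' ev()$incremental$icer_per_qaly                 # base-case ICER
#' ev(list(u_dp = 0.58))$incremental$icer_per_qaly # one-way endpoint
anchored_evaluator <- function(bundle) {
  validate_bundle(bundle)
  cal <- calibrate_model(bundle)
  an <- bundle$anchors
  costs0 <- bundle$costs
  base_rate <- bundle$structure$discount_rate_annual
  mae0 <- mae_one_off_cost(bundle$adverse_events)

  # discounted occupancy weights from the calibrated traces
  w <- function(arm, cycles) {
    tr <- cal$arms[[arm]]$trace
    sum(tr$pfs[cycles + 1] * tr$discount[cycles + 1])
  }
  n <- bundle$structure$n_cycles
  bt <- isTRUE(costs0$include_blood_tests)
  # base component contributions within each arm's PFS cost pool
  erl_comp <- c(erl_tt_per_cycle = w("erlotinib", 1:7) * costs0$erl_tt_per_cycle,
                blood_test_erl_per_cycle =
                  if (bt) w("erlotinib", 1:n) * costs0$blood_test_erl_per_cycle
                  else 0)
  cg_comp <- c(cg_tt_per_cycle = w("cg", 1:4) * costs0$cg_tt_per_cycle,
               cg_bsc_per_cycle = w("cg", 5:n) * costs0$cg_bsc_per_cycle,
               blood_test_cg_per_cycle =
                 if (bt) w("cg", 1:4) * costs0$blood_test_cg_per_cycle
                 else 0)
  erl_share <- erl_comp / sum(erl_comp)
  cg_share <- cg_comp / sum(cg_comp)
  cg_pool0 <- an$cost_pfs_cg - mae0 # CG PFS anchor is MAE-inclusive

  scale_pool <- function(anchor_pool, shares, costs) {
    ratios <- vapply(names(shares), function(f) {
      if (costs0[[f]] == 0) 1 else costs[[f]] / costs0[[f]]
    }, numeric(1))
    anchor_pool * sum(shares * ratios)
  }

  function(overrides = list()) {
    b <- apply_overrides(bundle, overrides)
    mae <- mae_one_off_cost(b$adverse_events)
    dp_ratio <- if (costs0$dp_cost_per_cycle == 0) 1 else
      b$costs$dp_cost_per_cycle / costs0$dp_cost_per_cycle

    comp <- list(
      erlotinib = c(ly_pfs = an$ly_pfs_erl,
                    ly_dp = bundle$survival$target_dp_ly_erl,
                    cost_pfs = scale_pool(an$cost_pfs_erl, erl_share,
                                          b$costs),
                    cost_dp = an$cost_dp_erl * dp_ratio),
      cg = c(ly_pfs = an$ly_pfs_cg,
             ly_dp = bundle$survival$target_dp_ly_cg,
             cost_pfs = mae + scale_pool(cg_pool0, cg_share, b$costs),
             cost_dp = an$cost_dp_cg * dp_ratio)
    )

    rate <- b$structure$discount_rate_annual
    if (rate != base_rate) {
      tc_new <- trace_components(b, cal, rate)
      tc_base <- trace_components(b, cal, base_rate)
      for (arm in names(comp)) {
        ratio <- tc_new[[arm]] / tc_base[[arm]]
        ratio[!is.finite(ratio)] <- 1
        comp[[arm]] <- comp[[arm]] * ratio
      }
    }

    erl <- econ_from_occupancy("erlotinib", comp$erlotinib[["ly_pfs"]],
                               comp$erlotinib[["ly_dp"]], b$utilities,
                               cost_pfs = comp$erlotinib[["cost_pfs"]],
                               cost_dp = comp$erlotinib[["cost_dp"]],
                               cost_mae = 0)
    cg <- econ_from_occupancy("cg", comp$cg[["ly_pfs"]],
                              comp$cg[["ly_dp"]], b$utilities,
                              cost_pfs = comp$cg[["cost_pfs"]],
                              cost_dp = comp$cg[["cost_dp"]],
                              cost_mae = mae, mae_folded = TRUE)
    list(erlotinib = erl, cg = cg, incremental = icer(erl, cg))
  }
}

#' Anchored base case
#'
#' Convenience wrapper: [anchored_evaluator()] evaluated with no overrides.
#'
#' @param bundle A `param_bundle`.
#' @return List with `erlotinib`, `cg` ([econ_result()]s) and
#'   `incremental`.
#' @export
anchored_base_case <- function(bundle) {
  anchored_evaluator(bundle)()
}
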