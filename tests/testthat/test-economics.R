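test_that("QALY recomposition from reported occupancies and utilities", {
  res <- table4_results()
  expect_equal(res$erlotinib$qaly_total, 1.4036, tolerance = 1e-9)
  expect_equal(res$cg$qaly_total, 1.9563, tolerance = 1e-9)
  expect_equal(round(res$erlotinib$qaly_total, 2), 1.40)
  expect_equal(round(res$cg$qaly_total, 2), 1.96)
  # utility identity: all utilities 1 collapses QALYs onto life-years
  u1 <- utility_set(1, 1, 1)
  res1 <- econ_from_occupancy("erlotinib", 1.27, 1.23, u1)
  expect_equal(res1$qaly_total, res1$ly_total)
})

test_that("ICERs from the reported totals match the printed ratios", {
  # printed two-decimal QALY/LY decomposition, taken at face value
  erl <- econ_result("erlotinib", ly_pfs = 1.27, ly_dp = 1.23,
                     qaly_pfs = 0.82, qaly_dp = 0.58,
                     cost_pfs = 14772.04, cost_dp = 25335.91)
  cg <- econ_result("cg", ly_pfs = 0.43, ly_dp = 3.65,
                    qaly_pfs = 0.24, qaly_dp = 1.72,
                    cost_pfs = 13060.35, cost_dp = 75166.95,
                    cost_mae = 1620.951, mae_folded = TRUE)
  inc <- icer(erl, cg)
  expect_equal(inc$delta_cost, 48119.35, tolerance = 1e-9)
  expect_equal(inc$icer_per_qaly, 85927.41, tolerance = 0.01 / 85927.41)
  expect_equal(inc$icer_per_ly, 30455.28, tolerance = 0.01 / 30455.28)
  expect_identical(inc$dominance, "none")
})

test_that("dominance and degenerate deltas are reported, not computed", {
  u <- utility_set()
  a <- econ_from_occupancy("erlotinib", 1, 1, u, cost_pfs = 1000)
  cheaper_better <- econ_from_occupancy("cg", 2, 2, u, cost_pfs = 500)
  inc <- icer(a, cheaper_better)
  expect_identical(inc$dominance, "b-dominant")
  expect_true(is.na(inc$icer_per_qaly))
  inc_rev <- icer(cheaper_better, a)
  expect_identical(inc_rev$dominance, "a-dominant")
  # equal effect, different cost: infinite sentinel, no error
  b <- econ_from_occupancy("cg", 1.27 * 0.65 / 0.56, 1.23, u,
                           cost_pfs = 2000)
  expect_equal(b$qaly_total,
               econ_from_occupancy("erlotinib", 1.27, 1.23, u)$qaly_total,
               tolerance = 1e-12)
  inc2 <- icer(econ_from_occupancy("erlotinib", 1.27, 1.23, u,
                                   cost_pfs = 1000), b)
  expect_identical(inc2$icer_per_qaly, Inf)
})

test_that("net monetary benefit behaves algebraically", {
  res <- table4_results()
  expect_equal(net_monetary_benefit(res$erlotinib, 0),
               -res$erlotinib$cost_total)
  # the two strategies' NMB curves cross exactly at the ICER
  inc <- icer(res$erlotinib, res$cg)
  lambda <- inc$icer_per_qaly
  expect_equal(net_monetary_benefit(res$erlotinib, lambda),
               net_monetary_benefit(res$cg, lambda), tolerance = 1e-6)
  # below the ICER the cheaper strategy wins, above it the more effective
  expect_gt(net_monetary_benefit(res$erlotinib, 13527),
            net_monetary_benefit(res$cg, 13527))
  expect_lt(net_monetary_benefit(res$erlotinib, lambda * 2),
            net_monetary_benefit(res$cg, lambda * 2))
  expect_error(net_monetary_benefit(res$erlotinib, -1), "wtp")
})

test_that("ICER is homogeneous of degree one in costs", {
  u <- utility_set()
  for (c_scale in c(0.5, 2, 10)) {
    erl <- econ_from_occupancy("erlotinib", 1.27, 1.23, u,
                               cost_pfs = 14772.04 * c_scale,
                               cost_dp = 25335.91 * c_scale)
    cg <- econ_from_occupancy("cg", 0.43, 3.65, u,
                              cost_pfs = 13060.35 * c_scale,
                              cost_dp = 75166.95 * c_scale)
    base <- table4_results()
    expect_equal(icer(erl, cg)$icer_per_qaly,
                 c_scale * icer(base$erlotinib, base$cg)$icer_per_qaly,
                 tolerance = 1e-9)
  }
})

test_that("pipeline ICER equals brute-force recomputation from traces", {
  b <- default_params()
  bc <- base_case(b)
  st <- b$structure
  cal <- bc$calibration
  # independent accumulation straight off the raw traces
  brute <- function(arm, strategy, ae) {
    tr <- cal$arms[[arm]]$trace
    sched <- cost_schedule(strategy, b$costs, ae, st)
    d <- tr$discount[-1]
    u_pfs <- if (strategy == "erlotinib") b$utilities$u_pfs_erlotinib
             else b$utilities$u_pfs_cg
    list(cost = sum(tr$pfs[-1] * d * sched$pfs_cost) +
           sum(tr$dp[-1] * d * sched$dp_cost) + sched$one_off_cost,
         qaly = st$cycle_years *
           (sum(tr$pfs[-1] * d) * u_pfs + sum(tr$dp[-1] * d) * b$utilities$u_dp))
  }
  e <- brute("erlotinib", "erlotinib", no_adverse_events())
  g <- brute("cg", "cg", b$adverse_events)
  expect_equal(bc$incremental$icer_per_qaly,
               (g$cost - e$cost) / (g$qaly - e$qaly), tolerance = 1e-9)
})

test_that("economic results respect their internal identities", {
  b <- default_params()
  bc <- base_case(b)
  for (res in bc$results) {
    expect_equal(res$qaly_total, res$qaly_pfs + res$qaly_dp,
                 tolerance = 1e-9)
    expect_equal(res$ly_total, res$ly_pfs + res$ly_dp, tolerance = 1e-9)
    expect_equal(res$cost_total, res$cost_pfs + res$cost_dp + res$cost_mae,
                 tolerance = 1e-2)
    expect_lte(res$qaly_total, res$ly_total)
  }
  expect_error(econ_result("x", 1, 1, qaly_pfs = 2, qaly_dp = 1,
                           cost_pfs = 0, cost_dp = 0),
               "cannot exceed")
})
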