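test_that("weibull survival matches its closed form", {
  expect_equal(weibull_survival(weibull_params(1, 10), 0), 1)
  expect_equal(weibull_survival(weibull_params(1, 18.899), 13.1), 0.5,
               tolerance = 1e-3)
  expect_equal(weibull_survival(weibull_params(2, 5), 5), exp(-1))
  expect_error(weibull_survival(weibull_params(1, 10), -1), ">= 0")
  expect_error(weibull_params(0, 10), "shape")
  expect_error(weibull_params(1, -2), "scale")
})

test_that("median calibration pins the survival function at 0.5", {
  expect_equal(weibull_from_median(13.1)$scale, 13.1 / log(2),
               tolerance = 1e-12)
  expect_equal(weibull_from_median(4.6)$scale, 4.6 / log(2),
               tolerance = 1e-12)
  for (m in c(0.5, 4.6, 13.1, 40)) {
    for (g in c(0.7, 1, 1.8, 3)) {
      expect_equal(weibull_survival(weibull_from_median(m, g), m), 0.5,
                   tolerance = 1e-14)
    }
  }
  expect_error(weibull_from_median(-1), "median")
})

test_that("hazard-ratio rescaling multiplies the cumulative hazard", {
  p <- weibull_params(1, 6.636)
  expect_equal(apply_hazard_ratio(p, 1)$scale, p$scale)
  expect_equal(apply_hazard_ratio(p, 0.16)$scale, 6.636 / 0.16,
               tolerance = 1e-9)
  # cumulative hazard scales by hr at arbitrary t, arbitrary shape
  p2 <- weibull_params(1.7, 12)
  t <- 7.3
  expect_equal(-log(weibull_survival(apply_hazard_ratio(p2, 0.4), t)),
               0.4 * -log(weibull_survival(p2, t)), tolerance = 1e-12)
  # inverse composition recovers the original scale
  expect_equal(apply_hazard_ratio(apply_hazard_ratio(p2, 3.7), 1 / 3.7)$scale,
               p2$scale, tolerance = 1e-12)
  expect_error(apply_hazard_ratio(p, 0), "hr")
})

test_that("noiseless Kaplan-Meier points recover Weibull parameters", {
  t <- seq(2, 20, by = 2)
  km <- data.frame(time = t, survival = exp(-(t / 10)^1.5))
  fit <- fit_weibull_to_km(km)
  expect_equal(fit$shape, 1.5, tolerance = 1e-6)
  expect_equal(fit$scale, 10, tolerance = 1e-6)
})

test_that("degenerate Kaplan-Meier input is a fitting error", {
  expect_error(fit_weibull_to_km(data.frame(time = 1:3, survival = 1)),
               "at least 2")
  expect_error(fit_weibull_to_km(data.frame(time = 2, survival = 0.5)),
               "at least 2")
})

test_that("Weibull fit recovers generator parameters from synthetic IPD", {
  ipd <- generate_ipd(list(x = weibull_from_median(13.1, 1)),
                      n_per_arm = 5000, censor_time = 1e6, seed = 101)
  fit <- fit_weibull_to_km(km_estimate(ipd, "x"))
  expect_lt(abs(fit$shape - 1), 0.05)
  fitted_median <- fit$scale * log(2)^(1 / fit$shape)
  expect_lt(abs(fitted_median - 13.1) / 13.1, 0.05)
})

test_that("per-cycle transition probabilities match the closed form", {
  u <- 21 / 30.4375
  cg <- weibull_from_median(4.6, 1)
  p <- cycle_transition_prob(cg, 1:20, u)
  expect_equal(p[1], 1 - exp(-log(2) / 4.6 * u), tolerance = 1e-12)
  expect_equal(p[1], 0.0988, tolerance = 1e-3)
  expect_true(all(abs(p - p[1]) < 1e-12)) # exponential memorylessness
  # increasing hazard when shape > 1
  p2 <- cycle_transition_prob(weibull_params(2, 10), c(1, 10), 1)
  expect_gt(p2[2], p2[1])
  expect_error(cycle_transition_prob(cg, 0, u), "k must be")
})

test_that("transition-probability products reproduce S(k*u) exactly", {
  u <- 21 / 30.4375
  for (shape in c(0.8, 1, 1.7)) {
    params <- weibull_from_median(8, shape)
    p <- cycle_transition_prob(params, 1:40, u)
    expect_equal(cumprod(1 - p), weibull_survival(params, (1:40) * u),
                 tolerance = 1e-12)
  }
})

test_that("a vanished survival curve becomes absorbing", {
  p <- cycle_transition_prob(weibull_params(5, 0.01), 50, 1)
  expect_equal(p, 1)
})

test_that("DP mortality calibration round-trips through the engine", {
  st <- model_structure()
  sched <- transition_schedule(weibull_from_median(4.6), st, p_dp_death = 0)
  # forward-simulate a known p, then recover it from the resulting target
  sched_true <- sched
  sched_true$p_dp_death <- 0.05
  target <- summarize_occupancy(build_trace(sched_true, st), st)$ly_dp
  p_hat <- calibrate_dp_mortality(target, sched, st)
  expect_equal(as.numeric(p_hat), 0.05, tolerance = 1e-6)
  expect_lt(abs(attr(p_hat, "achieved_dp_ly") - target), 1e-6)
})

test_that("DP person-time is monotone decreasing in DP mortality", {
  st <- small_structure(60)
  sched <- transition_schedule(weibull_from_median(4.6), st, p_dp_death = 0)
  ly_at <- function(p) {
    s <- sched
    s$p_dp_death <- p
    summarize_occupancy(build_trace(s, st), st)$ly_dp
  }
  values <- vapply(c(0, 0.02, 0.1, 0.5, 1), ly_at, numeric(1))
  expect_true(all(diff(values) < 0))
})

test_that("with p = 1 the DP state holds each entrant for one cycle only", {
  st <- small_structure(30)
  sched <- transition_schedule(weibull_from_median(4.6), st, p_dp_death = 1)
  trace <- build_trace(sched, st)
  # each cycle's DP occupancy is exactly that cycle's inflow
  inflow <- trace$pfs[-nrow(trace)] * sched$p_pfs_exit
  expect_equal(trace$dp[-1], inflow, tolerance = 1e-12)
  expect_equal(summarize_occupancy(trace, st)$ly_dp,
               sum(inflow * trace$discount[-1]) * st$cycle_years,
               tolerance = 1e-12)
})

test_that("unreachable targets report the achievable maximum", {
  st <- small_structure(10)
  sched <- transition_schedule(weibull_from_median(4.6), st, p_dp_death = 0)
  expect_error(calibrate_dp_mortality(50, sched, st), "maximum")
  expect_error(calibrate_dp_mortality(-1, sched, st), "target_dp_ly")
})
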