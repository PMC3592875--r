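test_that("moment matching reproduces the stated distribution parameters", {
  specs <- default_parameter_specs()
  # DP cost: gamma(shape ~ 96.05, scale ~ 12.60)
  d <- fit_distribution(specs[specs$role == "dp_cost_per_cycle", ])
  expect_equal(d$sd, (1451.95 - 967.97) / (2 * 1.96), tolerance = 1e-12)
  expect_equal(d$pars$shape, 96.05, tolerance = 1e-4)
  expect_equal(d$pars$scale, 12.60, tolerance = 1e-3)
  # erlotinib PFS utility: beta(alpha ~ 5.46, beta ~ 2.94)
  d <- fit_distribution(specs[specs$role == "u_pfs_erlotinib", ])
  expect_equal(d$pars$shape1, 5.46, tolerance = 1e-3)
  expect_equal(d$pars$shape2, 2.94, tolerance = 1e-3)
})

test_that("fitted distributions have the spec's mean and sd (oracle)", {
  specs <- default_parameter_specs()
  for (i in which(specs$family != "constant")) {
    d <- fit_distribution(specs[i, ])
    s <- d$sd
    m <- specs$base[i]
    moments <- switch(
      d$family,
      gamma = c(d$pars$shape * d$pars$scale,
                sqrt(d$pars$shape) * d$pars$scale),
      lognormal = {
        mu <- d$pars$meanlog; sg <- d$pars$sdlog
        c(exp(mu + sg^2 / 2),
          sqrt((exp(sg^2) - 1) * exp(2 * mu + sg^2)))
      },
      beta = {
        a <- d$pars$shape1; b <- d$pars$shape2
        c(a / (a + b), sqrt(a * b / ((a + b)^2 * (a + b + 1))))
      })
    expect_equal(moments[1], m, tolerance = 1e-9, label = specs$name[i])
    expect_equal(moments[2], s, tolerance = 1e-9, label = specs$name[i])
  }
})

test_that("sample means converge on the base values", {
  set.seed(11)
  specs <- default_parameter_specs()
  for (i in which(specs$family != "constant")) {
    d <- fit_distribution(specs[i, ])
    expect_lt(abs(mean(d$r(1e5)) - specs$base[i]) / specs$base[i], 0.01,
              label = specs$name[i])
  }
  # constant family is a point mass
  d <- fit_distribution(specs[specs$family == "constant", ])
  expect_equal(d$r(5), rep(0.03, 5))
})

test_that("degenerate specs raise named errors", {
  bad <- data.frame(name = "flat", base = 1, low = 1, high = 1,
                    family = "gamma", role = "dp_cost_per_cycle")
  expect_error(fit_distribution(bad), "non-positive sd")
  wide <- data.frame(name = "too-wide", base = 0.05, low = 0, high = 1,
                     family = "beta", role = "u_dp")
  expect_error(fit_distribution(wide), "too-wide")
})

test_that("one-way DP-utility ICERs equal the anchored closed form", {
  b <- default_params()
  ev <- anchored_evaluator(b)
  spec <- b$specs[b$specs$role == "u_dp", ]
  entry <- one_way(spec, b, ev)
  # closed-form oracle from the anchor recomposition
  icer_at <- function(u_dp) {
    dq <- (0.43 * 0.56 + 3.65 * u_dp) - (1.27 * 0.65 + 1.23 * u_dp)
    48119.35 / dq
  }
  expect_equal(entry$icer_at_low, icer_at(0.30), tolerance = 1e-6)
  expect_equal(entry$icer_at_high, icer_at(0.58), tolerance = 1e-6)
  expect_false(entry$unstable)
})

test_that("parameters affecting only costs leave incremental QALYs alone", {
  ev <- anchored_evaluator(default_params())
  base <- ev()$incremental
  moved <- ev(list(dp_cost_per_cycle = 1451.95))$incremental
  expect_equal(moved$delta_qaly, base$delta_qaly, tolerance = 1e-12)
  expect_gt(moved$delta_cost, base$delta_cost)
})

test_that("tornado ranks the DP utility first and ignores spec order", {
  b <- default_params()
  tor <- tornado(b)
  expect_s3_class(tor, "tornado_result")
  expect_equal(nrow(tor), 17)
  expect_identical(tor$parameter[1], "DP")
  expect_true(all(diff(tor$spread) <= 1e-9))
  expect_false(any(tor$unstable))
  set.seed(3)
  shuffled <- b$specs[sample(nrow(b$specs)), ]
  tor2 <- tornado(b, specs = shuffled)
  expect_equal(as.data.frame(tor), as.data.frame(tor2))
})

test_that("PSA is reproducible and respects the degenerate limit", {
  b <- default_params()
  s1 <- run_psa(b, n_iter = 10, seed = 5)
  s2 <- run_psa(b, n_iter = 10, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # all-constant specs collapse every iteration onto the base case
  b2 <- default_params()
  b2$specs$family <- "constant"
  s3 <- run_psa(b2, n_iter = 5, seed = 5)
  base_inc <- anchored_base_case(b2)$incremental
  expect_equal(s3$delta_cost, rep(base_inc$delta_cost, 5), tolerance = 1e-12)
  expect_equal(s3$delta_qaly, rep(base_inc$delta_qaly, 5), tolerance = 1e-12)
})

test_that("quadrant proportions partition the CE plane", {
  b <- default_params()
  samples <- run_psa(b, n_iter = 200, seed = 9)
  q <- quadrant_proportions(samples)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_named(q, c("NE", "NW", "SE", "SW"))
  # sign consistency of the labels
  expect_true(all(samples$delta_cost[samples$quadrant == "NE"] >= 0))
  expect_true(all(samples$delta_qaly[samples$quadrant == "NW"] < 0))
  # hand-built sample set entirely in the NE quadrant
  fake <- samples[1:4, ]
  fake$delta_cost <- c(1, 2, 3, 0)
  fake$delta_qaly <- c(1, 0, 2, 0)
  fake$quadrant <- classify_quadrant(fake$delta_cost, fake$delta_qaly)
  expect_equal(unname(quadrant_proportions(fake)), c(1, 0, 0, 0))
})

test_that("CEAC probabilities are complementary and well behaved", {
  b <- default_params()
  samples <- run_psa(b, n_iter = 300, seed = 13)
  curve <- ceac(samples, b$wtp)
  expect_equal(curve$p_cg + curve$p_erlotinib, rep(1, nrow(curve)),
               tolerance = 1e-12)
  # zero-WTP limit: CG is preferred only when it saves money
  expect_equal(curve$p_cg[curve$wtp == 0],
               mean(samples$delta_cost < 0), tolerance = 1e-12)
  # all sampled delta-costs are positive here, so the curve is monotone
  expect_true(all(samples$delta_cost > 0))
  expect_true(all(diff(curve$p_cg) >= 0))
})

test_that("CEAC crossing interpolates the 50% threshold", {
  fake <- data.frame(wtp = c(0, 100, 200), p_cg = c(0, 0.25, 0.75),
                     p_erlotinib = c(1, 0.75, 0.25))
  class(fake) <- c("ceac_curve", "data.frame")
  expect_equal(ceac_crossing(fake, 0.5), 150)
  expect_true(is.na(ceac_crossing(fake, 0.9)))
})

test_that("quadrant fractions from two seeds agree within binomial error", {
  b <- default_params()
  n <- 10000
  p1 <- quadrant_proportions(run_psa(b, n_iter = n, seed = 21))[["NE"]]
  p2 <- quadrant_proportions(run_psa(b, n_iter = n, seed = 22))[["NE"]]
  pool <- (p1 + p2) / 2
  se_diff <- sqrt(pool * (1 - pool) * 2 / n)
  expect_lt(abs(p1 - p2), 3 * se_diff + 1e-12)
})

test_that("the discount-rate one-way entry moves both ICER endpoints", {
  b <- default_params()
  spec <- b$specs[b$specs$role == "discount_rate_annual", ]
  entry <- one_way(spec, b)
  expect_true(is.finite(entry$icer_at_low) && is.finite(entry$icer_at_high))
  base <- anchored_base_case(b)$incremental$icer_per_qaly
  expect_lt(entry$icer_at_low, base)  # no discounting favours CG's later QALYs
  expect_gt(entry$icer_at_high, base)
})
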