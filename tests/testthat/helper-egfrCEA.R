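# Shared fixtures and independent oracles for the test suite.

# A transition schedule with arbitrary per-cycle probabilities (bypasses the
# Weibull constructor so engine behaviour can be probed directly).
manual_schedule <- function(p_pfs_exit, p_dp_death = 0, p_pfs_death = 0) {
  structure(list(p_pfs_exit = p_pfs_exit, p_pfs_death = p_pfs_death,
                 p_dp_death = p_dp_death),
            class = "transition_schedule")
}

# A small model structure: n_cycles cycles of 21 days, default discounting.
small_structure <- function(n_cycles, discount = 0.03) {
  model_structure(cycle_length_days = 21,
                  horizon_years = n_cycles * 21 / 365.25,
                  discount_rate_annual = discount)
}

# Brute-force product-limit estimator: explicit risk-set recomputation at
# every distinct observed time. Independent of survival::survfit.
km_brute_force <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- lapply(times, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n_risk)
    data.frame(time = t, survival = s, n_risk = n_risk, n_event = d)
  })
  do.call(rbind, out)
}

# Table-4-style worked-example economic results (printed occupancies and
# cost totals), used for identity checks.
table4_results <- function(utilities = utility_set()) {
  list(
    erlotinib = econ_from_occupancy("erlotinib", 1.27, 1.23, utilities,
                                    cost_pfs = 14772.04,
                                    cost_dp = 25335.91),
    cg = econ_from_occupancy("cg", 0.43, 3.65, utilities,
                             cost_pfs = 13060.35, cost_dp = 75166.95,
                             cost_mae = 1620.951, mae_folded = TRUE)
  )
}
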