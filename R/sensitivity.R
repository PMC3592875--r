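#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs the deterministic (anchored) pipeline at the parameter's low and
#' high value, all other inputs at base, and records both ICERs
#' (CG minus erlotinib orientation). If the incremental QALYs change sign
#' across the range the entry is flagged unstable (the ratio is then
#' meaningless in between).
#'
#' @param spec One row of a [default_parameter_specs()] table (data.frame
#'   with `name`, `base`, `low`, `high`, `role`).
#' @param bundle A `param_bundle`.
#' @param evaluator Optional evaluator closure from [anchored_evaluator()];
#'   built from `bundle` when NULL (pass one when scanning many parameters
#'   to avoid recalibrating).
#' @return A one-row data.frame: `parameter`, `icer_at_low`, `icer_at_high`,
#'   `spread`, `unstable`.
#' @export
one_way <- function(spec, bundle, evaluator = NULL) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  if (is.null(evaluator)) evaluator <- anchored_evaluator(bundle)
  at <- function(value) {
    evaluator(stats::setNames(list(value), spec$role))$incremental
  }
  lo <- at(spec$low)
  hi <- at(spec$high)
  unstable <- sign(lo$delta_qaly) != sign(hi$delta_qaly) ||
    lo$dominance != "none" || hi$dominance != "none"
  il <- if (lo$dominance == "none") lo$icer_per_qaly else
    sign(lo$delta_cost) * Inf
  ih <- if (hi$dominance == "none") hi$icer_per_qaly else
    sign(hi$delta_cost) * Inf
  data.frame(parameter = spec$name, icer_at_low = il, icer_at_high = ih,
             spread = abs(ih - il), unstable = unstable,
             stringsAsFactors = FALSE)
}

#' Tornado analysis
#'
#' [one_way()] over every parameter spec, sorted by ICER spread
#' (descending). The result is invariant to the input ordering of the
#' specs.
#'
#' @param bundle A `param_bundle`.
#' @param specs Parameter specification table; defaults to the bundle's.
#' @return A data.frame of class `tornado_result` with a `rank` column.
#' @export
#' @examples
#' tor <- tornado(default_params())
#' tor$parameter[1] # "DP" (the progressed-state utility dominates)
tornado <- function(bundle, specs = bundle$specs) {
  validate_parameter_specs(specs)
  evaluator <- anchored_evaluator(bundle)
  rows <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    one_way(specs[i, ], bundle, evaluator)
  }))
  rows <- rows[order(-rows$spread, rows$parameter), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  class(rows) <- c("tornado_result", "data.frame")
  rows
}

#' Fit a sampling distribution to a parameter specification
#'
#' Moment matching with mean = base and sd = (high - low) / (2 * 1.96)
#' (the range is read as a 95% interval). Gamma: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`. Lognormal: `sigma^2 = log(1 + sd^2/mean^2)`,
#' `mu = log(mean) - sigma^2/2` (mean and sd are those of the distribution
#' itself). Beta: `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean(1 - mean)/sd^2 - 1`. The `constant` family is a point mass.
#'
#' @param spec One row of a parameter specification table.
#' @return List of class `fitted_distribution`: `family`, `mean`, `sd`,
#'   `pars`, and `r(n)`, a sampler.
#' @export
#' @examples
#' d <- fit_distribution(default_parameter_specs()[10, ]) # DP cost, gamma
#' d$pars # shape about 96.05, scale about 12.60
fit_distribution <- function(spec) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  m <- spec$base
  if (spec$family == "constant") {
    out <- list(family = "constant", mean = m, sd = 0, pars = list(value = m),
                r = function(n) rep(m, n))
    class(out) <- "fitted_distribution"
    return(out)
  }
  s <- (spec$high - spec$low) / (2 * 1.96)
  if (s <= 0) stop("spec '", spec$name, "' has non-positive sd",
                   call. = FALSE)
  out <- switch(
    spec$family,
    gamma = {
      shape <- (m / s)^2
      scale <- s^2 / m
      list(pars = list(shape = shape, scale = scale),
           r = function(n) stats::rgamma(n, shape = shape, scale = scale))
    },
    lognormal = {
      sigma2 <- log(1 + s^2 / m^2)
      mu <- log(m) - sigma2 / 2
      list(pars = list(meanlog = mu, sdlog = sqrt(sigma2)),
           r = function(n) stats::rlnorm(n, mu, sqrt(sigma2)))
    },
    beta = {
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0) {
        stop("beta spec '", spec$name,
             "' has variance too large for its mean (nu <= 0)",
             call. = FALSE)
      }
      a <- m * nu
      b <- (1 - m) * nu
      list(pars = list(shape1 = a, shape2 = b),
           r = function(n) stats::rbeta(n, a, b))
    },
    stop("unknown family: ", spec$family, call. = FALSE)
  )
  out <- c(list(family = spec$family, mean = m, sd = s), out)
  class(out) <- "fitted_distribution"
  out
}

# Domain for resample-on-violation checks, by role.
role_domain <- function(role) {
  if (role %in% c("u_pfs_erlotinib", "u_pfs_cg", "u_dp") ||
      startsWith(role, "ae_rate:")) {
    c(0, 1)
  } else {
    c(0, Inf)
  }
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation: each iteration draws every non-constant
#' parameter independently from its fitted distribution (see
#' [fit_distribution()]), re-runs the anchored deterministic pipeline and
#' records the incremental cost and QALYs of CG versus erlotinib together
#' with the cost-effectiveness-plane quadrant. Draws outside a parameter's
#' domain are resampled (count recorded in attribute `n_resampled`); fully
#' reproducible given `seed`.
#'
#' @param bundle A `param_bundle`.
#' @param n_iter Number of iterations (default 1000).
#' @param seed Integer seed for the R random number generator.
#' @return A data.frame of class `psa_result`: `iteration`, one column per
#'   sampled parameter (named by role), `delta_cost`, `delta_qaly`,
#'   `quadrant`. Attributes: `seed`, `n_resampled`, `wtp_threshold`.
#' @export
run_psa <- function(bundle, n_iter = 1000, seed = NULL) {
  validate_bundle(bundle)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  specs <- bundle$specs[bundle$specs$family != "constant", , drop = FALSE]
  evaluator <- anchored_evaluator(bundle)

  n_resampled <- 0L
  draws <- matrix(NA_real_, nrow = n_iter, ncol = nrow(specs),
                  dimnames = list(NULL, specs$role))
  for (j in seq_len(nrow(specs))) {
    dist <- fit_distribution(specs[j, ])
    dom <- role_domain(specs$role[j])
    x <- dist$r(n_iter)
    bad <- x < dom[1] | x > dom[2]
    while (any(bad)) {
      n_resampled <- n_resampled + sum(bad)
      x[bad] <- dist$r(sum(bad))
      bad <- x < dom[1] | x > dom[2]
    }
    draws[, j] <- x
  }

  dc <- dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    inc <- evaluator(as.list(draws[i, ]))$incremental
    dc[i] <- inc$delta_cost
    dq[i] <- inc$delta_qaly
  }
  out <- data.frame(iteration = seq_len(n_iter), draws,
                    delta_cost = dc, delta_qaly = dq,
                    quadrant = classify_quadrant(dc, dq),
                    check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("psa_result", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_resampled") <- n_resampled
  attr(out, "wtp_threshold") <- bundle$wtp$threshold
  out
}

# Quadrants of the CE plane (costs north, effects east); exact zeros go to
# the positive side.
classify_quadrant <- function(delta_cost, delta_qaly) {
  north <- delta_cost >= 0
  east <- delta_qaly >= 0
  ifelse(north & east, "NE",
         ifelse(north & !east, "NW", ifelse(east, "SE", "SW")))
}

#' Quadrant proportions of PSA samples
#'
#' @param samples A [run_psa()] result.
#' @return Named numeric vector over `NE`, `NW`, `SE`, `SW`, summing to 1.
#' @export
quadrant_proportions <- function(samples) {
  stopifnot(inherits(samples, "psa_result"), nrow(samples) >= 1)
  counts <- table(factor(samples$quadrant,
                         levels = c("NE", "NW", "SE", "SW")))
  stats::setNames(as.numeric(counts) / nrow(samples),
                  c("NE", "NW", "SE", "SW"))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that CG chemotherapy
#' is cost-effective is the fraction of PSA samples with positive
#' incremental net monetary benefit (`wtp * dQALY - dCost > 0`, CG minus
#' erlotinib); erlotinib's probability is the complement.
#'
#' @param samples A [run_psa()] result.
#' @param wtp A [wtp_config()] or numeric vector of WTP values.
#' @return A data.frame of class `ceac_curve`: `wtp`, `p_cg`,
#'   `p_erlotinib`.
#' @export
ceac <- function(samples, wtp) {
  stopifnot(inherits(samples, "psa_result"), nrow(samples) >= 1)
  grid <- if (inherits(wtp, "wtp_config")) wtp$grid else as.numeric(wtp)
  p_cg <- vapply(grid, function(lambda) {
    mean(lambda * samples$delta_qaly - samples$delta_cost > 0)
  }, numeric(1))
  out <- data.frame(wtp = grid, p_cg = p_cg, p_erlotinib = 1 - p_cg)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' WTP at which a CEAC crosses a given probability
#'
#' Linear interpolation of the first crossing of `p_cg` above `prob` along
#' an acceptability curve; `NA` if the curve never reaches it.
#'
#' @param curve A [ceac()] result.
#' @param prob Target probability (default 0.5).
#' @return WTP in USD/QALY, or `NA`.
#' @export
ceac_crossing <- function(curve, prob = 0.5) {
  stopifnot(inherits(curve, "ceac_curve"))
  above <- which(curve$p_cg >= prob)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(curve$wtp[1])
  p0 <- curve$p_cg[i - 1]
  p1 <- curve$p_cg[i]
  if (p1 == p0) return(curve$wtp[i])
  curve$wtp[i - 1] + (prob - p0) / (p1 - p0) *
    (curve$wtp[i] - curve$wtp[i - 1])
}
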