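# Orchestration functions tying the modules into the four analyses
# (base case, tornado, PSA, trial simulation) with CSV/JSON artifacts and a
# run manifest. These are the package's operational entry points.

resolve_bundle <- function(config) {
  if (is.null(config)) return(default_params())
  if (inherits(config, "param_bundle")) return(config)
  if (is.character(config) && length(config) == 1) {
    return(load_config(config))
  }
  stop("config must be NULL, a param_bundle, or a file path", call. = FALSE)
}

write_manifest <- function(output_dir, command, files, seed = NULL,
                           bundle = NULL) {
  config_path <- file.path(output_dir, "config_used.json")
  if (!is.null(bundle)) write_config(bundle, config_path)
  manifest <- list(
    command = command,
    config_hash = if (file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("egfrCEA")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(c(files, config_path))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

econ_result_row <- function(res) {
  data.frame(strategy = res$strategy, ly_pfs = res$ly_pfs,
             ly_dp = res$ly_dp, ly_total = res$ly_total,
             qaly_pfs = res$qaly_pfs, qaly_dp = res$qaly_dp,
             qaly_total = res$qaly_total, cost_pfs = res$cost_pfs,
             cost_dp = res$cost_dp, cost_mae = res$cost_mae,
             cost_total = res$cost_total, stringsAsFactors = FALSE)
}

#' Run and export the base case
#'
#' Full trace pipeline (calibration, traces, economics, median validation)
#' plus the anchored base case, written as CSV/JSON with a run manifest.
#' Currency is 2010 USD throughout.
#'
#' @param config `NULL` (defaults), a `param_bundle`, or a config file path.
#' @param output_dir Directory for the artifacts (created if missing).
#' @return The [base_case()] result, invisibly (with the anchored result in
#'   `$anchored`).
#' @export
run_base_case <- function(config = NULL, output_dir) {
  bundle <- resolve_bundle(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  bc <- base_case(bundle)
  anchored <- anchored_base_case(bundle)
  bc$anchored <- anchored

  summary_df <- rbind(econ_result_row(bc$results$erlotinib),
                      econ_result_row(bc$results$cg))
  files <- file.path(output_dir,
                     c("base_case.csv", "medians.csv", "incremental.json",
                       "trace_erlotinib.csv", "trace_cg.csv"))
  utils::write.csv(summary_df, files[1], row.names = FALSE)
  utils::write.csv(bc$medians, files[2], row.names = FALSE)
  jsonlite::write_json(
    list(cg_vs_erlotinib = unclass(bc$incremental),
         erlotinib_vs_cg = unclass(bc$incremental_rev),
         anchored_cg_vs_erlotinib = unclass(anchored$incremental),
         currency = "2010 USD"),
    files[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_trace_csv(bc$calibration$arms$erlotinib$trace, files[4])
  write_trace_csv(bc$calibration$arms$cg$trace, files[5])
  write_manifest(output_dir, "base-case", files, bundle = bundle)
  invisible(bc)
}

#' Run and export the tornado analysis
#'
#' @inheritParams run_base_case
#' @return The [tornado()] table, invisibly.
#' @export
run_tornado <- function(config = NULL, output_dir) {
  bundle <- resolve_bundle(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- tornado(bundle)
  f <- file.path(output_dir, "tornado.csv")
  utils::write.csv(as.data.frame(tor), f, row.names = FALSE)
  write_manifest(output_dir, "tornado", f, bundle = bundle)
  invisible(tor)
}

#' Run and export the probabilistic sensitivity analysis
#'
#' Writes the per-iteration samples, the acceptability curve over the
#' bundle's WTP grid, and a JSON summary (quadrant proportions, probability
#' CG is cost-effective at the WTP threshold, CEAC 50% crossing).
#'
#' @inheritParams run_base_case
#' @param n_iter PSA iterations (default 1000).
#' @param seed Integer seed.
#' @return The [run_psa()] samples, invisibly.
#' @export
run_psa_analysis <- function(config = NULL, n_iter = 1000, seed = 1,
                             output_dir) {
  bundle <- resolve_bundle(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- run_psa(bundle, n_iter = n_iter, seed = seed)
  curve <- ceac(samples, bundle$wtp)
  at_threshold <- ceac(samples, bundle$wtp$threshold)$p_cg
  files <- file.path(output_dir,
                     c("psa_samples.csv", "ceac.csv", "psa_summary.json"))
  utils::write.csv(as.data.frame(samples), files[1], row.names = FALSE)
  utils::write.csv(as.data.frame(curve), files[2], row.names = FALSE)
  jsonlite::write_json(
    list(n_iter = n_iter, seed = seed,
         quadrant_proportions = as.list(quadrant_proportions(samples)),
         wtp_threshold = bundle$wtp$threshold,
         p_cg_cost_effective_at_threshold = at_threshold,
         ceac_50pct_crossing = ceac_crossing(curve, 0.5),
         n_resampled = attr(samples, "n_resampled"),
         currency = "2010 USD"),
    files[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(output_dir, "psa", files, seed = seed, bundle = bundle)
  invisible(samples)
}

#' Run and export the survival calibration
#'
#' @inheritParams run_base_case
#' @return The [calibrate_model()] result, invisibly.
#' @export
run_calibration <- function(config = NULL, output_dir) {
  bundle <- resolve_bundle(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibrate_model(bundle)
  f <- file.path(output_dir, "calibration.json")
  jsonlite::write_json(
    lapply(cal$arms, function(a) list(
      weibull_shape = a$pfs_params$shape,
      weibull_scale_months = a$pfs_params$scale,
      p_dp_death_per_cycle = a$p_dp_death,
      achieved_dp_ly = a$occupancy$ly_dp,
      median_pfs_months = a$occupancy$median_pfs)),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(output_dir, "calibrate", f, bundle = bundle)
  invisible(cal)
}

#' Simulate a pseudo trial and export IPD + Kaplan-Meier curves
#'
#' @inheritParams run_base_case
#' @param n_per_arm Patients per arm.
#' @param censor_time Administrative censoring time in months.
#' @param seed Integer seed.
#' @return The [generate_ipd()] table, invisibly.
#' @export
simulate_trial <- function(config = NULL, n_per_arm = 500, censor_time = 24,
                           seed = 1, output_dir) {
  bundle <- resolve_bundle(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  shape <- bundle$survival$weibull_shape
  ipd <- generate_ipd(
    params_by_arm = list(
      erlotinib = weibull_from_median(bundle$survival$median_pfs_erl, shape),
      cg = weibull_from_median(bundle$survival$median_pfs_cg, shape)),
    n_per_arm = n_per_arm, censor_time = censor_time, seed = seed)
  files <- file.path(output_dir,
                     c("ipd.csv", "km_erlotinib.csv", "km_cg.csv"))
  write_survival_csv(ipd, files[1])
  write_survival_csv(km_estimate(ipd, "erlotinib"), files[2])
  write_survival_csv(km_estimate(ipd, "cg"), files[3])
  write_manifest(output_dir, "simulate-trial", files, seed = seed,
                 bundle = bundle)
  invisible(ipd)
}
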