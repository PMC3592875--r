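# Flat-key JSON configuration I/O. Every scalar model input has one key;
# unknown keys are an error (misspelled overrides must not pass silently).

config_key_map <- function() {
  list(
    structure = c("cycle_length_days", "horizon_years",
                  "discount_rate_annual"),
    utilities = c("u_pfs_erlotinib", "u_pfs_cg", "u_dp"),
    costs = c("cg_tt_per_cycle", "cg_bsc_per_cycle", "erl_tt_per_cycle",
              "erl_after_donation_per_cycle", "admin_chemo_per_cycle",
              "blood_test_cg_per_cycle", "blood_test_erl_per_cycle",
              "dp_cost_per_cycle", "erl_unit_price_per_week",
              "dp_cost_basis", "include_blood_tests", "cg_bsc_blood_tests"),
    survival = c("median_pfs_erl", "median_pfs_cg",
                 "hazard_ratio_erl_vs_cg", "weibull_shape",
                 "target_dp_ly_erl", "target_dp_ly_cg", "use_hazard_ratio",
                 "p_pfs_death"),
    anchors = c("anchor_ly_pfs_erl", "anchor_ly_pfs_cg",
                "anchor_cost_pfs_erl", "anchor_cost_dp_erl",
                "anchor_cost_pfs_cg", "anchor_cost_dp_cg"),
    wtp = c("wtp_threshold", "wtp_grid"),
    adverse_events = c("ae_rate_neutropenia", "ae_rate_thrombocytopenia",
                       "ae_rate_anaemia", "ae_cost_neutropenia",
                       "ae_cost_thrombocytopenia", "ae_cost_anaemia")
  )
}

#' Load a parameter configuration file
#'
#' Reads a flat key/value JSON file and returns a validated parameter
#' bundle. Missing keys fall back to the published defaults; unknown keys
#' raise an error; values violating an invariant (e.g. a utility above 1)
#' raise a validation error naming the field.
#'
#' @param path Path to a JSON configuration file. An empty JSON object
#'   (`{}`) yields the default bundle.
#' @return A validated `param_bundle` (see [default_params()]).
#' @seealso [write_config()] for the inverse; the two round-trip exactly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("failed to parse config '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(cfg) == 0) cfg <- stats::setNames(list(), character())
  if (!is.list(cfg)) stop("config must be a JSON object", call. = FALSE)
  km <- config_key_map()
  known <- unlist(km, use.names = FALSE)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  take <- function(keys, strip = NULL) {
    got <- cfg[intersect(names(cfg), keys)]
    if (!is.null(strip)) names(got) <- sub(strip, "", names(got))
    # JSON whole numbers parse as integers; model inputs are doubles
    lapply(got, function(x) if (is.integer(x)) as.numeric(x) else x)
  }
  structure <- do.call(model_structure, take(km$structure))
  utilities <- do.call(utility_set, take(km$utilities))
  costs <- do.call(cost_params, take(km$costs))
  survival <- do.call(survival_inputs, take(km$survival))
  anchors <- do.call(base_case_anchors, take(km$anchors, "^anchor_"))
  wtp_args <- take(km$wtp, "^wtp_")
  names(wtp_args)[names(wtp_args) == "threshold"] <- "threshold"
  wtp <- do.call(wtp_config, wtp_args)

  ae <- adverse_event_profile()
  ae_over <- take(km$adverse_events)
  for (key in names(ae_over)) {
    field <- if (startsWith(key, "ae_rate_")) "rate" else "unit_cost"
    event <- sub("^ae_(rate|cost)_", "", key)
    ae$events[ae$events$name == event, field] <- ae_over[[key]]
  }
  ae <- adverse_event_profile(ae$events) # re-validate

  default_params(structure = structure, utilities = utilities,
                 costs = costs, adverse_events = ae, survival = survival,
                 anchors = anchors, wtp = wtp)
}

#' Write a parameter bundle as a flat-key configuration file
#'
#' Exports every scalar input of the bundle to JSON for provenance logging.
#' [load_config()] on the written file reproduces the bundle field for
#' field.
#'
#' @param bundle A `param_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path) {
  validate_bundle(bundle)
  s <- bundle$structure
  cfg <- list(
    cycle_length_days = s$cycle_length_days,
    horizon_years = s$horizon_years,
    discount_rate_annual = s$discount_rate_annual
  )
  cfg <- c(cfg, bundle$utilities[c("u_pfs_erlotinib", "u_pfs_cg", "u_dp")])
  cfg <- c(cfg, unclass(bundle$costs))
  cfg <- c(cfg, unclass(bundle$survival))
  a <- bundle$anchors
  names(a) <- paste0("anchor_", names(a))
  cfg <- c(cfg, a)
  cfg$wtp_threshold <- bundle$wtp$threshold
  cfg$wtp_grid <- bundle$wtp$grid
  ev <- bundle$adverse_events$events
  for (i in seq_len(nrow(ev))) {
    cfg[[paste0("ae_rate_", ev$name[i])]] <- ev$rate[i]
    cfg[[paste0("ae_cost_", ev$name[i])]] <- ev$unit_cost[i]
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
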