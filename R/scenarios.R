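# Scenario execution, qualitative outcome classification and parameter sweeps.

.pkg_cache <- new.env(parent = emptyenv())

.host_roles <- c("host_polymerase", "host_template")

.host_steady <- function(traj, window) {
  m <- nrow(traj$totals)
  idx <- seq.int(max(1L, m - ceiling(window * m) + 1L), m)
  steady <- colMeans(traj$totals[idx, , drop = FALSE])
  host <- traj$species$role %in% .host_roles
  list(steady = steady, host_total = sum(steady[host]), host = host)
}

# Cached host-cycle reference run (the two-species preset at its default
# horizon), used to scale the collapse threshold when no explicit reference
# trajectory is supplied.
.default_reference <- function() {
  ref <- .pkg_cache$model1_reference
  if (is.null(ref)) {
    ref <- integrate_model(build_preset("1"))
    .pkg_cache$model1_reference <- ref
  }
  ref
}

#' Classify the qualitative outcome of a finished run
#'
#' Operationalizes the qualitative habitat regimes as decision rules on the
#' late-time state. Steady totals are means over the final `window` fraction
#' of recorded samples; the host total sums the species with host roles. With
#' `H` the host steady total and `H_ref` the host steady total of the
#' two-species host-cycle reference (scaled by the ratio of host initial
#' concentrations):
#'
#' * `parasite_collapse` -- `H < collapse_frac * H_ref`;
#' * `fully_restored` -- an explicit `reference` trajectory was given and the
#'   relative host gap `|H - H_ref| / H_ref` is below `restore_tol`;
#' * `stabilized_parasites_prevalent` -- the host persists but a non-host
#'   species has the largest steady total;
#' * `sustained` -- otherwise.
#'
#' All thresholds are declared operational choices, exposed as arguments.
#'
#' @param traj a `trajectory` (at least 10 recorded samples).
#' @param spec the `model_spec` that generated it.
#' @param reference optional reference `trajectory` (typically the
#'   host-cycle preset) enabling the `fully_restored` rule. When omitted, the
#'   collapse threshold is scaled against an internally computed host-cycle
#'   reference run.
#' @param collapse_frac host-collapse threshold as a fraction of the
#'   reference host total.
#' @param restore_tol maximum relative host gap still counted as restored.
#' @param window fraction of final samples averaged into the steady totals.
#' @return object of class `outcome_summary`: steady totals, classification,
#'   `reference_gap` (NA without an explicit reference), `stationarity_norm`
#'   (max absolute rhs at the final state), `collapse_time` (first recorded
#'   time the host total crossed the collapse threshold, NA if never) and
#'   `host_steady`.
#' @export
classify_outcome <- function(traj, spec, reference = NULL,
                             collapse_frac = 0.05, restore_tol = 0.05,
                             window = 0.1) {
  m <- nrow(traj$totals)
  if (m < 10L) stop(sprintf("trajectory too short to classify (%d samples, need >= 10)", m))

  hs <- .host_steady(traj, window)
  ref_traj <- if (is.null(reference)) .default_reference() else reference
  rs <- .host_steady(ref_traj, window)

  # scale the reference by the ratio of host initial loads so that rescaled
  # scenarios compare against a comparable baseline
  ref_init <- sum(ref_traj$initials[ref_traj$species$role %in% .host_roles])
  own_init <- sum(traj$initials[traj$species$role %in% .host_roles])
  scale <- if (ref_init > 0) own_init / ref_init else 1
  ref_host <- rs$host_total * scale

  host_series <- rowSums(traj$totals[, hs$host, drop = FALSE])
  below <- which(host_series < collapse_frac * ref_host)
  collapse_time <- if (length(below) > 0) traj$times[below[1]] else NA_real_

  reference_gap <- if (is.null(reference)) NA_real_ else {
    abs(hs$host_total - ref_host) / ref_host
  }

  classification <- if (hs$host_total < collapse_frac * ref_host) {
    "parasite_collapse"
  } else if (!is.null(reference) && reference_gap < restore_tol) {
    "fully_restored"
  } else if (any(!hs$host) && max(hs$steady[!hs$host]) > max(hs$steady[hs$host])) {
    "stabilized_parasites_prevalent"
  } else {
    "sustained"
  }

  final_totals <- traj$totals[m, ]
  stationarity <- max(abs(model_rhs(spec, final_totals)))

  structure(list(
    steady_totals = hs$steady,
    classification = classification,
    reference_gap = reference_gap,
    stationarity_norm = stationarity,
    collapse_time = collapse_time,
    host_steady = hs$host_total,
    reference_host_steady = ref_host,
    thresholds = list(collapse_frac = collapse_frac,
                      restore_tol = restore_tol, window = window)
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %s\n", x$classification))
  cat("  steady totals:", paste(sprintf("%s = %.4g", names(x$steady_totals),
                                        x$steady_totals), collapse = ", "), "\n")
  cat(sprintf("  host steady total = %.4g (reference %.4g)\n",
              x$host_steady, x$reference_host_steady))
  if (!is.na(x$reference_gap)) cat(sprintf("  reference gap = %.3g\n", x$reference_gap))
  if (!is.na(x$collapse_time)) cat(sprintf("  collapse time = %g\n", x$collapse_time))
  cat(sprintf("  stationarity max|dR/dt| = %.3e\n", x$stationarity_norm))
  invisible(x)
}

#' Run a scenario end to end
#'
#' Builds the spec (preset id or configuration file), applies overrides,
#' integrates, classifies the outcome, and optionally writes the trajectory
#' CSV, an outcome-summary JSON and the resolved configuration YAML.
#'
#' @param model preset identifier (see [preset_ids()]); mutually exclusive
#'   with `config`.
#' @param config path to a configuration file readable by
#'   [read_model_config()].
#' @param overrides named list of parameter overrides applied through
#'   [set_spec_value()], e.g. `list(mu = 0, "kon[3,4]" = 1.0)`.
#' @param reference_model optional preset id integrated as the reference for
#'   the restoration rule (typically `"1"`).
#' @param record_every,record_complexes,tol passed to [integrate_model()].
#' @param out_prefix optional path prefix; writes `<prefix>.csv`,
#'   `<prefix>.summary.json` and `<prefix>.spec.yaml`.
#' @return (invisibly) list with `spec`, `trajectory` and `summary`.
#' @examples
#' \donttest{
#' res <- run_scenario("1")
#' res$summary$classification
#' }
#' @export
run_scenario <- function(model = NULL, config = NULL, overrides = list(),
                         reference_model = NULL, record_every = 10L,
                         record_complexes = FALSE, tol = 1e-12,
                         out_prefix = NULL) {
  if (is.null(model) == is.null(config)) {
    stop("supply exactly one of 'model' (preset id) or 'config' (file path)")
  }
  spec <- if (!is.null(model)) build_preset(model) else read_model_config(config)
  for (key in names(overrides)) {
    spec <- set_spec_value(spec, key, overrides[[key]])
  }
  traj <- integrate_model(spec, record_every = record_every,
                          record_complexes = record_complexes, tol = tol)
  reference <- if (!is.null(reference_model)) {
    integrate_model(build_preset(reference_model))
  } else NULL
  summary <- if (nrow(traj$totals) >= 10L) {
    classify_outcome(traj, spec, reference = reference)
  } else NULL

  if (!is.null(out_prefix)) {
    write_trajectory(traj, paste0(out_prefix, ".csv"))
    write_model_config(spec, paste0(out_prefix, ".spec.yaml"))
    if (!is.null(summary)) {
      js <- list(classification = summary$classification,
                 steady_totals = as.list(summary$steady_totals),
                 host_steady = summary$host_steady,
                 reference_host_steady = summary$reference_host_steady,
                 reference_gap = summary$reference_gap,
                 collapse_time = summary$collapse_time,
                 stationarity_norm = summary$stationarity_norm,
                 spec_fingerprint = traj$spec_fingerprint,
                 newton_max_iter = traj$stats$newton_max_iter,
                 clamp_events = traj$stats$clamp_events,
                 pi_negative_events = traj$stats$pi_negative_events)
      jsonlite::write_json(js, paste0(out_prefix, ".summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
    }
  }
  invisible(list(spec = spec, trajectory = traj, summary = summary))
}

#' Sweep one parameter across a set of values
#'
#' Runs the base model once per value of the addressed parameter and
#' tabulates the outcome, in the deterministic order of `values`.
#'
#' @param model preset identifier of the base model.
#' @param parameter parameter path understood by [set_spec_value()].
#' @param values numeric vector of values to try.
#' @param t_end optional horizon override applied to every run.
#' @param reference_model optional reference preset for classification.
#' @param record_every passed to [integrate_model()].
#' @return data frame with one row per value: the value, the classification,
#'   the host steady total, the collapse time and one `steady_<species>`
#'   column per species.
#' @examples
#' \donttest{
#' sweep_parameter("2.2", "alpha", c(0.001, 0.005, 0.01), t_end = 1000)
#' }
#' @export
sweep_parameter <- function(model, parameter, values, t_end = NULL,
                            reference_model = NULL, record_every = 10L) {
  rows <- lapply(values, function(v) {
    overrides <- setNames(list(v), parameter)
    if (!is.null(t_end)) overrides$t_end <- t_end
    res <- run_scenario(model, overrides = overrides,
                        reference_model = reference_model,
                        record_every = record_every)
    s <- res$summary
    out <- data.frame(value = v,
                      classification = s$classification,
                      host_steady = s$host_steady,
                      collapse_time = s$collapse_time,
                      stringsAsFactors = FALSE)
    st <- as.data.frame(as.list(s$steady_totals))
    names(st) <- paste0("steady_", names(s$steady_totals))
    cbind(out, st)
  })
  do.call(rbind, rows)
}
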