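#' Run the full trajectory-analysis pipeline
#'
#' Enforces the stage order of the analysis: minimum-duration filtering,
#' fixed-cell calibration, live-cell TAMSD, sub-noise trajectory removal,
#' sRg mobility classification, mobile-class Rayleigh-mixture
#' decomposition, and the corrected ensemble anomalous-exponent estimate.
#' Any stage failure aborts with the stage name. Outputs are deterministic
#' under a fixed seed.
#'
#' @param live Live-cell [spt_ensemble()].
#' @param fixed Fixed-cell [spt_ensemble()] used for calibration; or an
#'   `spt_calibration` already computed. Omitting both refuses to classify.
#' @param min_duration_s Duration filter cutoff in seconds.
#' @param n_max Frame-lag cap for live-cell TAMSD and fits.
#' @param fit_lag_range Lag range for live-cell power-law fits.
#' @param k_max Largest Rayleigh-mixture order for mobile trajectories.
#' @param max_mobile_fits Cap on the number of mobile trajectories given
#'   the per-trajectory mixture treatment (keeps desk-scale runs fast);
#'   `Inf` fits all.
#' @param seed Seed for the ensemble-exponent bootstrap and EM restarts.
#' @return A list of class `"spt_pipeline_result"` with elements
#'   `calibration`, `counts` (per-stage in/out bookkeeping),
#'   `classification`, `tamsd_fits`, `mobile_fits`, `ensemble_alpha`,
#'   `manifest`.
#' @export
run_pipeline <- function(live, fixed, min_duration_s = 20, n_max = 20,
                         fit_lag_range = c(1, 20), k_max = 4L,
                         max_mobile_fits = 500L, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  live <- stage("duration_filter", {
    out <- filter_min_duration(live, min_duration_s)
    counts$duration_filter <- c(n_in = length(live), n_out = length(out))
    out
  })

  calibration <- stage("calibration", {
    if (missing(fixed) || is.null(fixed))
      stop("no calibration input: supply fixed-cell trajectories or an ",
           "spt_calibration object")
    if (inherits(fixed, "spt_calibration")) fixed
    else calibrate_fixed_cells(filter_min_duration(fixed, min_duration_s))
  })

  curves <- stage("tamsd", ensemble_tamsd(live, n_max = n_max))

  live <- stage("subnoise_removal", {
    out <- remove_subnoise_trajectories(live, calibration$epsilon,
                                        n_max = n_max)
    counts$subnoise_removal <- c(n_in = length(curves),
                                  n_out = length(out),
                                  n_removed = attr(out, "n_removed"))
    curves <- curves[names(out$trajectories)]
    out
  })

  classification <- stage("classification",
                          classify_mobility(live, calibration))

  tamsd_fits <- stage("powerlaw_fits",
                      fit_power_laws(curves, lag_range = fit_lag_range))

  mobile_ids <- classification$table$traj_id[
    classification$table$label == "mobile"]
  mobile_fits <- stage("mobile_heterogeneity", {
    ids <- utils::head(mobile_ids, max_mobile_fits)
    lapply(live$trajectories[ids], function(tr) {
      fit_mobility_states(tr, k_max = k_max, seed = seed)$selected
    })
  })

  ensemble_alpha <- stage("ensemble_alpha", {
    mob_curves <- curves[mobile_ids]
    if (length(mob_curves) >= 2L)
      ensemble_alpha_estimate(mob_curves, epsilon = calibration$epsilon,
                              fit_lag_range = fit_lag_range, seed = seed)
    else NULL
  })

  manifest <- run_manifest(
    command = "run_pipeline",
    params = list(min_duration_s = min_duration_s, n_max = n_max,
                  fit_lag_range = fit_lag_range, k_max = k_max,
                  max_mobile_fits = max_mobile_fits),
    seeds = list(seed = seed))

  structure(list(calibration = calibration, counts = counts,
                 classification = classification,
                 tamsd_fits = tamsd_fits,
                 mobile_fits = mobile_fits,
                 ensemble_alpha = ensemble_alpha,
                 manifest = manifest),
            class = "spt_pipeline_result")
}

#' @export
print.spt_pipeline_result <- function(x, ...) {
  cat("<spt_pipeline_result>\n")
  print(x$calibration)
  print(x$classification)
  if (!is.null(x$ensemble_alpha)) print(x$ensemble_alpha)
  invisible(x)
}
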