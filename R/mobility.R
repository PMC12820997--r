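#' Scaled radius of gyration of a trajectory
#'
#' `sRg = sqrt(pi/2) * Rg / <r>`, where `Rg` is the root-mean-squared
#' distance of the observed positions from their centroid (arithmetic mean
#' of the non-gap positions) and `<r>` is the mean Euclidean length of
#' steps between consecutive non-gap frames (steps across gaps are
#' skipped). For positions that are pure isotropic Gaussian localization
#' noise, sRg has expectation close to 1 regardless of the noise
#' magnitude, which is what makes it a calibration-free mobility statistic.
#'
#' @param traj An [spt_trajectory()] with >= 2 non-gap positions and >= 1
#'   valid consecutive step.
#' @return One-row data.frame `traj_id,Rg,mean_step,sRg,degenerate`;
#'   `sRg` is `NA` and `degenerate` `TRUE` when all points coincide
#'   (`<r> = 0`).
#' @export
scaled_radius_of_gyration <- function(traj) {
  ok <- !is.na(traj$x)
  x <- traj$x[ok]; y <- traj$y[ok]
  if (length(x) < 2L) stop("need >= 2 non-gap positions")
  pair <- ok[-1L] & ok[-length(ok)]
  if (!any(pair)) stop("no valid consecutive step")
  rg <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
  r <- sqrt(diff(traj$x)[pair]^2 + diff(traj$y)[pair]^2)
  mean_step <- mean(r)
  if (mean_step == 0) {
    srg <- NA_real_
    degenerate <- TRUE
  } else {
    srg <- sqrt(pi / 2) * rg / mean_step
    degenerate <- FALSE
  }
  data.frame(traj_id = attr(traj, "id"), Rg = rg, mean_step = mean_step,
             sRg = srg, degenerate = degenerate)
}

#' sRg table for an ensemble
#' @param ensemble An [spt_ensemble()].
#' @return data.frame with one row per trajectory plus session/condition
#'   metadata columns.
#' @export
srg_table <- function(ensemble) {
  out <- do.call(rbind, lapply(ensemble$trajectories, function(tr) {
    cbind(scaled_radius_of_gyration(tr),
          cell_id = attr(tr, "cell_id"),
          session_id = attr(tr, "session_id"),
          condition = attr(tr, "condition"))
  }))
  rownames(out) <- NULL
  out
}

#' Classify trajectories as mobile or immobile
#'
#' A trajectory is labelled `mobile` iff its sRg strictly exceeds the
#' calibrated threshold; the boundary and degenerate (zero mean step)
#' trajectories are labelled `immobile`, since the threshold is the 95th
#' percentile of immobile-like spread.
#'
#' @param ensemble An [spt_ensemble()].
#' @param calibration An `spt_calibration` (see [calibrate_fixed_cells()])
#'   or a single numeric threshold.
#' @return A list of class `"spt_classification"`: `table`
#'   (`traj_id,sRg,label,...`), `counts` (mobile/immobile), and
#'   `by_session` counts.
#' @export
classify_mobility <- function(ensemble, calibration) {
  thr <- if (is.numeric(calibration)) calibration else calibration$srg_threshold
  stopifnot(is.finite(thr), thr > 0)
  tab <- srg_table(ensemble)
  tab$label <- ifelse(!is.na(tab$sRg) & tab$sRg > thr, "mobile", "immobile")
  counts <- c(mobile = sum(tab$label == "mobile"),
              immobile = sum(tab$label == "immobile"))
  by_session <- as.data.frame(table(session_id = tab$session_id,
                                    label = tab$label))
  structure(list(table = tab, counts = counts, by_session = by_session,
                 threshold = thr),
            class = "spt_classification")
}

#' @export
print.spt_classification <- function(x, ...) {
  cat(sprintf("<spt_classification> threshold %.4f: %d mobile / %d immobile\n",
              x$threshold, x$counts["mobile"], x$counts["immobile"]))
  invisible(x)
}

.or_strata_matrix <- function(strata) {
  need <- c("treated_mobile", "treated_immobile",
            "control_mobile", "control_immobile")
  stopifnot(all(need %in% names(strata)))
  m <- as.matrix(strata[, need])
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0)) stop("every stratum needs a nonzero margin")
  m
}

#' Mantel-Haenszel common odds ratio over session strata
#'
#' For strata with cells a = treated mobile, b = treated immobile,
#' c = control mobile, d = control immobile and totals n, the common OR is
#' `sum(a d / n) / sum(b c / n)`. The 95% CI uses the
#' Robins-Breslow-Greenland variance of the log OR and the p-value comes
#' from the Mantel-Haenszel chi-square (1 df, no continuity correction).
#'
#' @param strata data.frame with columns
#'   `treated_mobile,treated_immobile,control_mobile,control_immobile` (and
#'   optionally `session_id`), one row per experimental session.
#' @return A list of class `"spt_or"`: `common_or`, `ci95`, `p_value`,
#'   `method`, `n_strata`.
#' @export
mantel_haenszel_or <- function(strata) {
  m <- .or_strata_matrix(strata)
  a <- m[, 1L]; b <- m[, 2L]; cc <- m[, 3L]; d <- m[, 4L]
  n <- a + b + cc + d
  R <- a * d / n
  S <- b * cc / n
  sumR <- sum(R); sumS <- sum(S)

  # MH chi-square on the treated-mobile cell
  Ea <- (a + b) * (a + cc) / n
  Va <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  Va[!is.finite(Va)] <- 0
  chi <- (sum(a) - sum(Ea))^2 / sum(Va)
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)

  if (sumS == 0) {
    # infinite estimate: no finite upper bound
    return(structure(list(common_or = Inf, ci95 = c(NA_real_, Inf),
                          p_value = p, method = "session-stratified MH",
                          n_strata = nrow(m)),
                     class = "spt_or"))
  }
  or <- sumR / sumS
  P <- (a + d) / n
  Q <- (b + cc) / n
  var_log <- sum(P * R) / (2 * sumR^2) +
    sum(P * S + Q * R) / (2 * sumR * sumS) +
    sum(Q * S) / (2 * sumS^2)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_log))
  structure(list(common_or = or, ci95 = ci, p_value = p,
                 method = "session-stratified MH", n_strata = nrow(m)),
            class = "spt_or")
}

#' Treated-weighted common odds ratio against a pooled control
#'
#' For treatments lacking session-matched controls, each session's OR is
#' computed against the pooled control counts and the common estimate is
#' the exponential of the weighted mean of log ORs, weighted by each
#' session's total treated trajectory count. The CI uses the weighted
#' delta-method variance of the log OR; because the same pooled control
#' enters every session's OR, its variance contribution enters once, in
#' full, rather than being diluted by the weights. Sessions with a zero
#' cell get a +0.5 continuity correction on all four cells (recorded in
#' the result).
#'
#' @param treated data.frame with columns `mobile,immobile` (and optionally
#'   `session_id`), one row per treated session.
#' @param pooled_control Numeric `c(mobile, immobile)` for the pooled
#'   control group (both nonzero).
#' @return A list of class `"spt_or"` with `method = "treated-weighted"`.
#' @export
weighted_or <- function(treated, pooled_control) {
  stopifnot(all(c("mobile", "immobile") %in% names(treated)),
            length(pooled_control) == 2L, all(pooled_control > 0))
  a <- treated$mobile; b <- treated$immobile
  cm <- pooled_control[1L]; ci_ <- pooled_control[2L]
  corrected <- a == 0 | b == 0
  lo <- var_treated <- numeric(length(a))
  for (i in seq_along(a)) {
    aa <- a[i]; bb <- b[i]; cc <- cm; dd <- ci_
    if (corrected[i]) {
      aa <- aa + 0.5; bb <- bb + 0.5; cc <- cc + 0.5; dd <- dd + 0.5
    }
    lo[i] <- log((aa / bb) / (cc / dd))
    var_treated[i] <- 1 / aa + 1 / bb
  }
  w <- a + b
  est <- sum(w * lo) / sum(w)
  # the pooled control is common to all sessions, so its term enters once
  var_est <- sum(w^2 * var_treated) / sum(w)^2 + 1 / cm + 1 / ci_
  ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_est))
  z <- est / sqrt(var_est)
  structure(list(common_or = exp(est), ci95 = ci,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 method = "treated-weighted",
                 n_strata = length(a),
                 continuity_corrected = which(corrected)),
            class = "spt_or")
}

#' @export
print.spt_or <- function(x, ...) {
  cat(sprintf("<spt_or> %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d strata\n",
              x$method, x$common_or, x$ci95[1], x$ci95[2], x$p_value,
              x$n_strata))
  invisible(x)
}
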