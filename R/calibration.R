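#' Two-component Gaussian mixture on fitted anomalous exponents
#'
#' Fits a two-component univariate Gaussian mixture to the distribution of
#' per-trajectory power-law exponents from fixed-cell data, assigns each
#' trajectory to a component by posterior >= 0.5, and returns the members
#' of the lower-mean component — the trajectories consistent with a flat,
#' noise-dominated TAMSD (alpha near 0).
#'
#' Two degeneracy guards keep the selection honest on unimodal data: the
#' one- and two-component models are compared by BIC and a one-component
#' winner keeps the whole sample; and even when two components are fitted,
#' a mean separation at most twice the larger component SD — the
#' unimodality bound for an equal-variance two-Gaussian mixture — means the
#' fit split one population in half, so the whole sample is treated as the
#' lower-mean component (`merged = TRUE`). This matches the expectation
#' that most fixed-cell trajectories are consistent with pure localization
#' noise.
#'
#' @param alphas Numeric vector of fitted exponents (>= 20 values).
#' @return List: `means`, `sds`, `weights` (mixture parameters, component 1
#'   is the lower mean), `selected` (logical membership of the lower-mean
#'   component), `posterior`, `merged` (overlap degeneracy, see above),
#'   `fallback` (TRUE when a degenerate input forced a single-component
#'   description).
#' @export
fit_alpha_gmm <- function(alphas) {
  stopifnot(length(alphas) >= 20L)
  if (stats::sd(alphas) < 1e-12) {
    return(list(means = rep(alphas[1L], 2L), sds = c(0, 0),
                weights = c(0.5, 0.5),
                selected = rep(TRUE, length(alphas)),
                posterior = rep(1, length(alphas)),
                merged = TRUE, fallback = TRUE))
  }
  fit <- tryCatch(
    suppressWarnings(Mclust(alphas, G = 1:2, modelNames = c("V", "E"),
                            verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(means = rep(mean(alphas), 2L),
                sds = rep(stats::sd(alphas), 2L), weights = c(0.5, 0.5),
                selected = rep(TRUE, length(alphas)),
                posterior = rep(1, length(alphas)),
                merged = TRUE, fallback = TRUE))
  }
  if (fit$G == 1L) {
    mu <- unname(fit$parameters$mean)
    sig <- sqrt(unname(fit$parameters$variance$sigmasq))
    return(list(means = rep(mu, 2L), sds = rep(sig, 2L),
                weights = c(1, 0),
                selected = rep(TRUE, length(alphas)),
                posterior = rep(1, length(alphas)),
                merged = TRUE, fallback = FALSE))
  }
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  pro <- fit$parameters$pro
  low <- which.min(mu)
  ord <- c(low, setdiff(1:2, low))
  post_low <- fit$z[, low]
  merged <- abs(diff(mu)) <= 2 * max(sig)
  list(means = unname(mu[ord]), sds = unname(sig[ord]),
       weights = unname(pro[ord]),
       selected = if (merged) rep(TRUE, length(alphas)) else post_low >= 0.5,
       posterior = post_low, merged = merged, fallback = FALSE)
}

#' Semiparametric two-component kernel mixture on power-law coefficients
#'
#' EM for a two-component mixture whose component densities are weighted
#' kernel density estimates (Gaussian kernel, Silverman bandwidth on the
#' working sample), run on log-transformed K_alpha values (positive and
#' right-skewed). The E-step takes responsibilities from the current
#' weighted KDEs; the M-step reweights. Returns the members of the
#' lower-mean component.
#'
#' As in [fit_alpha_gmm()], a component-overlap degeneracy rule applies:
#' when the two component means end up within one kernel bandwidth of each
#' other on the log scale, the sample is treated as a single (lower-mean)
#' population and everything is selected (`merged = TRUE`).
#'
#' @param kalphas Positive power-law coefficients (>= 20 values).
#' @param bw Kernel bandwidth on the log scale; default Silverman
#'   ([stats::bw.nrd0()]).
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   mixing weights.
#' @return List: `weights`, `component_means` (on the K_alpha scale,
#'   component 1 is the lower mean), `selected` (logical), `responsibility`
#'   (of the lower-mean component), `merged`, `bw`, `n_iter`.
#' @export
fit_kalpha_kernel_mixture <- function(kalphas, bw = NULL, max_iter = 200L,
                                      tol = 1e-8) {
  stopifnot(length(kalphas) >= 20L)
  if (any(kalphas <= 0)) stop("K_alpha values must be positive")
  x <- log(kalphas)
  n <- length(x)
  if (is.null(bw)) bw <- stats::bw.nrd0(x)
  if (bw <= 0) bw <- 1e-6
  K <- exp(-outer(x, x, "-")^2 / (2 * bw^2)) / (sqrt(2 * pi) * bw)

  # deterministic init: split at the median
  g1 <- as.numeric(x <= stats::median(x))
  g1 <- pmin(pmax(g1, 0.05), 0.95)
  lambda <- c(mean(g1), 1 - mean(g1))
  it <- 0L
  repeat {
    it <- it + 1L
    w1 <- g1 / sum(g1)
    w2 <- (1 - g1) / sum(1 - g1)
    f1 <- as.vector(K %*% w1)
    f2 <- as.vector(K %*% w2)
    num1 <- lambda[1L] * f1
    g1_new <- num1 / (num1 + lambda[2L] * f2)
    lambda_new <- c(mean(g1_new), 1 - mean(g1_new))
    delta <- max(abs(lambda_new - lambda))
    g1 <- g1_new
    lambda <- lambda_new
    if (delta < tol || it >= max_iter) break
  }
  m1 <- sum(g1 * x) / sum(g1)
  m2 <- sum((1 - g1) * x) / sum(1 - g1)
  if (m1 <= m2) {
    resp_low <- g1
    weights <- lambda
    means <- exp(c(m1, m2))
  } else {
    resp_low <- 1 - g1
    weights <- rev(lambda)
    means <- exp(c(m2, m1))
  }
  merged <- abs(m1 - m2) < bw
  list(weights = weights, component_means = means,
       selected = if (merged) rep(TRUE, n) else resp_low >= 0.5,
       responsibility = resp_low, merged = merged,
       bw = bw, n_iter = it)
}

#' Localization-error level from the joint (K_alpha, alpha) density
#'
#' A 2D Gaussian-kernel density estimate on (log K_alpha, alpha) over a
#' regular 256 x 256 grid spanning the data range plus three bandwidths;
#' the localization-error TAMSD level epsilon is the K_alpha value at the
#' density mode. Ties are broken toward lower K_alpha.
#'
#' @param kalphas,alphas Selected fixed-cell fit results (>= 20 pairs).
#' @param grid_n Grid resolution per axis.
#' @return List: `epsilon` (um^2), `mode_alpha`, `bandwidths`, `grid_n`.
#' @export
estimate_localization_error <- function(kalphas, alphas, grid_n = 256L) {
  stopifnot(length(kalphas) == length(alphas), length(kalphas) >= 20L)
  if (any(kalphas <= 0)) stop("K_alpha values must be positive")
  lk <- log(kalphas)
  bw <- c(tryCatch(MASS::bandwidth.nrd(lk), error = function(e) 0),
          tryCatch(MASS::bandwidth.nrd(alphas), error = function(e) 0))
  bw[bw <= 0] <- 1e-3
  lims <- c(range(lk) + c(-3, 3) * bw[1L] / 4,
            range(alphas) + c(-3, 3) * bw[2L] / 4)
  dens <- MASS::kde2d(lk, alphas, h = bw, n = grid_n, lims = lims)
  best <- which(dens$z == max(dens$z), arr.ind = TRUE)
  best <- best[order(best[, 1L]), , drop = FALSE][1L, ]  # lower K_alpha wins
  list(epsilon = exp(dens$x[best[1L]]),
       mode_alpha = dens$y[best[2L]],
       bandwidths = bw, grid_n = grid_n)
}

#' sRg mobility threshold from selected fixed-cell trajectories
#'
#' The 95th percentile (linear-interpolation quantile) of the sRg values.
#'
#' @param srg Numeric sRg values (>= 20).
#' @param probs Percentile to use (default 0.95).
#' @return The threshold.
#' @export
compute_srg_threshold <- function(srg, probs = 0.95) {
  stopifnot(length(srg) >= 20L)
  unname(stats::quantile(srg, probs, type = 7, na.rm = TRUE))
}

#' Fixed-cell calibration of localization error and mobility threshold
#'
#' Runs the full fixed-cell calibration: per-trajectory TAMSD over one
#' decade of lags and power-law fits over lags 2-4 (lag 1 is
#' noise-dominated); a two-component Gaussian mixture over the exponents,
#' keeping the lower-mean subpopulation; a two-component kernel mixture
#' over the surviving K_alpha values, keeping the lower-mean
#' subpopulation; the localization-error level epsilon as the K_alpha at
#' the joint (log K_alpha, alpha) density mode; and the sRg mobility
#' threshold as the 95th percentile of the selected trajectories' sRg.
#'
#' @param ensemble Fixed-cell [spt_ensemble()].
#' @param n_max Frame-lag decade for the TAMSD (default 10).
#' @param fit_lag_range Lag range of the power-law fit (default 2-4).
#' @return A list of class `"spt_calibration"`: `epsilon`,
#'   `srg_threshold`, `alpha_mixture`, `kalpha_mixture`, `n_selected`,
#'   `n_input`, `settings`.
#' @export
calibrate_fixed_cells <- function(ensemble, n_max = 10,
                                  fit_lag_range = c(2, 4)) {
  curves <- ensemble_tamsd(ensemble, n_max = n_max)
  fits <- fit_power_laws(curves, lag_range = fit_lag_range)

  gmm <- fit_alpha_gmm(fits$alpha)
  sub <- fits[gmm$selected, , drop = FALSE]
  km <- fit_kalpha_kernel_mixture(sub$K_alpha)
  sel <- sub[km$selected, , drop = FALSE]

  loc <- estimate_localization_error(sel$K_alpha, sel$alpha)

  sel_ens <- ensemble[match(sel$traj_id, names(ensemble$trajectories))]
  srg <- srg_table(sel_ens)$sRg
  thr <- compute_srg_threshold(srg)

  structure(list(epsilon = loc$epsilon,
                 srg_threshold = thr,
                 alpha_mixture = gmm[c("means", "sds", "weights")],
                 kalpha_mixture = km[c("weights", "component_means", "bw")],
                 mode_alpha = loc$mode_alpha,
                 n_selected = nrow(sel),
                 n_input = length(ensemble),
                 fits = fits,
                 selected_ids = sel$traj_id,
                 settings = list(n_max = n_max,
                                 fit_lag_range = fit_lag_range,
                                 kde_grid = loc$grid_n,
                                 srg_percentile = 0.95)),
            class = "spt_calibration")
}

#' @export
print.spt_calibration <- function(x, ...) {
  cat(sprintf(paste0("<spt_calibration> epsilon %.4g um^2, sRg threshold ",
                     "%.3f (%d/%d trajectories selected)\n"),
              x$epsilon, x$srg_threshold, x$n_selected, x$n_input))
  invisible(x)
}
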