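#' Step-vector representation of a trajectory
#'
#' Steps are taken only between consecutive non-gap frames (a step across a
#' gap would conflate two displacements).
#'
#' @param traj An [spt_trajectory()].
#' @return data.frame `dx,dy,r` (micrometres) with attribute `traj_id`;
#'   zero rows when no valid step exists.
#' @export
extract_steps <- function(traj) {
  ok <- !is.na(traj$x)
  if (sum(ok) < 2L) stop("need >= 2 non-gap positions")
  pair <- ok[-1L] & ok[-length(ok)]
  dx <- diff(traj$x)[pair]
  dy <- diff(traj$y)[pair]
  structure(data.frame(dx = dx, dy = dy, r = sqrt(dx^2 + dy^2)),
            traj_id = attr(traj, "id"))
}

#' Scale step components by their per-axis root mean square
#'
#' Divides each axis by its own RMS over the trajectory, removing the
#' dependence of the step distribution on the individual diffusion
#' coefficient; after scaling the RMS of each axis is exactly 1.
#'
#' @param steps A [extract_steps()] data.frame with >= 1 nonzero component
#'   per axis.
#' @return The input with added columns `dxs,dys` (scaled components).
#' @export
scale_steps <- function(steps) {
  rms_x <- sqrt(mean(steps$dx^2))
  rms_y <- sqrt(mean(steps$dy^2))
  if (rms_x == 0 || rms_y == 0)
    stop("zero RMS axis; trajectory excluded from step scaling")
  steps$dxs <- steps$dx / rms_x
  steps$dys <- steps$dy / rms_y
  steps
}

#' Pooled scaled steps of the mobile class
#'
#' Extracts, scales and pools the 1D step components (both axes together)
#' across an ensemble, skipping trajectories with a zero-RMS axis.
#'
#' @param ensemble An [spt_ensemble()].
#' @return Numeric vector of pooled scaled step components.
#' @export
pooled_scaled_steps <- function(ensemble) {
  unlist(lapply(ensemble$trajectories, function(tr) {
    s <- tryCatch(scale_steps(extract_steps(tr)), error = function(e) NULL)
    if (is.null(s)) return(numeric(0))
    c(s$dxs, s$dys)
  }), use.names = FALSE)
}

#' Single-Gaussian and two-Gaussian models of the pooled step distribution
#'
#' The single Gaussian uses the sample mean and variance; the two-component
#' mixture is a maximum-likelihood Gaussian mixture fit. Comparing their
#' log-likelihoods quantifies the deviation of the pooled scaled steps from
#' Brownian (single-Gaussian) behaviour.
#'
#' @param steps Numeric vector of pooled scaled step components (>= 1000
#'   recommended).
#' @return A list of class `"spt_step_models"`: `single` (mean, var,
#'   loglik), `mixture` (weights, means, vars, loglik).
#' @export
fit_step_gaussians <- function(steps) {
  stopifnot(length(steps) >= 10L)
  m <- mean(steps)
  # ML variance (divide by n), so the two models are compared consistently
  v <- mean((steps - m)^2)
  ll1 <- sum(stats::dnorm(steps, m, sqrt(v), log = TRUE))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(steps, G = 2L, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || fit$loglik < ll1) {
    # the single Gaussian is nested in the mixture family, so an EM local
    # optimum below it is replaced by the nested solution itself
    mixture <- list(weights = c(1, 0), means = c(m, m), vars = c(v, v),
                    loglik = ll1)
  } else {
    mixture <- list(weights = unname(fit$parameters$pro),
                    means = unname(fit$parameters$mean),
                    vars = unname(fit$parameters$variance$sigmasq),
                    loglik = fit$loglik)
  }
  structure(list(single = list(mean = m, var = v, loglik = ll1),
                 mixture = mixture),
            class = "spt_step_models")
}

# normalized Rayleigh density
.drayleigh <- function(r, sigma) (r / sigma^2) * exp(-r^2 / (2 * sigma^2))

#' Rayleigh mixture fit of a trajectory's step lengths
#'
#' Maximum-likelihood fit of a k-component Rayleigh mixture to 2D step
#' lengths by EM: responsibilities from the normalized component densities
#' `(r/sigma_i^2) exp(-r^2 / (2 sigma_i^2))`, closed-form M-step
#' `sigma_i^2 = sum(gamma r^2) / (2 sum(gamma))`, multiple restarts with
#' quantile-spread initial sigmas. For `k = 1` the EM solution equals the
#' closed-form MLE `sigma^2 = sum(r^2) / (2 n)`. Components are reported
#' with sigmas ascending; each maps to an apparent diffusion coefficient
#' `D_i = sigma_i^2 / (2 dt)`. The AIC counts `2k - 1` free parameters
#' (k sigmas, k - 1 proportions).
#'
#' @param r Step lengths in micrometres (>= 200 recommended; the 20 s
#'   duration filter guarantees this for retained trajectories).
#' @param k Number of components (1-4).
#' @param dt Frame interval in seconds.
#' @param n_restarts EM restarts (default 10; restart 1 is deterministic,
#'   later ones jitter the initial sigmas).
#' @param tol,max_iter EM convergence tolerance on the log-likelihood and
#'   iteration cap.
#' @param seed Optional seed for the restart jitter.
#' @return A list of class `"spt_rayleigh_fit"`: `k`, `p`, `sigma`, `D`,
#'   `loglik`, `aic`, `converged`, `n_steps`, `degraded_to` (NULL, or the
#'   smaller k actually fitted when a component emptied out).
#' @export
fit_rayleigh_mixture <- function(r, k, dt, n_restarts = 10L, tol = 1e-8,
                                 max_iter = 500L, seed = NULL) {
  stopifnot(k >= 1L, k <= 4L, all(r >= 0), dt > 0)
  r <- r[r > 0]  # zero-length steps carry no density mass
  n <- length(r)
  if (n < 2L * k) stop("too few steps for ", k, " components")
  if (!is.null(seed)) set.seed(seed)

  if (k == 1L) {
    s2 <- sum(r^2) / (2 * n)
    ll <- sum(log(.drayleigh(r, sqrt(s2))))
    return(structure(list(k = 1L, p = 1, sigma = sqrt(s2),
                          D = s2 / (2 * dt), loglik = ll,
                          aic = 2 * 1 - 2 * ll, converged = TRUE,
                          n_steps = n, degraded_to = NULL),
                     class = "spt_rayleigh_fit"))
  }

  # sigma init from spread quantiles of r (Rayleigh mean = sigma sqrt(pi/2))
  base_sigma <- stats::quantile(r, probs = (seq_len(k) - 0.5) / k,
                                names = FALSE) / sqrt(pi / 2)
  base_sigma <- pmax(base_sigma, 1e-9)

  run_em <- function(sig) {
    p <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(i) p[i] * .drayleigh(r, sig[i]),
                     numeric(n))
      tot <- rowSums(dens)
      if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      if (ll < ll_old - 1e-6) return(NULL)  # EM must not decrease
      gam <- dens / tot
      p <- colMeans(gam)
      sig2 <- colSums(gam * r^2) / (2 * colSums(gam))
      if (any(!is.finite(sig2)) || any(sig2 < 1e-18)) return(NULL)
      sig <- sqrt(sig2)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(p = p, sigma = sig, loglik = ll)
  }

  best <- NULL
  for (s in seq_len(n_restarts)) {
    sig0 <- if (s == 1L) base_sigma
            else base_sigma * exp(stats::runif(k, -0.7, 0.7))
    res <- run_em(sort(sig0))
    if (!is.null(res) && (is.null(best) || res$loglik > best$loglik))
      best <- res
  }
  if (is.null(best) || any(best$p < 1 / n)) {
    # component collapse: refit with one fewer component
    sub <- fit_rayleigh_mixture(r, k - 1L, dt, n_restarts = n_restarts,
                                tol = tol, max_iter = max_iter)
    sub$degraded_to <- sub$k
    return(sub)
  }
  ord <- order(best$sigma, best$p)
  p <- best$p[ord]; sig <- best$sigma[ord]
  structure(list(k = k, p = p, sigma = sig, D = sig^2 / (2 * dt),
                 loglik = best$loglik,
                 aic = 2 * (2 * k - 1) - 2 * best$loglik,
                 converged = TRUE, n_steps = n, degraded_to = NULL),
            class = "spt_rayleigh_fit")
}

#' @export
print.spt_rayleigh_fit <- function(x, ...) {
  cat(sprintf("<spt_rayleigh_fit> k = %d, AIC = %.2f\n", x$k, x$aic))
  for (i in seq_len(x$k))
    cat(sprintf("  p = %.3f, sigma = %.4g um, D = %.4g um^2/s\n",
                x$p[i], x$sigma[i], x$D[i]))
  invisible(x)
}

#' AIC step-down selection among Rayleigh mixture fits
#'
#' Starts at the fit with minimum AIC; while the next-simpler converged
#' model's AIC exceeds the current one by less than 4, steps down to it.
#' This parsimony rule prefers fewer mobility states unless the extra
#' component earns at least 4 AIC units.
#'
#' @param fits List of `spt_rayleigh_fit` objects (one per candidate k;
#'   non-converged entries may be omitted or `NULL`).
#' @return The selected `spt_rayleigh_fit`, with `selected = TRUE` added.
#' @export
select_k <- function(fits) {
  fits <- Filter(function(f) !is.null(f) && isTRUE(f$converged), fits)
  if (!length(fits)) stop("no converged fits to select among")
  ks <- vapply(fits, function(f) f$k, integer(1))
  fits <- fits[order(ks)]
  ks <- sort(ks)
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  j <- which.min(aic)
  while (j > 1L && aic[j - 1L] - aic[j] < 4) j <- j - 1L
  out <- fits[[j]]
  out$selected <- TRUE
  out
}

#' Fit and select Rayleigh mixtures k = 1..k_max for one trajectory
#'
#' @param traj An [spt_trajectory()] (or a numeric vector of step lengths).
#' @param dt Frame interval in seconds (taken from the trajectory when one
#'   is given).
#' @param k_max Largest candidate component count (default 4).
#' @param ... Passed to [fit_rayleigh_mixture()].
#' @return List with `fits` (all candidates, indexed by k) and `selected`
#'   (the [select_k()] winner).
#' @export
fit_mobility_states <- function(traj, dt = NULL, k_max = 4L, ...) {
  if (inherits(traj, "spt_trajectory")) {
    r <- extract_steps(traj)$r
    dt <- attr(traj, "dt")
  } else {
    r <- traj
    if (is.null(dt)) stop("dt required when passing raw step lengths")
  }
  fits <- lapply(seq_len(k_max), function(k) {
    tryCatch(fit_rayleigh_mixture(r, k, dt, ...), error = function(e) NULL)
  })
  list(fits = fits, selected = select_k(fits))
}

#' Joint distribution of mixing proportion and apparent D across trajectories
#'
#' For every two-component fit, takes the (proportion, apparent D) pair of
#' the requested mobility state (slow/fast by ascending sigma) and builds a
#' joint Gaussian kernel density estimate on (proportion, log10 D).
#'
#' @param fits List of selected `spt_rayleigh_fit` objects.
#' @param component `"slow"` or `"fast"`.
#' @param noise_D Optional noise-equivalent diffusion coefficient
#'   (um^2/s); when given, the fraction of trajectories whose component D
#'   falls below it is reported.
#' @param grid_n KDE grid resolution.
#' @return List of class `"spt_population_summary"`: `points` (data.frame
#'   `proportion,D`), `kde` ([MASS::kde2d()] grid on proportion vs
#'   log10 D), `mode` (c(proportion, D) at the density mode),
#'   `frac_below_noise` (or `NA`), `n`.
#' @export
population_summary <- function(fits, component = c("slow", "fast"),
                               noise_D = NULL, grid_n = 128L) {
  component <- match.arg(component)
  two <- Filter(function(f) f$k == 2L, fits)
  if (length(two) < 20L)
    stop("need >= 20 two-component trajectories, got ", length(two))
  idx <- if (component == "slow") 1L else 2L
  pts <- data.frame(
    proportion = vapply(two, function(f) f$p[idx], numeric(1)),
    D = vapply(two, function(f) f$D[idx], numeric(1)))
  lD <- log10(pts$D)
  bw <- c(tryCatch(MASS::bandwidth.nrd(pts$proportion),
                   error = function(e) 0),
          tryCatch(MASS::bandwidth.nrd(lD), error = function(e) 0))
  bw[bw <= 0 | !is.finite(bw)] <- 1e-2
  kde <- MASS::kde2d(pts$proportion, lD, h = bw, n = grid_n)
  best <- which(kde$z == max(kde$z), arr.ind = TRUE)[1L, ]
  structure(list(points = pts, kde = kde,
                 mode = c(proportion = kde$x[best[1L]],
                          D = 10^kde$y[best[2L]]),
                 frac_below_noise = if (is.null(noise_D)) NA_real_
                                    else mean(pts$D < noise_D),
                 n = nrow(pts), component = component),
            class = "spt_population_summary")
}
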