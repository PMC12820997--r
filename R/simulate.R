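#' Simulation configuration
#'
#' Shared settings for the trajectory simulators. Defaults mirror the
#' acquisition geometry the analysis assumes: 10 frames/s (`dt = 0.1` s) and
#' a pixel edge of 0.1092 micrometres.
#'
#' @param n_traj Number of trajectories.
#' @param n_points Positions per trajectory (>= 2).
#' @param dt Frame interval in seconds.
#' @param loc_sigma Per-axis localization noise SD in micrometres, added to
#'   reported positions only (the true path is kept alongside).
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `"spt_sim_config"`.
#' @export
sim_config <- function(n_traj, n_points, dt = 0.1, loc_sigma = 0,
                       pixel_size = 0.1092, seed = NULL) {
  stopifnot(n_traj >= 1, n_points >= 2, dt > 0, loc_sigma >= 0,
            pixel_size > 0)
  structure(list(n_traj = as.integer(n_traj),
                 n_points = as.integer(n_points),
                 dt = dt, loc_sigma = loc_sigma,
                 pixel_size = pixel_size, seed = seed),
            class = "spt_sim_config")
}

# build an ensemble from per-axis position matrices (n_points x n_traj)
.ensemble_from_positions <- function(cfg, true_x, true_y, label, params,
                                     add_noise = TRUE) {
  n <- cfg$n_points
  if (add_noise && cfg$loc_sigma > 0) {
    x <- true_x + matrix(stats::rnorm(n * cfg$n_traj, 0, cfg$loc_sigma),
                         n, cfg$n_traj)
    y <- true_y + matrix(stats::rnorm(n * cfg$n_traj, 0, cfg$loc_sigma),
                         n, cfg$n_traj)
  } else {
    x <- true_x; y <- true_y
  }
  trajs <- lapply(seq_len(cfg$n_traj), function(j) {
    spt_trajectory(seq_len(n) - 1L, x[, j], y[, j], dt = cfg$dt,
                   id = as.character(j),
                   true_x = true_x[, j], true_y = true_y[, j])
  })
  spt_ensemble(trajs,
               labels = rep(label, cfg$n_traj),
               params = rep(list(params), cfg$n_traj),
               pixel_size = cfg$pixel_size)
}

#' Simulate immobile particles (pure localization noise)
#'
#' Each trajectory is a fixed true position; the reported positions are that
#' point plus i.i.d. isotropic 2D Gaussian noise of per-axis SD
#' `cfg$loc_sigma`. The expected 2D TAMSD is flat at `4 * loc_sigma^2` for
#' every lag, the flat noise floor that fixed-cell calibration estimates.
#'
#' @param cfg A [sim_config()]; `loc_sigma` is the noise magnitude.
#' @return An [spt_ensemble()] labelled `"immobile"`.
#' @export
simulate_immobile <- function(cfg) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  centers_x <- stats::runif(cfg$n_traj, 0, 10)
  centers_y <- stats::runif(cfg$n_traj, 0, 10)
  true_x <- matrix(centers_x, cfg$n_points, cfg$n_traj, byrow = TRUE)
  true_y <- matrix(centers_y, cfg$n_points, cfg$n_traj, byrow = TRUE)
  .ensemble_from_positions(cfg, true_x, true_y, "immobile",
                           list(loc_sigma = cfg$loc_sigma))
}

#' Simulate unrestricted 2D Brownian motion
#'
#' Per-axis increments are i.i.d. Gaussian with variance `2 * D * dt`
#' (sigma^2 = 2 D dt convention), so the expected 2D MSD at lag Delta is
#' `4 * D * Delta`. Localization noise from `cfg$loc_sigma` is added to
#' reported positions only.
#'
#' @param cfg A [sim_config()].
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @return An [spt_ensemble()] labelled `"brownian"`.
#' @export
simulate_brownian <- function(cfg, D) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  if (D < 0) stop("D must be non-negative")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_points
  step_sd <- sqrt(2 * D * cfg$dt)
  inc <- function() matrix(stats::rnorm((n - 1) * cfg$n_traj, 0, step_sd),
                           n - 1, cfg$n_traj)
  true_x <- rbind(0, apply(inc(), 2, cumsum))
  true_y <- rbind(0, apply(inc(), 2, cumsum))
  .ensemble_from_positions(cfg, true_x, true_y, "brownian",
                           list(D = D, loc_sigma = cfg$loc_sigma))
}

# fGn increment covariance (n-1 x n-1) for per-axis variance var1 at lag 1
.fgn_cov <- function(n_steps, alpha, var1) {
  h2 <- alpha # 2H
  k <- 0:(n_steps - 1)
  gamma <- var1 / 2 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  stats::toeplitz(gamma)
}

#' Simulate fractional Brownian motion trajectories
#'
#' Each axis is exact fractional Gaussian noise, synthesized by Cholesky
#' factorization of the fGn covariance (exactness over speed at the few
#' hundred points per trajectory this package targets), scaled so the
#' expected 2D MSD is `K_alpha * Delta^alpha`. `alpha = 1` reduces exactly
#' to Brownian motion.
#'
#' @param cfg A [sim_config()].
#' @param K_alpha Generalized diffusion coefficient in um^2/s^alpha (> 0).
#' @param alpha Anomalous exponent in (0, 2).
#' @return An [spt_ensemble()] labelled `"fbm"`.
#' @export
simulate_fbm <- function(cfg, K_alpha, alpha) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  if (alpha <= 0 || alpha >= 2) stop("alpha must lie in (0, 2)")
  if (K_alpha <= 0) stop("K_alpha must be positive")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_points
  var1 <- (K_alpha / 2) * cfg$dt^alpha  # per-axis increment variance at lag 1
  L <- chol(.fgn_cov(n - 1, alpha, var1))  # upper triangular: Sigma = L'L
  gen <- function() {
    z <- matrix(stats::rnorm((n - 1) * cfg$n_traj), n - 1, cfg$n_traj)
    rbind(0, apply(crossprod(L, z), 2, cumsum))
  }
  true_x <- gen(); true_y <- gen()
  .ensemble_from_positions(cfg, true_x, true_y, "fbm",
                           list(K_alpha = K_alpha, alpha = alpha,
                                loc_sigma = cfg$loc_sigma))
}

#' Simulate two-state (fast/slow) stepping particles
#'
#' Every step independently draws a mobility state (fast with stationary
#' probability `p_fast`), then per-axis displacements from a zero-mean
#' Gaussian with the state's SD. Step lengths therefore follow a
#' two-component Rayleigh mixture exactly; no localization noise is added
#' (the mixture of the reported steps is the model under test).
#'
#' @param cfg A [sim_config()] (`loc_sigma` is ignored here).
#' @param p_fast Stationary probability of the fast state, in \[0, 1\].
#' @param sigma_slow,sigma_fast Per-axis step SDs in micrometres,
#'   `sigma_fast > sigma_slow > 0`.
#' @return An [spt_ensemble()] labelled `"two_state"`.
#' @export
simulate_two_state <- function(cfg, p_fast, sigma_slow, sigma_fast) {
  stopifnot(inherits(cfg, "spt_sim_config"))
  if (p_fast < 0 || p_fast > 1) stop("p_fast must lie in [0, 1]")
  if (!(sigma_fast > sigma_slow && sigma_slow > 0))
    stop("need sigma_fast > sigma_slow > 0")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_points
  m <- (n - 1) * cfg$n_traj
  sd_step <- ifelse(stats::runif(m) < p_fast, sigma_fast, sigma_slow)
  dx <- matrix(stats::rnorm(m, 0, sd_step), n - 1, cfg$n_traj)
  dy <- matrix(stats::rnorm(m, 0, sd_step), n - 1, cfg$n_traj)
  true_x <- rbind(0, apply(dx, 2, cumsum))
  true_y <- rbind(0, apply(dy, 2, cumsum))
  .ensemble_from_positions(cfg, true_x, true_y, "two_state",
                           list(p_fast = p_fast, sigma_slow = sigma_slow,
                                sigma_fast = sigma_fast),
                           add_noise = FALSE)
}

#' Inject skipped-frame gaps into an ensemble
#'
#' Each interior point is independently replaced by the gap placeholder
#' (`NA` coordinates) with probability `gap_prob`; first and last points are
#' never gapped and frame indices are preserved.
#'
#' @param ensemble An [spt_ensemble()].
#' @param gap_prob Gap probability in \[0, 1).
#' @param seed Optional integer seed.
#' @return The gapped ensemble.
#' @export
inject_gaps <- function(ensemble, gap_prob, seed = NULL) {
  stopifnot(inherits(ensemble, "spt_ensemble"))
  if (gap_prob < 0 || gap_prob >= 1) stop("gap_prob must lie in [0, 1)")
  if (gap_prob == 0) return(ensemble)
  if (!is.null(seed)) set.seed(seed)
  ensemble$trajectories <- lapply(ensemble$trajectories, function(tr) {
    n <- nrow(tr)
    if (n > 2L) {
      hit <- which(stats::runif(n - 2L) < gap_prob) + 1L
      tr$x[hit] <- NA_real_
      tr$y[hit] <- NA_real_
    }
    tr
  })
  ensemble
}
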