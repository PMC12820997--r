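# independent brute-force oracles and small fixture builders

# O(N^2) double-loop TAMSD oracle, gap-aware
brute_force_tamsd <- function(traj, n_max) {
  x <- traj$x
  y <- traj$y
  N <- length(x)
  vals <- rep(NA_real_, n_max)
  pairs <- integer(n_max)
  for (n in seq_len(n_max)) {
    acc <- c()
    for (k in seq_len(N - n)) {
      if (!is.na(x[k]) && !is.na(x[k + n])) {
        acc <- c(acc, (x[k + n] - x[k])^2 + (y[k + n] - y[k])^2)
      }
    }
    pairs[n] <- length(acc)
    if (length(acc)) vals[n] <- mean(acc)
  }
  list(values = vals, valid_pairs = pairs)
}

# hand-rolled spt_tamsd object from explicit values
make_curve <- function(values, dt = 0.1, valid_pairs = NULL, id = "c") {
  structure(list(lags = seq_along(values), values = values,
                 valid_pairs = valid_pairs %||% rep(100L, length(values)),
                 dt = dt, traj_id = id),
            class = "spt_tamsd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fake converged Rayleigh fit carrying only what select_k needs
fake_fit <- function(k, aic) {
  structure(list(k = as.integer(k), p = rep(1 / k, k),
                 sigma = seq_len(k) * 0.05, D = seq_len(k) * 0.01,
                 loglik = -aic / 2, aic = aic, converged = TRUE,
                 n_steps = 100L, degraded_to = NULL),
            class = "spt_rayleigh_fit")
}

# random walk trajectory with gaps knocked out at given 1-based rows
gapped_trajectory <- function(n = 30, gaps = integer(), seed = 1) {
  set.seed(seed)
  x <- cumsum(rnorm(n, 0, 0.1))
  y <- cumsum(rnorm(n, 0, 0.1))
  x[gaps] <- NA
  y[gaps] <- NA
  spt_trajectory(seq_len(n) - 1L, x, y, dt = 0.1)
}
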