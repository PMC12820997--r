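test_that("step extraction respects gaps", {
  tr <- spt_trajectory(0:2, c(0, 1, 1), c(0, 0, 1), dt = 0.1)
  s <- extract_steps(tr)
  expect_equal(s$dx, c(1, 0))
  expect_equal(s$dy, c(0, 1))
  expect_equal(s$r, c(1, 1))

  # gap at frame 2 of 4: only the 0->1 step survives
  trg <- spt_trajectory(0:3, c(0, 1, NA, 3), c(0, 0, NA, 0), dt = 0.1)
  expect_equal(nrow(extract_steps(trg)), 1L)

  const <- spt_trajectory(0:3, rep(0, 4), rep(0, 4), dt = 0.1)
  expect_true(all(extract_steps(const)$r == 0))
})

test_that("scaled step components have unit RMS by construction", {
  s <- scale_steps(data.frame(dx = c(2, -2), dy = c(1, 1),
                              r = c(sqrt(5), sqrt(5))))
  expect_equal(s$dxs, c(1, -1))

  for (seed in 1:5) {
    tr <- gapped_trajectory(60, gaps = if (seed > 2) c(5, 17, 30) else
                              integer(), seed = seed)
    sc <- scale_steps(extract_steps(tr))
    expect_equal(sqrt(mean(sc$dxs^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(mean(sc$dys^2)), 1, tolerance = 1e-12)
  }

  expect_error(scale_steps(data.frame(dx = c(0, 0), dy = c(1, -1),
                                      r = c(1, 1))), "zero RMS")
})

test_that("pooled Brownian scaled steps are standard normal", {
  ens <- simulate_brownian(sim_config(60, 200, dt = 0.1, seed = 50), 0.05)
  steps <- pooled_scaled_steps(ens)
  ks <- suppressWarnings(ks.test(steps, "pnorm"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("pooled step models detect mixture structure and respect nesting", {
  # single-Gaussian data: per-point likelihood gain vanishes
  set.seed(51)
  x <- rnorm(20000)
  m <- fit_step_gaussians(x)
  expect_gte(m$mixture$loglik, m$single$loglik)
  expect_lt((m$mixture$loglik - m$single$loglik) / length(x), 0.005)
  # symmetric input: mixture mass stays centred
  expect_lt(abs(sum(m$mixture$weights * m$mixture$means)), 0.05)

  # two-state data: the two-component model wins decisively
  ens <- simulate_two_state(sim_config(40, 200, dt = 0.1, seed = 52),
                            0.5, 0.03, 0.10)
  m2 <- fit_step_gaussians(pooled_scaled_steps(ens))
  expect_gt(m2$mixture$loglik - m2$single$loglik, 10)
})

test_that("single-Rayleigh EM equals the closed-form MLE", {
  expect_equal(fit_rayleigh_mixture(c(1, 1), 1, 0.1)$sigma, sqrt(0.5),
               tolerance = 1e-12)
  set.seed(53)
  r <- sqrt(rnorm(500, 0, 0.05)^2 + rnorm(500, 0, 0.05)^2)
  f <- fit_rayleigh_mixture(r, 1, 0.1)
  expect_equal(f$sigma, sqrt(sum(r^2) / (2 * length(r))), tolerance = 1e-12)
  expect_equal(f$aic, 2 - 2 * f$loglik, tolerance = 1e-12)

  # sigma = 0.1, dt = 0.1 maps to apparent D = sigma^2 / (2 dt) = 0.05
  expect_equal(fit_rayleigh_mixture(rep(0.1, 100) * sqrt(2), 1, 0.1)$D,
               0.1^2 / (2 * 0.1), tolerance = 1e-12)
})

test_that("Rayleigh-mixture EM is monotone and nested in likelihood", {
  ens <- simulate_two_state(sim_config(1, 201, dt = 0.1, seed = 54),
                            0.5, 0.03, 0.10)
  r <- extract_steps(ens$trajectories[[1]])$r
  f1 <- fit_rayleigh_mixture(r, 1, 0.1)
  f2 <- fit_rayleigh_mixture(r, 2, 0.1, seed = 1)
  f3 <- fit_rayleigh_mixture(r, 3, 0.1, seed = 1)
  expect_true(f2$converged)
  # the EM guard rejects any iteration that decreases the log-likelihood,
  # so a converged fit certifies monotonicity; nesting orders the optima
  expect_gte(f2$loglik, f1$loglik)
  expect_gte(f3$loglik, f2$loglik - 1e-6)
  expect_equal(sum(f2$p), 1, tolerance = 1e-9)
  expect_equal(f2$aic, 2 * 3 - 2 * f2$loglik, tolerance = 1e-12)
  expect_true(all(diff(f2$sigma) > 0))
})

test_that("AIC step-down reproduces the hand-traced selections", {
  fits <- list(fake_fit(1, 100), fake_fit(2, 97), fake_fit(3, 96.5),
               fake_fit(4, 99))
  expect_equal(select_k(fits)$k, 1L)

  fits2 <- list(fake_fit(1, 100), fake_fit(2, 90), fake_fit(3, 89),
                fake_fit(4, 95))
  expect_equal(select_k(fits2)$k, 2L)

  # minimum already simplest
  fits3 <- list(fake_fit(1, 80), fake_fit(2, 90))
  expect_equal(select_k(fits3)$k, 1L)
})

test_that("pure Rayleigh data select one component in most replicates", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    r <- sqrt(rnorm(300, 0, 0.05)^2 + rnorm(300, 0, 0.05)^2)
    sel <- fit_mobility_states(r, dt = 0.1, seed = seed)$selected
    if (sel$k == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("two-state parameters are recovered within 10% in the median", {
  p_true <- 0.5
  ss <- 0.03
  sf <- 0.10
  ens <- simulate_two_state(sim_config(100, 201, dt = 0.1, seed = 55),
                            p_true, ss, sf)
  est <- t(vapply(ens$trajectories, function(tr) {
    f <- fit_rayleigh_mixture(extract_steps(tr)$r, 2, 0.1, seed = 1)
    if (f$k != 2L) return(c(NA, NA, NA))
    c(f$p[2], f$sigma[1], f$sigma[2])
  }, numeric(3)))
  med <- apply(est, 2, median, na.rm = TRUE)
  expect_lt(abs(med[1] - p_true) / p_true, 0.1)
  expect_lt(abs(med[2] - ss) / ss, 0.1)
  expect_lt(abs(med[3] - sf) / sf, 0.1)
})

test_that("population summary finds the generative mode and noise fraction", {
  ens <- simulate_two_state(sim_config(50, 301, dt = 0.1, seed = 56),
                            0.5, 0.03, 0.10)
  fits <- lapply(ens$trajectories, function(tr) {
    fit_rayleigh_mixture(extract_steps(tr)$r, 2, 0.1, seed = 1)
  })
  fits <- Filter(function(f) f$k == 2L, fits)
  fast <- population_summary(fits, "fast")
  D_true <- 0.10^2 / (2 * 0.1)
  expect_lt(abs(fast$mode["proportion"] - 0.5) / 0.5, 0.2)
  expect_lt(abs(fast$mode["D"] - D_true) / D_true, 0.2)

  slow <- population_summary(fits, "slow", noise_D = 1)
  expect_equal(slow$frac_below_noise, 1)  # all slow D under a huge floor
  expect_error(population_summary(fits[1:5], "slow"), ">= 20")
})
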