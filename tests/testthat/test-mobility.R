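test_that("sRg matches the hand-evaluated definition", {
  tr <- spt_trajectory(0:2, c(0, 1, 2), c(0, 0, 0), dt = 0.1)
  s <- scaled_radius_of_gyration(tr)
  expect_equal(s$Rg, sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(s$mean_step, 1)
  expect_equal(s$sRg, sqrt(pi / 2) * sqrt(2 / 3), tolerance = 1e-10)
})

test_that("sRg is invariant to translation, rotation and uniform scaling", {
  set.seed(40)
  x <- cumsum(rnorm(50, 0, 0.1))
  y <- cumsum(rnorm(50, 0, 0.1))
  base <- scaled_radius_of_gyration(
    spt_trajectory(0:49, x, y, dt = 0.1))$sRg

  shifted <- scaled_radius_of_gyration(
    spt_trajectory(0:49, x + 5, y - 3, dt = 0.1))$sRg
  expect_equal(shifted, base, tolerance = 1e-12)

  th <- 0.7
  rot <- scaled_radius_of_gyration(
    spt_trajectory(0:49, cos(th) * x - sin(th) * y,
                   sin(th) * x + cos(th) * y, dt = 0.1))$sRg
  expect_equal(rot, base, tolerance = 1e-12)

  scaled <- scaled_radius_of_gyration(
    spt_trajectory(0:49, 3.7 * x, 3.7 * y, dt = 0.1))$sRg
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("sRg steps skip gaps and degenerate trajectories are flagged", {
  # gap at frame 2: steps 1->2 and 2->3 are both invalid
  tr <- spt_trajectory(c(0, 1, 2, 3), c(0, 1, NA, 5), c(0, 0, NA, 0),
                       dt = 0.1)
  s <- scaled_radius_of_gyration(tr)
  expect_equal(s$mean_step, 1)  # only the 0->1 step counts

  const <- spt_trajectory(0:4, rep(1, 5), rep(1, 5), dt = 0.1)
  sd_ <- scaled_radius_of_gyration(const)
  expect_true(sd_$degenerate)
  expect_true(is.na(sd_$sRg))
})

test_that("classification labels the boundary immobile and recovers mixtures", {
  # boundary case: threshold equal to the trajectory's own sRg
  tr <- spt_trajectory(0:2, c(0, 1, 2), c(0, 0, 0), dt = 0.1)
  srg <- scaled_radius_of_gyration(tr)$sRg
  ens1 <- spt_ensemble(list(tr))
  cl <- classify_mobility(ens1, srg)
  expect_equal(unname(cl$counts["immobile"]), 1L)
  cl2 <- classify_mobility(ens1, srg - 1e-9)
  expect_equal(unname(cl2$counts["mobile"]), 1L)

  # two-population mixture: recovered mobile fraction within 3%
  sigma <- 0.02
  n_imm <- 240
  n_mob <- 160
  cal <- calibrate_fixed_cells(
    simulate_immobile(sim_config(400, 200, loc_sigma = sigma, seed = 41)))
  imm <- simulate_immobile(sim_config(n_imm, 200, loc_sigma = sigma,
                                      seed = 42))
  mob <- simulate_brownian(sim_config(n_mob, 200, dt = 0.1,
                                      loc_sigma = sigma, seed = 43), 0.05)
  both <- spt_ensemble(c(
    imm$trajectories,
    lapply(mob$trajectories, function(tr) {
      attr(tr, "id") <- paste0("m", attr(tr, "id"))
      tr
    })))
  cl3 <- classify_mobility(both, cal)
  frac <- cl3$counts["mobile"] / (n_imm + n_mob)
  # the 95th-percentile threshold mislabels 5% of true immobiles by
  # construction; invert that known rate to recover the mixing fraction
  p_est <- (frac - 0.05) / 0.95
  expect_lt(abs(p_est - n_mob / (n_imm + n_mob)), 0.03)
})

test_that("MH common OR matches the single-stratum identity and printed counts", {
  one <- data.frame(treated_mobile = 11097, treated_immobile = 5666,
                    control_mobile = 5906, control_immobile = 3670)
  res <- mantel_haenszel_or(one)
  simple <- (11097 * 3670) / (5666 * 5906)
  expect_equal(res$common_or, simple, tolerance = 1e-12)
  expect_equal(res$common_or, 1.217, tolerance = 1e-3)

  # replicated strata leave the estimate unchanged, and give an
  # independent cross-check against the stats implementation
  two <- rbind(one, one)
  res2 <- mantel_haenszel_or(two)
  expect_equal(res2$common_or, simple, tolerance = 1e-12)
  arr <- array(rep(c(11097, 5906, 5666, 3670), 2), dim = c(2, 2, 2))
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(res2$common_or, unname(mh$estimate), tolerance = 1e-9)
  expect_equal(res2$p_value, mh$p.value, tolerance = 1e-9)

  # treated == control gives the null
  null <- data.frame(treated_mobile = 50, treated_immobile = 30,
                     control_mobile = 50, control_immobile = 30)
  expect_equal(mantel_haenszel_or(null)$common_or, 1, tolerance = 1e-12)

  # all-mobile control: infinite estimate reported as such
  inf <- data.frame(treated_mobile = 20, treated_immobile = 10,
                    control_mobile = 0, control_immobile = 10)
  expect_equal(mantel_haenszel_or(inf)$common_or, Inf)
})

test_that("MH chi-square and RBG interval agree with the stats implementation", {
  set.seed(44)
  strata <- data.frame(treated_mobile = c(120, 85, 230),
                       treated_immobile = c(80, 95, 170),
                       control_mobile = c(100, 70, 190),
                       control_immobile = c(110, 90, 220))
  res <- mantel_haenszel_or(strata)
  arr <- array(0, dim = c(2, 2, 3))
  for (i in 1:3) {
    arr[, , i] <- matrix(c(strata$treated_mobile[i],
                           strata$control_mobile[i],
                           strata$treated_immobile[i],
                           strata$control_immobile[i]), 2, 2)
  }
  mh <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$common_or, unname(mh$estimate), tolerance = 1e-9)
  expect_equal(res$p_value, mh$p.value, tolerance = 1e-9)
  expect_equal(res$ci95, unname(mh$conf.int), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("treated-weighted OR reduces correctly and covers the truth", {
  pooled <- c(500, 500)
  one <- data.frame(mobile = 150, immobile = 100)
  res <- weighted_or(one, pooled)
  expect_equal(res$common_or, (150 / 100) / (500 / 500), tolerance = 1e-12)

  same <- data.frame(mobile = rep(150, 4), immobile = rep(100, 4))
  expect_equal(weighted_or(same, pooled)$common_or, 1.5, tolerance = 1e-12)

  # coverage experiment: true OR 1.5 across 5 sessions
  set.seed(45)
  p_control <- 0.5
  odds_treated <- 1.5 * p_control / (1 - p_control)
  p_treated <- odds_treated / (1 + odds_treated)
  hits <- 0L
  for (rep_i in 1:100) {
    n_c <- 800
    cm <- rbinom(1, n_c, p_control)
    tm <- rbinom(5, 400, p_treated)
    strata <- data.frame(mobile = tm, immobile = 400 - tm)
    ci <- weighted_or(strata, c(cm, n_c - cm))$ci95
    if (ci[1] <= 1.5 && 1.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})
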