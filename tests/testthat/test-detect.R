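params_default <- detection_params(dog_sigma_small = 1, dog_sigma_large = 3)

test_that("DoG filter rejects DC, is linear, and matches kernel arithmetic", {
  const <- matrix(7, 32, 32)
  expect_equal(max(abs(dog_filter(const, params_default))), 0,
               tolerance = 1e-12)

  set.seed(60)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(dog_filter(3.5 * img, params_default),
               3.5 * dog_filter(img, params_default), tolerance = 1e-12)

  # single bright pixel: centre value is the difference of the central
  # weights of the two truncated, normalized 1D kernels, squared (separable)
  imp <- matrix(0, 33, 33)
  amp <- 50
  imp[17, 17] <- amp
  central_w <- function(sigma) {
    half <- ceiling(4 * sigma)
    k <- exp(-(-half:half)^2 / (2 * sigma^2))
    (k / sum(k))[half + 1]
  }
  expected <- amp * (central_w(1)^2 - central_w(3)^2)
  out <- dog_filter(imp, params_default)
  expect_equal(out[17, 17], expected, tolerance = 1e-10)

  imp[3, 3] <- NaN
  expect_error(dog_filter(imp, params_default), "non-finite")
})

test_that("detection finds separated components with sub-pixel accuracy", {
  blank <- matrix(0, 32, 32)
  expect_equal(nrow(detect_spots(blank, blank,
                                 detection_params(threshold = 1))), 0L)

  # one rendered spot at a known sub-pixel position, high SNR
  tr <- spt_trajectory(0:1, c(10.30, 10.30) * 0.1092,
                       c(5.70, 5.70) * 0.1092, dt = 0.1)
  ens <- spt_ensemble(list(tr))
  mv <- render_movie(ens, psf_sigma = 1.3, amplitude = 200,
                     background = 10, noise_sd = 1, image_shape = c(32, 32),
                     seed = 61)
  det <- detect_movie(mv$stack, params_default)
  expect_equal(nrow(det), 2L)
  err <- sqrt((det$x_px - 10.30)^2 + (det$y_px - 5.70)^2)
  expect_lt(max(err), 0.15)

  # two blobs sharing no pixels give exactly two detections
  two <- matrix(0, 32, 32)
  two[8, 8] <- 10
  two[24, 24] <- 10
  d2 <- detect_spots(two, two, detection_params(threshold = 5))
  expect_equal(nrow(d2), 2L)
})

test_that("connectivity setting controls component merging", {
  # two pixels touching only diagonally
  img <- matrix(0, 16, 16)
  img[8, 8] <- 10
  img[9, 9] <- 10
  d8 <- detect_spots(img, img, detection_params(threshold = 5,
                                                connectivity = 8))
  d4 <- detect_spots(img, img, detection_params(threshold = 5,
                                                connectivity = 4))
  expect_equal(nrow(d8), 1L)
  expect_equal(nrow(d4), 2L)
})

test_that("linking follows the radius contract, splits jumps, bridges gaps", {
  p <- params_default
  # steady 1 px/frame walker: one 10-point trajectory
  d1 <- data.frame(frame = 0:9, x_px = 0:9, y_px = rep(10, 10))
  e1 <- link_detections(d1, p, dt = 0.1)
  expect_equal(length(e1), 1L)
  expect_equal(n_positions(e1$trajectories[[1]]), 10L)
  # micrometre conversion is exact
  expect_equal(e1$trajectories[[1]]$x, (0:9) * 0.1092, tolerance = 1e-12)

  # a 4 px jump mid-walk (radius 3) splits the track in two
  d2 <- data.frame(frame = 0:9, x_px = c(0:4, 8 + 0:4), y_px = rep(10, 10))
  expect_equal(length(link_detections(d2, p, dt = 0.1)), 2L)

  # detection missing at frame 2 with max_gap_frames = 1: one trajectory
  # with a gap placeholder
  d3 <- data.frame(frame = c(0, 1, 3, 4), x_px = c(5, 5.5, 6, 6.5),
                   y_px = rep(5, 4))
  e3 <- link_detections(d3, p, dt = 0.1)
  expect_equal(length(e3), 1L)
  tr <- e3$trajectories[[1]]
  expect_equal(nrow(tr), 5L)
  expect_true(is.na(tr$x[3]))

  # with max_gap_frames = 0 the same data split in two
  p0 <- detection_params(max_gap_frames = 0)
  expect_equal(length(link_detections(d3, p0, dt = 0.1)), 2L)
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(62)
  base <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f,
               x_px = c(5, 15, 25) + f * 0.5 + rnorm(3, 0, 0.1),
               y_px = c(5, 15, 25))
  }))
  shuffled <- do.call(rbind, lapply(split(base, base$frame),
                                    function(d) d[sample(nrow(d)), ]))
  canon <- function(e) {
    xs <- lapply(e$trajectories, function(tr) round(tr$x, 9))
    unname(xs[order(vapply(xs, function(v) v[1], numeric(1)))])
  }
  expect_equal(canon(link_detections(base, params_default, 0.1)),
               canon(link_detections(shuffled, params_default, 0.1)))
})

test_that("duration filter keeps the boundary and implies 200 positions", {
  mk <- function(n, id) spt_trajectory(seq_len(n) - 1L,
                                       cumsum(rnorm(n, 0, 0.01)),
                                       cumsum(rnorm(n, 0, 0.01)),
                                       dt = 0.1, id = id)
  set.seed(63)
  ens <- spt_ensemble(list(mk(50, "a"), mk(199, "b"), mk(200, "c"),
                           mk(400, "d")))
  kept <- filter_min_duration(ens, 20)
  expect_equal(names(kept$trajectories), c("c", "d"))
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(min(vapply(kept$trajectories, nrow, integer(1))), 200L)

  empty <- filter_min_duration(spt_ensemble(list()), 20)
  expect_equal(length(empty), 0L)
})

test_that("noise-free movies are recovered track-for-track", {
  set.seed(64)
  cfg <- sim_config(3, 15, dt = 0.1, seed = 64)
  ens <- simulate_brownian(cfg, 0.01)
  for (i in 1:3) {
    tr <- ens$trajectories[[i]]
    off_x <- c(1.2, 2.4, 3.3)[i]
    off_y <- c(1.1, 2.9, 1.8)[i]
    tr$x <- tr$x + off_x
    tr$true_x <- tr$true_x + off_x
    tr$y <- tr$y + off_y
    tr$true_y <- tr$true_y + off_y
    ens$trajectories[[i]] <- tr
  }
  mv <- render_movie(ens, psf_sigma = 1.3, amplitude = 150, background = 5,
                     noise_sd = 0, image_shape = c(64, 64), seed = 65)
  det <- detect_movie(mv$stack, params_default)
  tracks <- link_detections(det, params_default, dt = 0.1)
  expect_equal(length(tracks), 3L)

  err <- vapply(seq_len(nrow(det)), function(i) {
    tt <- mv$truth[mv$truth$frame == det$frame[i], ]
    min(sqrt((tt$x_px - det$x_px[i])^2 + (tt$y_px - det$y_px[i])^2))
  }, numeric(1))
  expect_lt(max(err), 0.15)
})

test_that("the ID-switch diagnostic measures density regimes", {
  # two static spots 20 px apart: NN distance 20 every frame, no risk
  d <- do.call(rbind, lapply(0:4, function(f) {
    data.frame(frame = f, x_px = c(5, 25), y_px = c(10, 10))
  }))
  rep1 <- id_switch_diagnostic(d, params = params_default)
  expect_true(all(rep1$per_frame$mean_nn == 20))
  expect_equal(rep1$risk_fraction, 0)

  # dense random field at about one spot per (3 px)^2: risk everywhere
  set.seed(66)
  dense <- do.call(rbind, lapply(0:4, function(f) {
    data.frame(frame = f, x_px = runif(400, 0, 60), y_px = runif(400, 0, 60))
  }))
  rep2 <- id_switch_diagnostic(dense, params = params_default)
  expect_equal(rep2$risk_fraction, 1)

  # single-spot movie: empty table plus an explanatory note
  single <- data.frame(frame = 0:4, x_px = 5, y_px = 5)
  rep3 <- id_switch_diagnostic(single, params = params_default)
  expect_equal(nrow(rep3$per_frame), 0L)
  expect_match(rep3$note, "insufficient")
})

test_that("rendering reports out-of-bounds particles instead of clipping", {
  tr <- spt_trajectory(0:1, c(0, 20), c(0, 0), dt = 0.1)  # 20 um >> image
  expect_error(render_movie(spt_ensemble(list(tr)), image_shape = c(32, 32)),
               "outside")
})

test_that("static noise-free spots peak at the same pixel every frame", {
  tr <- spt_trajectory(0:4, rep(10 * 0.1092, 5), rep(12 * 0.1092, 5),
                       dt = 0.1)
  mv <- render_movie(spt_ensemble(list(tr)), amplitude = 100,
                     background = 0, noise_sd = 0, image_shape = c(32, 32))
  peaks <- apply(mv$stack, 3, which.max)
  expect_equal(length(unique(peaks)), 1L)
  # matrix row 13, column 11 corresponds to (x, y) = (10, 12)
  expect_equal(unique(peaks), (11 - 1) * 32 + 13)
})
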