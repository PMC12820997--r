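#' Detection and linking parameters
#'
#' @param dog_sigma_small,dog_sigma_large SDs (pixels) of the two Gaussian
#'   blurs in the difference-of-Gaussians bandpass; small < large.
#' @param threshold Intensity threshold applied to the DoG-filtered frame.
#'   `NULL` selects it automatically as `mean + auto_k * SD` of the frame.
#' @param auto_k Multiplier for the automatic threshold.
#' @param link_radius Maximum frame-to-frame displacement in pixels for two
#'   detections to be the same particle (default 3).
#' @param max_gap_frames Maximum number of consecutive missed frames a track
#'   may bridge with gap placeholders (default 1).
#' @param min_duration_s Minimum trajectory span in seconds (default 20).
#' @param pixel_size_um Micrometres per pixel (default 0.1092).
#' @param connectivity 8 (default) or 4, for "spatially continuous pixels".
#' @return A list of class `"spt_detection_params"`.
#' @export
detection_params <- function(dog_sigma_small = 1, dog_sigma_large = 3,
                             threshold = NULL, auto_k = 5,
                             link_radius = 3, max_gap_frames = 1,
                             min_duration_s = 20, pixel_size_um = 0.1092,
                             connectivity = 8) {
  stopifnot(dog_sigma_small < dog_sigma_large, link_radius > 0,
            min_duration_s > 0, connectivity %in% c(4, 8))
  structure(list(dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 threshold = threshold, auto_k = auto_k,
                 link_radius = link_radius,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_duration_s = min_duration_s,
                 pixel_size_um = pixel_size_um,
                 connectivity = as.integer(connectivity)),
            class = "spt_detection_params")
}

# truncated, row-renormalized 1D Gaussian convolution operator (n x n);
# renormalization makes blur of a constant image exactly constant
.blur_matrix <- function(n, sigma) {
  half <- ceiling(4 * sigma)
  idx <- seq_len(n)
  B <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-d^2 / (2 * sigma^2)), 0)
  })
  B / rowSums(B)
}

#' Difference-of-Gaussians spatial bandpass filter
#'
#' Per frame, the difference of a small- and large-sigma Gaussian blur.
#' A constant image maps to exactly zero.
#'
#' @param stack 2D matrix or ny x nx x n_frames array.
#' @param params A [detection_params()].
#' @return Filtered stack, same shape as input.
#' @export
dog_filter <- function(stack, params) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (!all(is.finite(stack))) stop("stack contains non-finite pixels")
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  Bs_y <- .blur_matrix(ny, params$dog_sigma_small)
  Bs_x <- .blur_matrix(nx, params$dog_sigma_small)
  Bl_y <- .blur_matrix(ny, params$dog_sigma_large)
  Bl_x <- .blur_matrix(nx, params$dog_sigma_large)
  out <- stack
  for (f in seq_len(dim(stack)[3])) {
    fr <- stack[, , f]
    out[, , f] <- Bs_y %*% fr %*% t(Bs_x) - Bl_y %*% fr %*% t(Bl_x)
  }
  if (dim(out)[3] == 1L) out[, , 1L] else out
}

# connected-component labelling of a logical mask (BFS, 4- or 8-connectivity)
.label_components <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  if (connectivity == 8L) {
    nbr <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nbr <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      p <- queue[1L]; queue <- queue[-1L]
      i <- (p - 1L) %% ny + 1L
      j <- (p - 1L) %/% ny + 1L
      for (k in seq_len(nrow(nbr))) {
        ii <- i + nbr[k, 1L]; jj <- j + nbr[k, 2L]
        if (ii >= 1L && ii <= ny && jj >= 1L && jj <= nx) {
          q <- (jj - 1L) * ny + ii
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- current
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# symmetric 2D Gaussian least-squares centroid on a raw patch;
# returns c(x_px, y_px, amplitude, fit_ok)
.gaussian_centroid <- function(raw, cx, cy, patch_half) {
  ny <- nrow(raw); nx <- ncol(raw)
  xr <- max(0L, cx - patch_half):min(nx - 1L, cx + patch_half)
  yr <- max(0L, cy - patch_half):min(ny - 1L, cy + patch_half)
  patch <- raw[yr + 1L, xr + 1L, drop = FALSE]
  dat <- data.frame(x = rep(xr, each = length(yr)),
                    y = rep(yr, times = length(xr)),
                    z = as.vector(patch))
  w <- pmax(dat$z - min(dat$z), 0)
  wx <- sum(w * dat$x) / sum(w)
  wy <- sum(w * dat$y) / sum(w)
  fit <- tryCatch({
    m <- suppressWarnings(minpack.lm::nlsLM(
      z ~ B + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = dat,
      start = list(B = min(dat$z), A = max(dat$z) - min(dat$z),
                   x0 = wx, y0 = wy, s = max(patch_half / 2, 0.8)),
      control = minpack.lm::nls.lm.control(maxiter = 100)))
    cf <- stats::coef(m)
    if (cf[["A"]] <= 0 || cf[["x0"]] < min(xr) - 1 || cf[["x0"]] > max(xr) + 1 ||
        cf[["y0"]] < min(yr) - 1 || cf[["y0"]] > max(yr) + 1)
      stop("implausible fit")
    c(cf[["x0"]], cf[["y0"]], cf[["A"]], 1)
  }, error = function(e) c(wx, wy, max(dat$z) - min(dat$z), 0))
  fit
}

#' Detect spots in a single frame
#'
#' Supra-threshold pixels of the DoG-filtered frame are grouped into
#' connected components (one particle each); the centroid of each component
#' is refined to sub-pixel precision by a symmetric 2D Gaussian
#' least-squares fit on a raw-image patch around the component peak, falling
#' back to the intensity-weighted centroid (flagged `fit_ok = 0`) when the
#' fit fails.
#'
#' @param filtered DoG-filtered frame (matrix).
#' @param raw Raw frame (matrix, same shape).
#' @param params A [detection_params()].
#' @return data.frame `x_px,y_px,cluster_size,amplitude,fit_ok` (possibly
#'   zero rows); coordinates are 0-based pixel units.
#' @export
detect_spots <- function(filtered, raw, params) {
  thr <- params$threshold
  if (is.null(thr))
    thr <- mean(filtered) + params$auto_k * stats::sd(as.vector(filtered))
  mask <- filtered > thr
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      cluster_size = integer(0), amplitude = numeric(0),
                      fit_ok = integer(0))
  if (!any(mask)) return(empty)
  labels <- .label_components(mask, params$connectivity)
  patch_half <- ceiling(3 * params$dog_sigma_small)
  ny <- nrow(filtered)
  out <- lapply(seq_len(max(labels)), function(lab) {
    px <- which(labels == lab)
    peak <- px[which.max(filtered[px])]
    cy <- (peak - 1L) %% ny       # 0-based row -> y
    cx <- (peak - 1L) %/% ny      # 0-based col -> x
    g <- .gaussian_centroid(raw, cx, cy, patch_half)
    data.frame(x_px = g[1], y_px = g[2], cluster_size = length(px),
               amplitude = g[3], fit_ok = as.integer(g[4]))
  })
  do.call(rbind, out)
}

#' Detect spots in every frame of a movie
#'
#' Convenience wrapper: [dog_filter()] then [detect_spots()] per frame.
#'
#' @param stack ny x nx x n_frames array.
#' @param params A [detection_params()].
#' @return data.frame with a leading 0-based `frame` column.
#' @export
detect_movie <- function(stack, params) {
  filtered <- dog_filter(stack, params)
  if (is.matrix(filtered)) filtered <- array(filtered, c(dim(filtered), 1L))
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- detect_spots(filtered[, , f], stack[, , f], params)
    if (nrow(d)) cbind(frame = f - 1L, d)
    else cbind(frame = integer(0), d)
  })
  do.call(rbind, out)
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment between consecutive frames: candidate
#' pairs within `link_radius` pixels are accepted in ascending order of
#' distance. A track missing up to `max_gap_frames` consecutive frames
#' continues with gap placeholders; longer absences terminate it and any
#' unmatched detection starts a new track. Output positions are converted
#' to micrometres with `pixel_size_um`.
#'
#' @param detections data.frame `frame,x_px,y_px` (0-based frames).
#' @param params A [detection_params()].
#' @param dt Frame interval in seconds.
#' @return An [spt_ensemble()] of linked trajectories (each with >= 2
#'   positions; single-detection tracks are dropped).
#' @export
link_detections <- function(detections, params, dt = 0.1) {
  if (nrow(detections) == 0)
    return(spt_ensemble(list(), pixel_size = params$pixel_size_um))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- min(detections$frame):max(detections$frame)
  # track store: list of lists(frames=..., x=..., y=..., last_frame)
  open <- list()
  done <- list()
  next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    # retire tracks that can no longer be bridged
    if (length(open)) {
      last <- vapply(open, function(t) t$last_frame, numeric(1))
      expired <- f - last - 1 > params$max_gap_frames
      done <- c(done, open[expired])
      open <- open[!expired]
    }
    assigned_det <- rep(FALSE, nrow(det))
    if (length(open) && nrow(det)) {
      lastx <- vapply(open, function(t) t$x[length(t$x)], numeric(1))
      lasty <- vapply(open, function(t) t$y[length(t$y)], numeric(1))
      dmat <- sqrt(outer(lastx, det$x_px, "-")^2 +
                   outer(lasty, det$y_px, "-")^2)
      cand <- which(dmat <= params$link_radius, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_track <- rep(FALSE, length(open))
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1L]; di <- cand[r, 2L]
          if (used_track[ti] || assigned_det[di]) next
          used_track[ti] <- TRUE
          assigned_det[di] <- TRUE
          tr <- open[[ti]]
          gap <- f - tr$last_frame - 1L
          if (gap > 0L) {
            tr$frames <- c(tr$frames, tr$last_frame + seq_len(gap))
            tr$x <- c(tr$x, rep(NA_real_, gap))
            tr$y <- c(tr$y, rep(NA_real_, gap))
          }
          tr$frames <- c(tr$frames, f)
          tr$x <- c(tr$x, det$x_px[di])
          tr$y <- c(tr$y, det$y_px[di])
          tr$last_frame <- f
          open[[ti]] <- tr
        }
      }
    }
    for (di in which(!assigned_det)) {
      open[[length(open) + 1L]] <- list(id = next_id,
                                        frames = f,
                                        x = det$x_px[di], y = det$y_px[di],
                                        last_frame = f)
      next_id <- next_id + 1L
    }
  }
  done <- c(done, open)
  keep <- vapply(done, function(t) sum(!is.na(t$x)) >= 2L, logical(1))
  n_singletons <- sum(!keep)
  done <- done[keep]
  done <- done[order(vapply(done, function(t) t$id, integer(1)))]
  px <- params$pixel_size_um
  trajs <- lapply(done, function(t) {
    keep <- seq_len(max(which(!is.na(t$x))))  # trim trailing gap padding
    spt_trajectory(t$frames[keep], t$x[keep] * px, t$y[keep] * px,
                   dt = dt, id = as.character(t$id))
  })
  out <- spt_ensemble(trajs, pixel_size = px)
  attr(out, "n_singletons") <- n_singletons
  out
}

#' Filter trajectories by minimum duration
#'
#' Retains trajectories whose span, `(last frame - first frame + 1) * dt`,
#' is at least `min_duration_s` (boundary inclusive). With the defaults
#' (dt = 0.1 s, 20 s cutoff) every retained trajectory has at least 200
#' frame slots.
#'
#' @param ensemble An [spt_ensemble()].
#' @param min_duration_s Minimum span in seconds.
#' @return The filtered ensemble, with attribute `n_removed`.
#' @export
filter_min_duration <- function(ensemble, min_duration_s = 20) {
  keep <- vapply(ensemble$trajectories, function(tr) {
    nrow(tr) * attr(tr, "dt") >= min_duration_s
  }, logical(1))
  out <- ensemble[which(keep)]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Nearest-neighbour ID-switching diagnostic
#'
#' Per frame, the mean and median nearest-neighbour distance among
#' detections; pooled step sizes from the linked trajectories; and the
#' fraction of frames whose median nearest-neighbour distance falls below
#' `2 * link_radius`, the density regime where identity switching during
#' linking becomes plausible.
#'
#' @param detections data.frame `frame,x_px,y_px`.
#' @param ensemble Optional linked [spt_ensemble()] for the pooled step
#'   sizes (reported in pixels using `params$pixel_size_um`).
#' @param params A [detection_params()].
#' @return List with `per_frame` (frame, n, mean_nn, median_nn),
#'   `step_sizes_px`, `risk_fraction` and `note`.
#' @export
id_switch_diagnostic <- function(detections, ensemble = NULL, params) {
  per_frame <- lapply(split(detections, detections$frame), function(d) {
    if (nrow(d) < 2L) return(NULL)
    dm <- as.matrix(stats::dist(d[, c("x_px", "y_px")]))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, min)
    data.frame(frame = d$frame[1L], n = nrow(d),
               mean_nn = mean(nn), median_nn = stats::median(nn))
  })
  per_frame <- do.call(rbind, per_frame)
  steps <- numeric(0)
  if (!is.null(ensemble)) {
    steps <- unlist(lapply(ensemble$trajectories, function(tr) {
      ok <- !is.na(tr$x)
      pair <- ok[-1] & ok[-length(ok)]
      sqrt(diff(tr$x)[pair]^2 + diff(tr$y)[pair]^2)
    }), use.names = FALSE) / params$pixel_size_um
  }
  if (is.null(per_frame) || nrow(per_frame) == 0L) {
    return(list(per_frame = data.frame(frame = integer(0), n = integer(0),
                                       mean_nn = numeric(0),
                                       median_nn = numeric(0)),
                step_sizes_px = steps, risk_fraction = NA_real_,
                note = "insufficient detection density (< 2 per frame)"))
  }
  rownames(per_frame) <- NULL
  list(per_frame = per_frame,
       step_sizes_px = steps,
       risk_fraction = mean(per_frame$median_nn < 2 * params$link_radius),
       note = "risk regime: median nearest neighbour < 2 x link radius")
}
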