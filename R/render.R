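#' Render an ensemble as a diffraction-limited spot movie
#'
#' Each non-gap position is drawn as a symmetric 2D Gaussian of SD
#' `psf_sigma` pixels on a constant background with additive Gaussian read
#' noise, giving a toy movie with known ground truth for exercising
#' detection and linking. True (noise-free) coordinates are rendered when
#' the simulators kept them; reported positions otherwise.
#'
#' Pixel coordinates have their origin at the centre of pixel (0, 0):
#' a particle at `x_px = 3, y_px = 5` peaks at matrix element `[6, 4]`.
#'
#' @param ensemble An [spt_ensemble()]; positions in micrometres are
#'   converted with the ensemble's `pixel_size`.
#' @param psf_sigma PSF standard deviation in pixels (> 0).
#' @param amplitude Peak height above background, in counts.
#' @param background Constant background level, counts.
#' @param noise_sd SD of additive Gaussian noise, counts.
#' @param image_shape `c(ny, nx)` image size in pixels.
#' @param offset_px `c(x, y)` offset in pixels added to all positions,
#'   useful to centre trajectories that start at the origin.
#' @param seed Optional integer seed for the noise.
#' @return List with `stack` (ny x nx x n_frames array of counts) and
#'   `truth` (data.frame `frame,traj_id,x_px,y_px`).
#' @export
render_movie <- function(ensemble, psf_sigma = 1.3, amplitude = 100,
                         background = 10, noise_sd = 2,
                         image_shape = c(64, 64), offset_px = c(0, 0),
                         seed = NULL) {
  stopifnot(inherits(ensemble, "spt_ensemble"), psf_sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  px <- attr(ensemble, "pixel_size")
  ny <- image_shape[1]; nx <- image_shape[2]

  pts <- do.call(rbind, lapply(ensemble$trajectories, function(tr) {
    ok <- !is.na(tr$x)
    xs <- if (!is.null(tr$true_x)) tr$true_x else tr$x
    ys <- if (!is.null(tr$true_y)) tr$true_y else tr$y
    data.frame(frame = tr$frame[ok], traj_id = attr(tr, "id"),
               x_px = xs[ok] / px + offset_px[1],
               y_px = ys[ok] / px + offset_px[2])
  }))
  oob <- pts$x_px < 0 | pts$x_px > nx - 1 | pts$y_px < 0 | pts$y_px > ny - 1
  if (any(oob))
    stop(sum(oob), " rendered positions fall outside the ", ny, "x", nx,
         " image; first offender: traj ", pts$traj_id[which(oob)[1]],
         " frame ", pts$frame[which(oob)[1]])

  n_frames <- max(pts$frame) + 1L
  stack <- array(background, dim = c(ny, nx, n_frames))
  half <- ceiling(4 * psf_sigma)
  for (i in seq_len(nrow(pts))) {
    x0 <- pts$x_px[i]; y0 <- pts$y_px[i]; f <- pts$frame[i] + 1L
    cx <- round(x0); cy <- round(y0)
    xr <- max(0, cx - half):min(nx - 1, cx + half)
    yr <- max(0, cy - half):min(ny - 1, cy + half)
    g <- amplitude *
      outer(exp(-(yr - y0)^2 / (2 * psf_sigma^2)),
            exp(-(xr - x0)^2 / (2 * psf_sigma^2)))
    stack[yr + 1L, xr + 1L, f] <- stack[yr + 1L, xr + 1L, f] + g
  }
  if (noise_sd > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  rownames(pts) <- NULL
  list(stack = stack, truth = pts)
}

#' Write a movie stack as a 16-bit multi-page TIFF
#'
#' Counts are clipped to \[0, 65535\] and stored as 16-bit samples.
#'
#' @param stack ny x nx x n_frames numeric array of counts.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(stack[, , f], 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie into a counts array
#'
#' Inverse of [write_movie_tiff()]: 16-bit samples are rescaled to counts.
#'
#' @param path TIFF path.
#' @return ny x nx x n_frames numeric array.
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF movies")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  array(unlist(frames) * 65535,
        dim = c(dim(frames[[1]])[1:2], length(frames)))
}
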