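#' Construct a single-particle trajectory
#'
#' A trajectory is the atom of all analysis in sptkit: one particle's
#' time-ordered 2D positions in micrometres on a contiguous frame grid.
#' Skipped frames are kept as rows with `NA` coordinates (gap placeholders),
#' so that frame indices always advance by one between consecutive rows.
#'
#' @param frame Integer vector of frame indices (0-based, strictly increasing).
#'   Missing interior frames are filled in with gap placeholders.
#' @param x,y Numeric coordinates in micrometres; `NA` marks a gap.
#' @param dt Frame interval in seconds.
#' @param id Trajectory identifier (coerced to character).
#' @param cell_id,session_id,condition Optional metadata strings.
#' @param true_x,true_y Optional noise-free coordinates (same length as `x`),
#'   kept by the simulators so calibration tests can compare against truth.
#' @return A data.frame of class `"spt_trajectory"` with columns `frame`,
#'   `x`, `y` (and `true_x`, `true_y` when supplied) and attributes `id`,
#'   `dt`, `cell_id`, `session_id`, `condition`.
#' @examples
#' tr <- spt_trajectory(0:3, c(0, 1, 2, 3), c(0, 0, 0, 0), dt = 0.1)
#' n_positions(tr)
#' @export
spt_trajectory <- function(frame, x, y, dt, id = "1",
                           cell_id = NA_character_,
                           session_id = NA_character_,
                           condition = NA_character_,
                           true_x = NULL, true_y = NULL) {
  frame <- as.integer(frame)
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) < 2L) stop("a trajectory needs at least 2 frame slots")
  if (any(diff(frame) <= 0L)) stop("frame indices must be strictly increasing")
  if (dt <= 0) stop("dt must be positive")

  # expand to a contiguous frame grid, inserting gap rows where frames skip
  full <- seq(frame[1L], frame[length(frame)])
  idx <- match(full, frame)
  df <- data.frame(frame = full,
                   x = x[idx],
                   y = y[idx])
  if (!is.null(true_x)) {
    df$true_x <- true_x[idx]
    df$true_y <- true_y[idx]
  }
  if (is.na(df$x[1L]) || is.na(df$x[nrow(df)]))
    stop("first and last positions must not be gaps")
  if (sum(!is.na(df$x)) < 2L) stop("a trajectory needs >= 2 non-gap positions")
  structure(df,
            id = as.character(id), dt = dt,
            cell_id = cell_id, session_id = session_id,
            condition = condition,
            class = c("spt_trajectory", "data.frame"))
}

#' @export
print.spt_trajectory <- function(x, ...) {
  cat(sprintf("<spt_trajectory '%s'> %d frame slots (%d gaps), dt = %g s\n",
              attr(x, "id"), nrow(x), sum(is.na(x$x)), attr(x, "dt")))
  invisible(x)
}

#' Number of non-gap positions in a trajectory
#' @param traj An `spt_trajectory`.
#' @return Integer count of rows with observed coordinates.
#' @export
n_positions <- function(traj) sum(!is.na(traj$x))

#' Construct a trajectory ensemble
#'
#' @param trajectories List of [spt_trajectory()] objects.
#' @param labels Optional character vector of per-trajectory ground-truth
#'   mobility classes (simulators fill this in).
#' @param params Optional list of per-trajectory generative parameters.
#' @param pixel_size Pixel size in micrometres per pixel carried as metadata.
#' @return A list of class `"spt_ensemble"` with elements `trajectories`,
#'   `labels`, `params` and attribute `pixel_size`.
#' @export
spt_ensemble <- function(trajectories, labels = NULL, params = NULL,
                         pixel_size = 0.1092) {
  stopifnot(is.list(trajectories))
  if (!is.null(labels) && length(labels) != length(trajectories))
    stop("labels must align 1:1 with trajectories")
  if (!is.null(params) && length(params) != length(trajectories))
    stop("params must align 1:1 with trajectories")
  ids <- vapply(trajectories, function(t) attr(t, "id"), character(1))
  names(trajectories) <- ids
  structure(list(trajectories = trajectories, labels = labels,
                 params = params),
            pixel_size = pixel_size,
            class = "spt_ensemble")
}

#' @export
print.spt_ensemble <- function(x, ...) {
  cat(sprintf("<spt_ensemble> %d trajectories\n", length(x$trajectories)))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' @export
length.spt_ensemble <- function(x) length(x$trajectories)

#' @export
`[.spt_ensemble` <- function(x, i) {
  spt_ensemble(x$trajectories[i],
               labels = if (!is.null(x$labels)) x$labels[i],
               params = if (!is.null(x$params)) x$params[i],
               pixel_size = attr(x, "pixel_size"))
}

#' Frame interval of an ensemble
#' @param ensemble An `spt_ensemble`.
#' @return The common `dt` (seconds) of its trajectories.
#' @export
ensemble_dt <- function(ensemble) {
  dts <- unique(vapply(ensemble$trajectories, attr, numeric(1), "dt"))
  if (length(dts) != 1L) stop("trajectories have differing dt")
  dts
}

#' Flatten an ensemble to the shared trajectory table schema
#'
#' @param x An `spt_ensemble`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return data.frame with columns
#'   `traj_id,frame,x_um,y_um,cell_id,session_id,condition`; gap rows carry
#'   `NA` coordinates.
#' @export
as.data.frame.spt_ensemble <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  out <- lapply(x$trajectories, function(tr) {
    data.frame(traj_id = attr(tr, "id"),
               frame = tr$frame,
               x_um = tr$x, y_um = tr$y,
               cell_id = attr(tr, "cell_id"),
               session_id = attr(tr, "session_id"),
               condition = attr(tr, "condition"))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
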