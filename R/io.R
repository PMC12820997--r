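#' Read trajectories from the shared CSV schema
#'
#' Expects columns `traj_id,frame,x_um,y_um` and optionally
#' `cell_id,session_id,condition`. Empty coordinate fields encode gap
#' placeholders; frames are 0-based integers; coordinates are in micrometres.
#'
#' @param path CSV file path.
#' @param dt Frame interval in seconds (not stored in the CSV).
#' @param pixel_size Pixel size metadata to attach to the ensemble.
#' @return An [spt_ensemble()].
#' @export
read_trajectories <- function(path, dt = 0.1, pixel_size = 0.1092) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(traj_id = "character"))
  need <- c("traj_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (opt in c("cell_id", "session_id", "condition"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_

  key <- paste(df$traj_id, df$frame)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (traj_id, frame) rows at data rows: ",
         paste(utils::head(rows, 10), collapse = ", "))
  }
  trajs <- lapply(split(seq_len(nrow(df)), df$traj_id), function(i) {
    sub <- df[i, ]
    if (is.unsorted(sub$frame, strictly = TRUE)) {
      bad <- i[which(diff(sub$frame) <= 0) + 1L]
      stop("non-monotone frames for trajectory ", sub$traj_id[1],
           " at data rows: ", paste(utils::head(bad, 10), collapse = ", "))
    }
    spt_trajectory(sub$frame, sub$x_um, sub$y_um, dt = dt,
                   id = sub$traj_id[1], cell_id = sub$cell_id[1],
                   session_id = sub$session_id[1],
                   condition = sub$condition[1])
  })
  spt_ensemble(unname(trajs[unique(df$traj_id)]), pixel_size = pixel_size)
}

#' Write an ensemble to the shared CSV schema
#'
#' Gap placeholders are written as empty fields.
#'
#' @param ensemble An [spt_ensemble()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  df <- as.data.frame(ensemble)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build a run manifest
#'
#' Ties an output to its inputs, parameters, seeds and software version so
#' every number is auditable.
#'
#' @param command Short description of the operation performed.
#' @param params Named list of parameter values.
#' @param seeds Named list or vector of seeds used.
#' @param inputs Character vector of input file paths (digested with md5 when
#'   they exist).
#' @return A list of class `"spt_manifest"`.
#' @export
run_manifest <- function(command, params = list(), seeds = list(),
                         inputs = character()) {
  digests <- vapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, character(1))
  structure(list(command = command,
                 inputs = as.list(digests),
                 params = params,
                 seeds = seeds,
                 software = paste0("sptkit ",
                                   as.character(utils::packageVersion("sptkit"))),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ")),
            class = "spt_manifest")
}

#' Write a manifest (or any report list) as JSON
#' @param x List to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
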