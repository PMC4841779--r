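#' Link localizations into trajectories by mutual nearest neighbors
#'
#' Greedy nearest-neighbor linking between consecutive frames: a detection in
#' frame t and a detection in frame t+1 are linked iff each is the other's
#' nearest neighbor and their distance does not exceed `max_displacement`.
#' Unmatched detections start new tracks; tracks end when unmatched. There is
#' no gap closing and no merging/splitting, so a blinking molecule yields
#' separate tracks. Detections are canonically ordered within each frame
#' (by x, then y) before assignment, making the result invariant to the input
#' row order; remaining distance ties are broken by the lower canonical index.
#'
#' @param localizations data frame with columns `frame`, `x_um`, `y_um`
#'   (as produced by [detect_movie()]).
#' @param max_displacement scan radius (um); see
#'   [suggest_max_displacement()] for the default rule.
#' @param field_area optional field area (um^2) used to emit a warning when
#'   the mean per-frame detection density exceeds 0.1/um^2.
#' @return data frame `track_id`, `frame`, `x_um`, `y_um` ordered by track
#'   and frame.
#' @export
link_trajectories <- function(localizations, max_displacement,
                              field_area = NULL) {
  assert_positive(max_displacement, "max_displacement")
  loc <- as.data.frame(localizations)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(loc)))
  if (!nrow(loc)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  loc <- loc[order(loc$frame, loc$x_um, loc$y_um), , drop = FALSE]
  rownames(loc) <- NULL

  if (!is.null(field_area)) {
    dens <- nrow(loc) / length(unique(loc$frame)) / field_area
    if (dens > 0.1)
      warning(sprintf("mean detection density %.3f/um^2 exceeds 0.1/um^2: %s",
                      dens, "risk of mistracking"), call. = FALSE)
  }

  idx_by_frame <- split(seq_len(nrow(loc)), loc$frame)
  frames <- as.integer(names(idx_by_frame))
  track_id <- integer(nrow(loc))
  next_id <- 0L

  # start tracks in the first frame
  for (i in idx_by_frame[[1L]]) { next_id <- next_id + 1L; track_id[i] <- next_id }

  if (length(frames) > 1L) for (k in seq_len(length(frames) - 1L)) {
    a <- idx_by_frame[[k]]; b <- idx_by_frame[[k + 1L]]
    linked_b <- rep(FALSE, length(b))
    if (frames[k + 1L] == frames[k] + 1L && length(a) && length(b)) {
      dmat <- outer(loc$x_um[a], loc$x_um[b], "-")^2 +
              outer(loc$y_um[a], loc$y_um[b], "-")^2
      nn_a <- apply(dmat, 1L, which.min)   # which.min breaks ties low index
      nn_b <- apply(dmat, 2L, which.min)
      for (i in seq_along(a)) {
        j <- nn_a[i]
        if (nn_b[j] == i && dmat[i, j] <= max_displacement^2) {
          track_id[b[j]] <- track_id[a[i]]
          linked_b[j] <- TRUE
        }
      }
    }
    for (j in which(!linked_b)) {
      next_id <- next_id + 1L
      track_id[b[j]] <- next_id
    }
  }

  out <- data.frame(track_id = track_id, frame = loc$frame,
                    x_um = loc$x_um, y_um = loc$y_um)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  # renumber tracks in order of first appearance
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}

#' Default nearest-neighbor scan radius from an estimated diffusion rate
#'
#' `3 * sqrt(4 * D * dt)`: three times the RMS frame-to-frame displacement of
#' a Brownian molecule. At this radius the probability of a true displacement
#' falling outside the scan area is `exp(-9)` (~1e-4), so the linked
#' displacement distribution is essentially untruncated; a tighter 2x radius
#' discards ~2% of true links and biases MSD-derived D low by ~7%.
#'
#' @param D estimated diffusion coefficient (um^2/s), e.g. from a pilot
#'   [compute_msd()] pass.
#' @param frame_interval frame interval (s).
#' @return scan radius (um).
#' @export
suggest_max_displacement <- function(D, frame_interval) {
  assert_nonneg(D, "D"); assert_positive(frame_interval, "frame_interval")
  3 * sqrt(4 * D * frame_interval)
}

#' Write / read trajectory tables as CSV
#'
#' The dialect is UTF-8 comma-separated with a mandatory header row and
#' columns `track_id, frame, x_um, y_um`.
#'
#' @param tracks trajectory data frame.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks[, c("track_id", "frame", "x_um", "y_um")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) read.csv(path)

#' Write a localization table as CSV
#'
#' Columns: `frame, x_um, y_um, intensity, snr` (UTF-8, header mandatory).
#'
#' @param localizations data frame from [detect_movie()].
#' @param path file path.
#' @export
write_localizations_csv <- function(localizations, path) {
  write.csv(localizations[, c("frame", "x_um", "y_um", "intensity", "snr")],
            path, row.names = FALSE)
  invisible(path)
}
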