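#' Partition trajectories into cluster and non-cluster groups
#'
#' A trajectory belongs to the cluster group iff its first localization falls
#' on a mask pixel; the two groups are disjoint and exhaustive. Mask and
#' trajectories must share the coordinate frame (pixel (0,0) covers
#' `[0, pixel_size)^2`).
#'
#' @param tracks trajectory data frame (`track_id`, `frame`, `x_um`, `y_um`).
#' @param mask a `cluster_mask` from [segment_clusters()].
#' @return list with `assignment` (data frame `track_id`, `clustered`),
#'   `cluster` and `non_cluster` (the corresponding subsets of `tracks`).
#'   Localizations outside the image bounds are an error.
#' @export
partition_trajectories <- function(tracks, mask) {
  stopifnot(inherits(mask, "cluster_mask"))
  if (!nrow(tracks)) {
    empty <- tracks
    return(list(assignment = data.frame(track_id = integer(0),
                                        clustered = logical(0)),
                cluster = empty, non_cluster = empty))
  }
  first <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    tr[which.min(tr$frame), c("track_id", "x_um", "y_um")]
  }))
  ps <- mask$pixel_size
  col <- floor(first$x_um / ps) + 1L
  row <- floor(first$y_um / ps) + 1L
  if (any(col < 1L | col > ncol(mask$mask) | row < 1L | row > nrow(mask$mask)))
    stop2("localization outside image bounds")
  clustered <- mask$mask[cbind(row, col)]
  assignment <- data.frame(track_id = first$track_id, clustered = clustered)
  rownames(assignment) <- NULL
  in_cluster <- tracks$track_id %in% assignment$track_id[assignment$clustered]
  list(assignment = assignment,
       cluster = tracks[in_cluster, , drop = FALSE],
       non_cluster = tracks[!in_cluster, , drop = FALSE])
}

#' Group-wise apparent on-rates (cluster / non-cluster / whole)
#'
#' Computes the gamma_on time course (see [estimate_gamma_on()]) for the
#' whole trajectory set and for the cluster group, and derives the
#' non-cluster series as total minus cluster, so the three series are exactly
#' consistent window by window.
#'
#' @param partition result of [partition_trajectories()].
#' @param window_length window length (s).
#' @param frame_interval frame interval (s).
#' @param t_grid optional window start grid (s); defaults to contiguous
#'   windows covering the whole set.
#' @return list of three `rate_timecourse` data frames: `total`, `cluster`,
#'   `non_cluster`.
#' @export
groupwise_gamma_on <- function(partition, window_length = 48,
                               frame_interval = NULL, t_grid = NULL) {
  all_tracks <- rbind(partition$cluster, partition$non_cluster)
  total <- estimate_gamma_on(all_tracks, window_length, t_grid,
                             frame_interval)
  if (is.null(t_grid)) t_grid <- total$window_start_s
  cluster <- if (nrow(partition$cluster)) {
    estimate_gamma_on(partition$cluster, window_length, t_grid,
                      frame_interval)
  } else {
    z <- total
    z$n_events <- 0L; z$gamma_on_per_min <- 0; z$se_per_min <- 0
    z
  }
  non_cluster <- total
  non_cluster$n_events <- total$n_events - cluster$n_events
  non_cluster$gamma_on_per_min <-
    total$gamma_on_per_min - cluster$gamma_on_per_min
  non_cluster$se_per_min <- sqrt(non_cluster$n_events) / (window_length / 60)
  list(total = total, cluster = cluster, non_cluster = non_cluster)
}
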