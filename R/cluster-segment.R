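#' Deterministic 1D 2-means intensity threshold
#'
#' Exact two-means partition of the pixel intensities: in one dimension the
#' optimal 2-means clustering is an interval split of the sorted values, so
#' the globally optimal split is found by scanning all split points with
#' prefix sums (O(n log n), fully deterministic — no random initialization).
#' The threshold is the midpoint between the two cluster centers.
#'
#' @param values numeric vector of intensities.
#' @return list with `threshold`, `centers` (sorted), `withinss`. A constant
#'   input returns `threshold = Inf` (nothing above threshold).
#' @export
kmeans_threshold <- function(values) {
  v <- sort(as.numeric(values[is.finite(values)]))
  n <- length(v)
  if (!n) stop2("no finite intensities")
  if (v[1] == v[n])
    return(list(threshold = Inf, centers = c(v[1], v[n]), withinss = 0))
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  k <- seq_len(n - 1L)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  ss <- ss_lo + ss_hi
  ss[v[k] == v[k + 1L]] <- Inf   # split must separate distinct values
  kbest <- which.min(ss)
  c1 <- cs[kbest] / kbest
  c2 <- (cs[n] - cs[kbest]) / (n - kbest)
  list(threshold = (c1 + c2) / 2, centers = sort(c(c1, c2)),
       withinss = ss[kbest])
}

# two-pass union-find labeling of 8-connected foreground components
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc]) next
    nbs <- integer(0)
    if (rr > 1 && mask[rr - 1, cc]) nbs <- c(nbs, labels[rr - 1, cc])
    if (cc > 1) {
      if (mask[rr, cc - 1]) nbs <- c(nbs, labels[rr, cc - 1])
      if (rr > 1 && mask[rr - 1, cc - 1]) nbs <- c(nbs, labels[rr - 1, cc - 1])
      if (rr < nr && mask[rr + 1, cc - 1]) nbs <- c(nbs, labels[rr + 1, cc - 1])
    }
    if (!length(nbs)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      labels[rr, cc] <- nxt
    } else {
      roots <- unique(vapply(nbs, find, integer(1)))
      r0 <- min(roots)
      labels[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(labels)
  # resolve and compact labels
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  idx <- labels > 0L
  labels[idx] <- remap[roots[labels[idx]]]
  labels
}

#' Segment binding-site clusters by k-means thresholding
#'
#' Pixels above the deterministic 1D 2-means threshold (see
#' [kmeans_threshold()]) form a binary mask; 8-connected components are
#' labeled and components smaller than `min_size_psf` PSF areas
#' (`pi * psf_sigma^2`) are removed. A constant image yields an empty mask
#' (no clusters), not an error. The threshold adapts to the intensity scale,
#' so segmentation is invariant to multiplying the image by a constant.
#'
#' @param image numeric matrix (row = y, col = x), e.g. a single frame or a
#'   temporal mean over a window ([temporal_mean()]).
#' @param pixel_size pixel size (um/px).
#' @param psf_sigma PSF standard deviation (um) defining the minimum
#'   component size.
#' @param min_size_psf minimum component size in PSF areas.
#' @return object of class `cluster_mask`: list with `mask` (logical matrix),
#'   `labels` (integer matrix, labels contiguous from 1), `stats` (per
#'   component: `label`, `area_um2`, `mean_intensity`, `centroid_x_um`,
#'   `centroid_y_um`), `threshold`, `pixel_size`.
#' @export
segment_clusters <- function(image, pixel_size, psf_sigma,
                             min_size_psf = 1) {
  image <- as.matrix(image)
  assert_positive(pixel_size, "pixel_size")
  assert_positive(psf_sigma, "psf_sigma")
  km <- kmeans_threshold(as.vector(image))
  mask <- image > km$threshold
  labels <- label_components_8(mask)

  min_px <- max(1L, ceiling(min_size_psf * pi * psf_sigma^2 / pixel_size^2))
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    drop <- which(sizes < min_px)
    if (length(drop)) {
      mask[labels %in% drop] <- FALSE
      labels[labels %in% drop] <- 0L
      keep <- which(sizes >= min_px)
      remap <- integer(length(sizes))
      remap[keep] <- seq_along(keep)
      labels[labels > 0L] <- remap[labels[labels > 0L]]
    }
  }

  n_comp <- max(labels)
  stats <- if (n_comp > 0L) {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    vals <- image[labels > 0L]
    do.call(rbind, lapply(seq_len(n_comp), function(l) {
      sel <- lab == l
      data.frame(label = l,
                 area_um2 = sum(sel) * pixel_size^2,
                 mean_intensity = mean(vals[sel]),
                 centroid_x_um = (mean(idx[sel, "col"]) - 0.5) * pixel_size,
                 centroid_y_um = (mean(idx[sel, "row"]) - 0.5) * pixel_size)
    }))
  } else {
    data.frame(label = integer(0), area_um2 = numeric(0),
               mean_intensity = numeric(0), centroid_x_um = numeric(0),
               centroid_y_um = numeric(0))
  }
  structure(list(mask = mask, labels = labels, stats = stats,
                 threshold = km$threshold, pixel_size = pixel_size),
            class = "cluster_mask")
}

#' Cluster statistics and the clustering metric
#'
#' The clustering metric is mean cluster size (um^2) times cluster number,
#' the quantity used to follow binding-site cluster formation over time. For
#' an empty mask the metric is 0.
#'
#' @param mask a `cluster_mask` from [segment_clusters()].
#' @param time time point of the underlying image (s).
#' @return one-row data frame: `t_s`, `cluster_count`, `mean_cluster_size_um2`,
#'   `clustering_metric` (= size x count).
#' @export
cluster_stats <- function(mask, time = NA_real_) {
  stopifnot(inherits(mask, "cluster_mask"))
  n <- nrow(mask$stats)
  mean_size <- if (n) mean(mask$stats$area_um2) else 0
  data.frame(t_s = time, cluster_count = n,
             mean_cluster_size_um2 = mean_size,
             clustering_metric = mean_size * n)
}

#' Temporal mean image over a frame window
#'
#' @param movie a `movie_stack`.
#' @param frames integer frame indices (0-based) to average.
#' @return numeric matrix.
#' @export
temporal_mean <- function(movie, frames) {
  stopifnot(inherits(movie, "movie_stack"))
  sel <- frames + 1L
  Reduce(`+`, movie$frames[sel]) / length(sel)
}

#' Write a cluster mask as 8-bit TIFF
#'
#' Mask pixels are written as 255, background as 0.
#'
#' @param mask a `cluster_mask`.
#' @param path output TIFF path.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "cluster_mask"))
  tiff::writeTIFF(ifelse(mask$mask, 1, 0), path, bits.per.sample = 8)
  invisible(path)
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat("<cluster_mask>", nrow(x$stats), "components, threshold =",
      signif(x$threshold, 5), "\n")
  invisible(x)
}
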