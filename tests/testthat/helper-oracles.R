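# Independent brute-force oracles and fixture builders used across the suite.

# naive exhaustive 1D 2-means: try every split of the sorted values and
# recompute means/SS directly
brute_kmeans2_threshold <- function(v) {
  v <- sort(v[is.finite(v)])
  n <- length(v)
  best_ss <- Inf
  best_thr <- Inf
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next
    lo <- v[1:k]; hi <- v[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best_thr <- (mean(lo) + mean(hi)) / 2
    }
  }
  best_thr
}

# naive O(n^3) average-linkage agglomeration on uncentered correlation;
# similarities recomputed from scratch at every step; ties broken by the
# lexicographically smallest sorted member-label string
naive_uncentered <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

naive_avg_linkage <- function(mat) {
  labels <- rownames(mat)
  clusters <- lapply(seq_len(nrow(mat)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_sim <- -Inf; best_key <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        sims <- c()
        for (a in clusters[[i]]) for (b in clusters[[j]])
          sims <- c(sims, naive_uncentered(mat[a, ], mat[b, ]))
        sim <- mean(sims)
        key <- paste(sort(labels[c(clusters[[i]], clusters[[j]])]),
                     collapse = "\r")
        if (sim > best_sim + 1e-12 ||
            (abs(sim - best_sim) <= 1e-12 &&
             (is.null(best_key) || key < best_key))) {
          best <- c(i, j); best_sim <- sim; best_key <- key
        }
      }
    }
    members <- sort(labels[c(clusters[[best[1]]], clusters[[best[2]]])])
    merges[[length(merges) + 1]] <-
      data.frame(similarity = best_sim,
                 members = paste(members, collapse = ","))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  do.call(rbind, merges)
}

# two series of length n with exact Pearson correlation r (Gram-Schmidt)
correlated_series <- function(r, n, seed = 1) {
  set.seed(seed)
  a <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ a))            # orthogonal to a
  a_s <- as.numeric(scale(a))
  e_s <- as.numeric(scale(e))
  b <- r * a_s + sqrt(1 - r^2) * e_s
  list(a = a_s, b = b)
}

# direct Brownian trajectory table (no imaging), for MSD-only tests
brownian_tracks <- function(n_tracks, len, D, dt, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    data.frame(track_id = i, frame = 0:(len - 1),
               x_um = cumsum(c(10, rnorm(len - 1, 0, sqrt(2 * D * dt)))),
               y_um = cumsum(c(10, rnorm(len - 1, 0, sqrt(2 * D * dt)))))
  }))
}

# hand-built single-molecule event log (for renderer unit tests)
manual_event_log <- function(x, y, n_frames, config) {
  positions <- data.frame(frame = 0:(n_frames - 1),
                          t_s = (0:(n_frames - 1)) * config$frame_interval,
                          molecule_id = 1L, x_um = x, y_um = y,
                          observable = TRUE)
  events <- data.frame(molecule_id = 1L, bind_time_s = 0,
                       unbind_time_s = NA_real_, censored = TRUE,
                       n_rebinds = 0L, bleach_time_s = Inf,
                       first_site_id = 1L)
  structure(list(events = events, positions = positions,
                 occupancy = data.frame(frame = 0:(n_frames - 1),
                                        t_s = positions$t_s,
                                        n_bound = 1L, n_phospho = 1L,
                                        cum_bindings = 1L),
                 t_end = (n_frames - 1) * config$frame_interval,
                 config = config),
            class = "binding_event_log")
}

# match detections to ground truth within one PSF radius; returns counts
match_detections <- function(truth, detections, radius) {
  tp <- 0L
  for (f in unique(truth$frame)) {
    tru <- truth[truth$frame == f, , drop = FALSE]
    det <- detections[detections$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    for (i in seq_len(nrow(tru))) {
      if (!nrow(det)) next
      d2 <- (det$x_um - tru$x_um[i])^2 + (det$y_um - tru$y_um[i])^2
      d2[used] <- Inf
      j <- which.min(d2)
      if (length(j) && d2[j] <= radius^2) { tp <- tp + 1L; used[j] <- TRUE }
    }
  }
  list(tp = tp, n_truth = nrow(truth), n_det = nrow(detections))
}
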