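test_that("the 2-means threshold separates constructed bimodal images exactly", {
  set.seed(3)
  img <- matrix(rnorm(64 * 64, 10, 1), 64, 64)
  disc <- function(cx, cy, r) {
    idx <- expand.grid(row = 1:64, col = 1:64)
    idx[(idx$row - cy)^2 + (idx$col - cx)^2 <= r^2, ]
  }
  d1 <- disc(16, 16, 4); d2 <- disc(44, 40, 6)
  img[as.matrix(d1[, c("row", "col")])] <- 100
  img[as.matrix(d2[, c("row", "col")])] <- 100
  mask <- segment_clusters(img, pixel_size = 0.16, psf_sigma = 0.16)
  expect_identical(nrow(mask$stats), 2L)
  areas_px <- sort(mask$stats$area_um2) / 0.16^2
  expect_equal(areas_px, sort(c(nrow(d1), nrow(d2))))

  # intensity scale invariance: same mask, same metric
  mask5 <- segment_clusters(img * 5, 0.16, 0.16)
  expect_identical(mask$mask, mask5$mask)
  expect_equal(cluster_stats(mask)$clustering_metric,
               cluster_stats(mask5)$clustering_metric)
})

test_that("constant and sparse-noise images yield no clusters", {
  # constant image: empty mask, not an error
  m <- segment_clusters(matrix(7, 32, 32), 0.16, 0.16)
  expect_identical(nrow(m$stats), 0L)
  expect_true(all(!m$mask))
  expect_equal(cluster_stats(m)$clustering_metric, 0)

  # isolated bright pixels (shot noise) are removed by the PSF-area filter
  set.seed(4)
  img <- matrix(10, 64, 64)
  img[sample(64 * 64, 60)] <- 100
  m2 <- segment_clusters(img, 0.16, 0.2)
  expect_identical(nrow(m2$stats), 0L)
})

test_that("k-means threshold equals the exhaustive-search oracle", {
  toy <- rep(c(5, 50, 100), each = 10)
  expect_equal(kmeans_threshold(toy)$threshold, brute_kmeans2_threshold(toy))

  set.seed(11)
  for (r in 1:50) {
    v <- sample(0:63, 40, replace = TRUE)   # <= 64 distinct intensity levels
    if (min(v) == max(v)) next
    expect_equal(kmeans_threshold(v)$threshold, brute_kmeans2_threshold(v),
                 tolerance = 1e-12)
  }
})

test_that("8-connected labeling joins diagonal pixels", {
  img <- matrix(0, 16, 16)
  img[cbind(c(4, 5, 6), c(4, 5, 6))] <- 100   # diagonal run
  m <- segment_clusters(img, 0.16, 0.1, min_size_psf = 0.5)
  expect_identical(nrow(m$stats), 1L)
  expect_equal(m$stats$area_um2, 3 * 0.16^2)
})

test_that("trajectory partition is exhaustive, disjoint and bounds-checked", {
  tracks <- data.frame(track_id = rep(1:10, each = 3),
                       frame = rep(0:2, 10),
                       x_um = rep(seq(0.5, 9.5, by = 1), each = 3),
                       y_um = 5)
  empty_mask <- segment_clusters(matrix(1, 64, 64), 0.16, 0.16)
  p <- partition_trajectories(tracks, empty_mask)
  expect_identical(nrow(p$cluster), 0L)
  expect_identical(nrow(p$non_cluster), nrow(tracks))

  full <- empty_mask; full$mask[] <- TRUE
  p2 <- partition_trajectories(tracks, full)
  expect_identical(nrow(p2$non_cluster), 0L)

  # conservation for a random mask
  half <- empty_mask; half$mask[, 1:32] <- TRUE
  p3 <- partition_trajectories(tracks, half)
  expect_identical(nrow(p3$cluster) + nrow(p3$non_cluster), nrow(tracks))
  expect_identical(sort(unique(c(p3$cluster$track_id,
                                 p3$non_cluster$track_id))), 1:10)

  out <- tracks; out$x_um[1] <- 100
  expect_error(partition_trajectories(out, empty_mask), "outside")
})

test_that("group-wise gamma_on is exactly additive", {
  mk <- function(ids, starts) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      data.frame(track_id = ids[i], frame = starts[i] + 0:2,
                 x_um = 1, y_um = 1)
    }))
  }
  partition <- list(cluster = mk(1:18, rep(10, 18)),
                    non_cluster = mk(19:24, rep(20, 6)))
  g <- groupwise_gamma_on(partition, window_length = 48,
                          frame_interval = 0.1, t_grid = 0)
  expect_equal(g$cluster$gamma_on_per_min, 22.5)
  expect_equal(g$non_cluster$gamma_on_per_min, 7.5)
  expect_equal(g$total$gamma_on_per_min, 30)
  expect_equal(g$total$gamma_on_per_min,
               g$cluster$gamma_on_per_min + g$non_cluster$gamma_on_per_min)
})

test_that("clustered binding sites partition tracks at >95% accuracy", {
  # strongly clustered field, clusters formed from the start; the mask is
  # computed from the temporal mean of a densely activated movie
  cfg <- suppressWarnings(   # dense activation emulates the total channel
    simulation_config(n_frames = 120, frame_interval = 0.5,
                      n_sites = 240, tau_phospho = 2, tau_cluster = 2,
                      clustered_fraction_max = 0.85, cluster_count = 6,
                      cluster_radius = 0.25, k_off_true = 1,
                      rebind_probability = 0.3, D_bound = 0.002,
                      activation_density = 5, seed = 19))
  field <- simulate_phosphosite_dynamics(cfg)
  log <- simulate_sh2_binding(field, cfg)
  mov <- render_movie(log, cfg)
  img <- temporal_mean(mov, 20:119)
  mask <- segment_clusters(img, cfg$pixel_size, cfg$psf_sigma)
  expect_gt(nrow(mask$stats), 0)

  # ground-truth tracks from the simulator's observable positions
  tracks <- data.frame(track_id = log$positions$molecule_id,
                       frame = log$positions$frame,
                       x_um = log$positions$x_um, y_um = log$positions$y_um)
  p <- partition_trajectories(tracks, mask)

  # ground truth: was the first bound site inside a cluster at bind time?
  ev <- log$events
  st <- field$sites[ev$first_site_id, ]
  truly_clustered <- is.finite(st$t_cluster) & st$t_cluster <= ev$bind_time_s
  truth <- data.frame(track_id = ev$molecule_id, clustered = truly_clustered)
  cmp <- merge(p$assignment, truth, by = "track_id",
               suffixes = c("_called", "_true"))
  acc <- mean(cmp$clustered_called == cmp$clustered_true)
  expect_gte(acc, 0.95)
})

test_that("cluster-group recruitment lags non-cluster recruitment when clustering is slow", {
  cfg <- scenario_config("egf-clustered", seed = 23)
  field <- simulate_phosphosite_dynamics(cfg)
  log <- simulate_sh2_binding(field, cfg)
  ev <- log$events
  st <- field$sites[ev$first_site_id, ]
  clustered <- is.finite(st$t_cluster) & st$t_cluster <= ev$bind_time_s
  grid <- seq(0, log$t_end - 48, by = 48)
  g_cl <- estimate_gamma_on(ev$bind_time_s[clustered], t_grid = grid)
  g_nc <- estimate_gamma_on(ev$bind_time_s[!clustered], t_grid = grid)
  tau_cl <- fit_recovery(g_cl$window_mid_s / 60, g_cl$gamma_on_per_min)$tau
  tau_nc <- fit_recovery(g_nc$window_mid_s / 60, g_nc$gamma_on_per_min)$tau
  expect_gt(tau_cl, tau_nc)
})
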