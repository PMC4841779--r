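test_that("detection handles empty and ideal single-spot frames", {
  expect_identical(nrow(detect_spots(matrix(0, 64, 64), 0.16, 0.16)), 0L)
  expect_error(detect_spots(matrix(0, 64, 64), 0.16, 0.05),
               "half a pixel")

  cfg <- suppressWarnings(
    simulation_config(n_sites = 1, n_frames = 3, field_size = 10.24,
                      photons_per_molecule = 800, background_photons = 10,
                      activation_density = 1, seed = 4))
  x <- 5.131; y <- 3.274
  log <- manual_event_log(x, y, 3, cfg)
  mov <- render_movie(log, cfg, noise = FALSE)
  loc <- detect_spots(mov$frames[[1]], cfg$pixel_size, cfg$psf_sigma)
  expect_identical(nrow(loc), 1L)
  # sub-pixel accuracy: within 0.05 px of the true center
  expect_lt(abs(loc$x_um - x), 0.05 * cfg$pixel_size)
  expect_lt(abs(loc$y_um - y), 0.05 * cfg$pixel_size)
})

test_that("recall and precision exceed 0.95 on rendered movies at SNR ~8", {
  # peak amplitude ~ photons/(2*pi*sigma_px^2) = 230/6.28 ~ 37 counts over a
  # raw background MAD of ~4.5 counts: SNR ~ 8 under the package's definition
  cfg <- simulation_config(field_size = 10.24, n_frames = 200,
                           n_sites = 400, tau_phospho = 5,
                           clustered_fraction_max = 0,
                           rebind_probability = 0, k_off_true = 0.5,
                           activation_density = 0.03,
                           photons_per_molecule = 230, seed = 31)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  mov <- render_movie(log, cfg)
  loc <- detect_movie(mov, psf_sigma = cfg$psf_sigma, threshold_snr = 5)
  m <- match_detections(mov$truth, loc, cfg$psf_sigma)
  expect_gte(m$tp / m$n_truth, 0.95)   # recall
  expect_gte(m$tp / m$n_det, 0.95)     # precision
})

test_that("linking produces the expected trajectories in controlled cases", {
  # one detection per frame, static -> one trajectory spanning all frames
  loc <- data.frame(frame = 0:19, x_um = 5, y_um = 5)
  tr <- link_trajectories(loc, max_displacement = 0.2)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 20L)

  # two static molecules 10 x max_displacement apart -> two trajectories
  loc2 <- rbind(data.frame(frame = rep(0:19, 2),
                           x_um = rep(c(2, 4), each = 20), y_um = 5))
  tr2 <- link_trajectories(loc2, max_displacement = 0.2)
  expect_identical(length(unique(tr2$track_id)), 2L)

  # localization count is conserved: each belongs to exactly one trajectory
  expect_identical(nrow(tr2), nrow(loc2))

  # permutation invariance of the input ordering
  set.seed(1)
  loc3 <- data.frame(frame = rep(0:9, each = 5),
                     x_um = runif(50, 0, 10), y_um = runif(50, 0, 10))
  tr_a <- link_trajectories(loc3, 0.5)
  tr_b <- link_trajectories(loc3[sample(50), ], 0.5)
  expect_identical(tr_a, tr_b)
})

test_that("tracks of simulated Brownian molecules are recovered without switches", {
  cfg <- simulation_config(field_size = 10.24, n_frames = 200, n_sites = 400,
                           tau_phospho = 5, clustered_fraction_max = 0,
                           rebind_probability = 0, k_off_true = 0.5,
                           D_bound = 0.02, activation_density = 0.03,
                           seed = 37)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  mov <- render_movie(log, cfg)
  loc <- detect_movie(mov, psf_sigma = cfg$psf_sigma)
  tr <- link_trajectories(loc, suggest_max_displacement(0.02, 0.1))

  # assign every localization to the nearest ground-truth molecule
  assign_mol <- function(f, x, y) {
    tru <- mov$truth[mov$truth$frame == f, ]
    if (!nrow(tru)) return(NA_integer_)
    d2 <- (tru$x_um - x)^2 + (tru$y_um - y)^2
    if (min(d2) > cfg$psf_sigma^2) return(NA_integer_)
    tru$molecule_id[which.min(d2)]
  }
  tr$mol <- mapply(assign_mol, tr$frame, tr$x_um, tr$y_um)
  by_track <- split(tr$mol, tr$track_id)
  pure <- vapply(by_track, function(m) {
    m <- m[!is.na(m)]
    length(m) > 0 && length(unique(m)) == 1
  }, logical(1))
  expect_gte(mean(pure), 0.95)

  # >= 90% of ground-truth tracks (2+ visible frames) recovered by a pure track
  truth_tracks <- table(mov$truth$molecule_id)
  eligible <- as.integer(names(truth_tracks)[truth_tracks >= 2])
  lens <- vapply(by_track, length, integer(1))
  pure_track_mols <- unique(unlist(lapply(which(pure & lens >= 2), function(i) {
    m <- by_track[[i]]
    unique(m[!is.na(m)])[1]
  })))
  expect_gte(mean(eligible %in% pure_track_mols), 0.90)
})

test_that("MSD is exact for static and drifting molecules", {
  # static: MSD identically zero, D = 0
  tr <- data.frame(track_id = 1, frame = 0:9, x_um = 3, y_um = 3)
  m <- compute_msd(tr, 0.1)
  expect_true(all(m$msd$msd_um2 == 0))
  expect_equal(m$D_um2_s, 0)

  # deterministic drift v: MSD(lag) = (v * lag * dt)^2 exactly; the linear
  # fit must still return a D and a nonzero residual norm revealing curvature
  v <- 1.5; dt <- 0.1
  tr <- data.frame(track_id = 1, frame = 0:29,
                   x_um = v * (0:29) * dt, y_um = 0)
  m <- compute_msd(tr, dt, max_lag = 6)
  expect_equal(m$msd$msd_um2, (v * m$msd$lag_s)^2, tolerance = 1e-12)
  expect_true(is.finite(m$D_um2_s))
  expect_gt(m$residual_norm, 1e-6)

  # no qualifying trajectory -> explicit empty result
  short <- data.frame(track_id = 1, frame = 0:1, x_um = 0, y_um = 0)
  expect_warning(m0 <- compute_msd(short, 0.1), "no trajectory")
  expect_identical(m0$n_trajectories, 0L)
  expect_true(is.na(m0$D_um2_s))
})

test_that("MSD recovers the diffusion coefficient of Brownian tracks within 10%", {
  tr <- brownian_tracks(3000, 10, D = 0.021, dt = 0.1, seed = 5)
  m <- compute_msd(tr, 0.1)
  expect_gte(m$n_trajectories, 3000)
  expect_lt(abs(m$D_um2_s - 0.021) / 0.021, 0.10)
  # the per-track D distribution is unbiased in the mean (the median of
  # short-track estimates is skewed low, a known property of per-trajectory
  # MSD fits)
  expect_lt(abs(mean(m$per_track$D_um2_s, na.rm = TRUE) - 0.021) / 0.021,
            0.10)
})
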