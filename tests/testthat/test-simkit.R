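test_that("phosphosite creation follows first-order kinetics", {
  # rate -> 0 limit: essentially no site phosphorylates within the movie
  cfg <- simulation_config(n_sites = 1000, tau_phospho = 1e9, seed = 3)
  field <- simulate_phosphosite_dynamics(cfg)
  expect_identical(n_phosphorylated(field, 60), 0L)

  # tau = 60 s at t = 60 s: expected count n * (1 - exp(-1)) = 632,
  # within binomial sampling error
  cfg <- simulation_config(n_sites = 1000, tau_phospho = 60, seed = 3)
  field <- simulate_phosphosite_dynamics(cfg)
  p <- 1 - exp(-1)
  expect_lt(abs(n_phosphorylated(field, 60) - 1000 * p),
            4 * sqrt(1000 * p * (1 - p)))

  # deterministic given the seed
  field2 <- simulate_phosphosite_dynamics(cfg)
  expect_identical(field$sites, field2$sites)

  # monotone non-decreasing without dephosphorylation
  counts <- n_phosphorylated(field, seq(0, 300, by = 5))
  expect_true(all(diff(counts) >= 0))
})

test_that("clustering destiny and geometry respect the configuration", {
  cfg <- simulation_config(n_sites = 400, clustered_fraction_max = 0, seed = 5)
  field <- simulate_phosphosite_dynamics(cfg)
  st <- site_state(field, 1e6)
  expect_true(all(is.na(st$cluster_id)))

  cfg <- simulation_config(n_sites = 400, clustered_fraction_max = 0.7,
                           tau_cluster = 30, cluster_count = 6,
                           cluster_radius = 0.25, seed = 5)
  field <- simulate_phosphosite_dynamics(cfg)
  st <- site_state(field, 1e6)   # after all relocations
  frac <- mean(!is.na(st$cluster_id))
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / 400))
  # every clustered site lies within the disc of its cluster center
  cl <- st[!is.na(st$cluster_id), ]
  ctr <- field$centers[cl$cluster_id, ]
  expect_true(all((cl$x_um - ctr$cx)^2 + (cl$y_um - ctr$cy)^2 <=
                    cfg$cluster_radius^2 + 1e-12))
  # cluster centers inside the field
  expect_true(all(field$centers$cx >= 0 & field$centers$cx <= cfg$field_size))

  expect_error(simulation_config(n_sites = 5, cluster_count = 10,
                                 clustered_fraction_max = 0.5),
               "cluster_count")
})

test_that("binding log degenerate and censored cases behave", {
  cfg <- simulation_config(n_sites = 50, k_on_intrinsic = 0, n_frames = 50,
                           seed = 2)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  expect_identical(nrow(log$events), 0L)

  # one always-phosphorylated site, no unbinding, no bleaching: a single
  # event censored at the movie end
  cfg <- simulation_config(n_sites = 1, tau_phospho = 1e-6, k_off_true = 0,
                           k_bleach = 0, n_frames = 80,
                           k_on_intrinsic = 2.5e-3, seed = 2)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  expect_identical(nrow(log$events), 1L)
  expect_true(log$events$censored)
  expect_true(is.na(log$events$unbind_time_s))

  expect_error(simulation_config(k_off_true = -1), "k_off_true")
})

test_that("exponential dwell MLE recovers the intrinsic off-rate without rebinding", {
  cfg <- simulation_config(n_sites = 400, tau_phospho = 1e-6,
                           clustered_fraction_max = 0, rebind_probability = 0,
                           k_off_true = 0.5, k_on_intrinsic = 2.5e-5,
                           n_frames = 1200, seed = 7)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  dw <- dwell_times(log)
  expect_gt(sum(!dw$censored), 3000)
  lam <- sum(!dw$censored) / sum(dw$dwell_s)   # closed-form censored MLE
  expect_lt(abs(lam - 0.5) / 0.5, 0.10)
})

test_that("molecule bookkeeping is exactly conservative", {
  cfg <- scenario_config("egf-clustered", seed = 11, n_frames = 241L,
                         n_sites = 150L)
  log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  ev <- log$events
  occ <- log$occupancy
  # bound(t) = bindings up to t minus unbindings up to t, at every frame
  for (i in seq(1, nrow(occ), by = 20)) {
    t <- occ$t_s[i]
    expect_identical(occ$n_bound[i],
                     sum(ev$bind_time_s <= t) -
                       sum(!is.na(ev$unbind_time_s) & ev$unbind_time_s <= t))
  }
  # occupancy never exceeds the phosphorylated-site count
  expect_true(all(occ$n_bound <= occ$n_phospho))
  # uncensored events have unbind strictly after bind
  expect_true(all(ev$unbind_time_s[!ev$censored] > ev$bind_time_s[!ev$censored]))
})

test_that("constant-rate occupancy matches the closed form over replicates", {
  n_rep <- 50
  gamma_site <- 2.5e-5 * 3914                     # per-site binding rate (1/s)
  n_sites <- 30; k_off <- 1
  curves <- sapply(seq_len(n_rep), function(r) {
    cfg <- simulation_config(n_sites = n_sites, tau_phospho = 1e-6,
                             clustered_fraction_max = 0,
                             rebind_probability = 0, k_off_true = k_off,
                             n_frames = 150, seed = 1000 + r)
    log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
    log$occupancy$n_bound
  })
  t <- (0:149) * 0.1
  gamma <- n_sites * gamma_site
  expected <- (gamma / k_off) * (1 - exp(-k_off * t))
  mc_mean <- rowMeans(curves)
  # pointwise binomial-ish sampling error of the replicate mean
  se <- sqrt(pmax(expected, 0.05)) / sqrt(n_rep)
  expect_lt(mean(abs(mc_mean - expected) / (4 * se + 1e-9)), 1)
  expect_lt(abs(mean(mc_mean[t > 5]) - gamma / k_off), 4 * 0.3)
})

test_that("clustering extends the ground-truth membrane dwell via rebinding", {
  mean_dwell <- function(cfm) {
    cfg <- scenario_config("egf-clustered", seed = 21, n_frames = 481L,
                           n_sites = 200L, clustered_fraction_max = cfm,
                           tau_cluster = 60)
    log <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
    dw <- dwell_times(log)
    mean(dw$dwell_s[!dw$censored])
  }
  expect_gt(mean_dwell(0.8), mean_dwell(0))
})

test_that("identical seed and config give bit-identical event logs", {
  cfg <- scenario_config("egf-clustered", seed = 13, n_frames = 161L,
                         n_sites = 100L)
  log1 <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  log2 <- simulate_sh2_binding(simulate_phosphosite_dynamics(cfg), cfg)
  expect_identical(log1$events, log2$events)
  expect_identical(log1$positions, log2$positions)
})
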