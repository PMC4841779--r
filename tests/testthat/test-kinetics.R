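test_that("gamma_on windowing counts recruitment events correctly", {
  # no events -> zero everywhere
  g0 <- estimate_gamma_on(numeric(0), t_grid = c(0, 48, 96))
  expect_true(all(g0$gamma_on_per_min == 0))

  # 24 new molecules inside one 0.8-min window -> 30 events/min
  g <- estimate_gamma_on(seq(1, 47, length.out = 24), window_length = 48,
                         t_grid = 0)
  expect_equal(g$gamma_on_per_min, 30)

  # events at t = 0 (present in frame 0) are not recruitment events
  tracks <- data.frame(track_id = rep(1:3, each = 2),
                       frame = c(0, 1, 5, 6, 10, 11),
                       x_um = 0, y_um = 0)
  g2 <- estimate_gamma_on(tracks, window_length = 48, t_grid = 0,
                          frame_interval = 0.1)
  expect_identical(g2$n_events, 2L)

  # conservation: window counts sum to the total number of events
  set.seed(2)
  times <- runif(500, 0.1, 479)
  g3 <- estimate_gamma_on(times, window_length = 48,
                          t_grid = seq(0, 432, by = 48))
  expect_identical(sum(g3$n_events), 500L)

  expect_error(estimate_gamma_on(1:10, t_grid = numeric(0)), "window grid")
})

test_that("windowed gamma_on of a constant-rate process is Poisson around the truth", {
  set.seed(8)
  rate <- 2.5                                   # events per second
  times <- cumsum(rexp(3000, rate))
  g <- estimate_gamma_on(times, window_length = 48,
                         t_grid = seq(0, max(times) - 48, by = 48))
  expected <- rate * 60                         # events/min
  se <- sd(g$gamma_on_per_min) / sqrt(nrow(g))
  expect_lt(abs(mean(g$gamma_on_per_min) - expected), 4 * se)
})

test_that("lambda_off MLE matches the exponential sampling distribution", {
  set.seed(5)
  dw <- rexp(5000, 1)
  fit <- estimate_lambda_off(dw, k_bleach = 0)
  expect_lt(abs(fit$lambda_off - 1), 0.05)
  expect_lt(abs(fit$se - 1 / sqrt(5000)), 0.005)

  # bleach-rate correction under competing exponential risks
  set.seed(6)
  dw2 <- pmin(rexp(4000, 0.7), rexp(4000, 0.3))
  fit2 <- estimate_lambda_off(dw2, k_bleach = 0.3)
  expect_lt(abs(fit2$lambda_obs - 1.0), 4 * 1.0 / sqrt(4000))
  expect_lt(abs(fit2$lambda_off - 0.7), 4 * 1.0 / sqrt(4000))
  expect_false(fit2$degenerate)

  # time-unit invariance: rescaling dwells rescales lambda exactly
  fit_ms <- estimate_lambda_off(dw * 1000)
  expect_equal(fit_ms$lambda_obs * 1000, fit$lambda_obs, tolerance = 1e-12)

  # bootstrap CI covers the estimate
  set.seed(7)
  fit3 <- estimate_lambda_off(dw, n_boot = 200)
  expect_true(fit3$ci95[1] < fit3$lambda_off &&
                fit3$lambda_off < fit3$ci95[2])
})

test_that("censoring-dominated and degenerate off-rate fits are flagged", {
  dwell <- data.frame(dwell_s = rep(5, 40), censored = TRUE)
  fit <- estimate_lambda_off(dwell)
  expect_true(fit$censored_dominated)
  expect_true(is.na(fit$lambda_off))
  expect_equal(fit$lambda_obs, 0)   # lower bound only

  set.seed(9)
  fit2 <- estimate_lambda_off(rexp(100, 0.2), k_bleach = 0.5)
  expect_true(fit2$degenerate)
  expect_lt(fit2$lambda_off, 0)     # reported as-is, no silent clipping
})

test_that("recovery fitting is exact on its own model and flags bad input", {
  t <- seq(0, 20, length.out = 40)
  y <- 1 - exp(-t / 4.58)
  fit <- fit_recovery(t, y)
  expect_equal(fit$tau, 4.58, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$poor_fit)

  # pinned amplitude mode
  fitp <- fit_recovery(t, y, pin_amplitude = TRUE)
  expect_equal(fitp$tau, 4.58, tolerance = 1e-6)
  expect_equal(fitp$A, 1)

  # scale equivariance: y * c leaves tau unchanged
  fit_scaled <- fit_recovery(t, 37 * y)
  expect_equal(fit_scaled$tau, fit$tau, tolerance = 1e-6)

  # constant y: non-identifiable, poor-fit flag rather than an error
  flat <- fit_recovery(t, rep(0.7, 40))
  expect_true(flat$poor_fit)
  expect_false(flat$converged)

  expect_error(fit_recovery(t, c(y[-1], NA)), "non-finite")
  expect_error(fit_recovery(t[1:4], y[1:4]), "at least 5")
})

test_that("recovery fitting has <5% median error under measurement noise", {
  set.seed(42)
  taus <- replicate(200, {
    t <- seq(0, 3 * 4.58, length.out = 60)
    y <- 1 - exp(-t / 4.58) + rnorm(60, 0, 0.05)
    fit_recovery(t, y)$tau
  })
  expect_lt(abs(median(taus) - 4.58) / 4.58, 0.05)
})

test_that("timeseries R-squared equals the squared correlation", {
  a <- c(0.1, 0.4, 0.9, 1.0, 0.8)
  expect_equal(timeseries_r2(a, a), 1)
  expect_equal(timeseries_r2(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)  # orthogonal
  # series constructed with exact Pearson r = 0.954 -> R^2 = 0.91, the
  # association strength between GRB2 binding and EGFR pY1068 phosphorylation
  cs <- correlated_series(0.954, 13, seed = 3)
  expect_equal(timeseries_r2(cs$a, cs$b), 0.954^2, tolerance = 1e-10)
  expect_equal(round(timeseries_r2(cs$a, cs$b), 2), 0.91)

  expect_error(timeseries_r2(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(timeseries_r2(1:2, 1:2), "at least 3")
})
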