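#' Apparent on-rate (gamma_on) time course from recruitment events
#'
#' The apparent membrane on-rate in a time window is the number of newly
#' appearing membrane-bound molecules (trajectory starts, or ground-truth
#' binding events) divided by the window length; the canonical window is
#' 0.8 min (48 s). Molecules already present in frame 0 are not counted as
#' recruitment events, since pre-existing binding cannot be distinguished from
#' recruitment.
#'
#' @param x either a trajectory data frame with columns `track_id` and
#'   `frame` (then `frame_interval` is required) or a numeric vector of event
#'   start times in seconds (e.g. `events$bind_time_s` of a
#'   [simulate_sh2_binding()] log).
#' @param window_length window length (s); default 48 s = 0.8 min.
#' @param t_grid vector of window start times (s); defaults to contiguous
#'   windows from 0 covering all events. Must be non-empty.
#' @param frame_interval frame interval (s), required when `x` is a
#'   trajectory table.
#' @return data frame of class `rate_timecourse`: `window_start_s`,
#'   `window_mid_s`, `n_events`, `gamma_on_per_min`, `se_per_min` (Poisson
#'   sampling error `sqrt(n)/window`).
#' @export
estimate_gamma_on <- function(x, window_length = 48, t_grid = NULL,
                              frame_interval = NULL) {
  assert_positive(window_length, "window_length")
  if (is.data.frame(x)) {
    if (is.null(frame_interval))
      stop2("frame_interval is required with trajectory input")
    starts <- vapply(split(x$frame, x$track_id), min, numeric(1))
    starts <- starts[starts > 0]          # frame-0 molecules are not events
    times <- starts * frame_interval
  } else {
    times <- as.numeric(x)
    times <- times[times > 0]
  }
  if (is.null(t_grid)) {
    t_max <- if (length(times)) max(times) else window_length
    t_grid <- seq(0, t_max, by = window_length)
  }
  if (!length(t_grid)) stop2("empty window grid")
  n <- vapply(t_grid, function(t0) {
    sum(times > t0 & times <= t0 + window_length)
  }, numeric(1))
  per_min <- window_length / 60
  out <- data.frame(window_start_s = t_grid,
                    window_mid_s = t_grid + window_length / 2,
                    n_events = as.integer(n),
                    gamma_on_per_min = n / per_min,
                    se_per_min = sqrt(n) / per_min)
  class(out) <- c("rate_timecourse", "data.frame")
  out
}

#' Apparent off-rate (lambda_off) from dwell times
#'
#' Maximum-likelihood fit of a single-exponential to observed membrane dwell
#' times with right censoring: `lambda_obs = n_uncensored / sum(dwells)`. The
#' apparent off-rate is `lambda_obs - k_bleach`, since bleaching and
#' dissociation are competing exponential risks and the observed disappearance
#' rate is their sum. The standard error is the observed-information value
#' `lambda_obs / sqrt(n_uncensored)`; a nonparametric bootstrap over dwells is
#' available for error bars.
#'
#' @param x one of: a numeric vector of dwell times (s); a data frame with
#'   `dwell_s` and `censored` (e.g. from [dwell_times()]); or a trajectory
#'   data frame with `track_id` and `frame` (then `frame_interval` is
#'   required; dwell = track length in frames times `frame_interval`, tracks
#'   reaching the last frame are censored).
#' @param censored optional logical vector when `x` is a numeric vector.
#' @param k_bleach photobleaching rate to subtract (1/s), from the simulation
#'   config or an immobilized-control measurement.
#' @param frame_interval frame interval (s) for trajectory input.
#' @param last_frame last frame index of the movie (for censoring of
#'   trajectory input); defaults to `max(frame)`.
#' @param min_track_frames trajectory input only: tracks shorter than this
#'   many frames are discarded (isolated spurious detections and blinking
#'   fragments). By the memoryless property of the exponential, the fit then
#'   uses the dwell exceedance over the detection minimum,
#'   `(length - min_track_frames + 0.5) * frame_interval`; the half frame
#'   compensates the discrete sampling of a continuous dwell.
#' @param n_boot number of bootstrap resamples for a percentile 95% CI
#'   (0 = skip).
#' @param min_trajectories minimum number of dwells required.
#' @return list of class `lambda_off_fit`: `lambda_obs`, `lambda_off`, `se`,
#'   `n`, `n_uncensored`, `censored_dominated` (no uncensored dwell: only the
#'   lower bound `lambda_obs` is meaningful), `degenerate`
#'   (`lambda_obs <= k_bleach`: flagged, not clipped), and optional `ci95`.
#' @export
estimate_lambda_off <- function(x, censored = NULL, k_bleach = 0,
                                frame_interval = NULL, last_frame = NULL,
                                n_boot = 0, min_trajectories = 30,
                                min_track_frames = 2L) {
  assert_nonneg(k_bleach, "k_bleach")
  if (is.data.frame(x) && all(c("track_id", "frame") %in% names(x))) {
    if (is.null(frame_interval))
      stop2("frame_interval is required with trajectory input")
    len <- vapply(split(x$frame, x$track_id), length, integer(1))
    endf <- vapply(split(x$frame, x$track_id), max, numeric(1))
    lf <- last_frame %||% max(x$frame)
    keep <- len >= min_track_frames
    len <- len[keep]; endf <- endf[keep]
    dwell <- (len - min_track_frames + 0.5) * frame_interval
    cens <- endf >= lf
  } else if (is.data.frame(x)) {
    dwell <- x$dwell_s; cens <- x$censored
  } else {
    dwell <- as.numeric(x)
    cens <- censored %||% rep(FALSE, length(dwell))
  }
  if (length(dwell) < min_trajectories)
    stop2("need at least ", min_trajectories, " dwell times (got ",
          length(dwell), ")")
  # a censored dwell of zero length (bound at the very last instant) carries
  # no information but is not an error
  if (any(dwell < 0) || any(dwell[!cens] <= 0))
    stop2("dwell times must be positive")

  mle <- function(d, c) sum(!c) / sum(d)
  lambda_obs <- mle(dwell, cens)
  n_unc <- sum(!cens)
  censored_dominated <- n_unc == 0
  se <- if (censored_dominated) NA_real_ else lambda_obs / sqrt(n_unc)
  out <- list(lambda_obs = lambda_obs,
              lambda_off = lambda_obs - k_bleach,
              se = se, n = length(dwell), n_uncensored = n_unc,
              k_bleach = k_bleach,
              censored_dominated = censored_dominated,
              degenerate = !censored_dominated && lambda_obs <= k_bleach)
  if (censored_dominated) out$lambda_off <- NA_real_
  if (n_boot > 0 && !censored_dominated) {
    bs <- replicate(n_boot, {
      i <- sample.int(length(dwell), replace = TRUE)
      mle(dwell[i], cens[i]) - k_bleach
    })
    out$ci95 <- unname(quantile(bs, c(0.025, 0.975)))
  }
  class(out) <- "lambda_off_fit"
  out
}

#' @export
print.lambda_off_fit <- function(x, ...) {
  cat("<lambda_off_fit> lambda_off =", signif(x$lambda_off, 4), "1/s (se",
      signif(x$se, 3), "), n =", x$n,
      if (x$censored_dominated) "[censoring-dominated: lower bound only]" else "",
      if (isTRUE(x$degenerate)) "[degenerate: lambda_obs <= k_bleach]" else "",
      "\n")
  invisible(x)
}
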