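#' Mean square displacement and diffusion coefficient
#'
#' Time-and-ensemble averaged MSD over all trajectories longer than four
#' frames (default), and the diffusion coefficient from an unweighted linear
#' fit `MSD = 4*D*lag + c` over the first `fit_lags` lag times. The intercept
#' absorbs the static localization-error offset; `MSD(0) = 0` by construction
#' and is not part of the fit. Per-trajectory diffusion coefficients (same
#' fit applied per track) are returned for distribution analyses.
#'
#' @param tracks trajectory data frame (`track_id`, `frame`, `x_um`, `y_um`),
#'   frames consecutive within each track.
#' @param frame_interval frame interval (s).
#' @param max_lag maximum lag (frames) tabulated.
#' @param min_length minimum track length in frames; the default 5 keeps
#'   trajectories strictly longer than 4 frames.
#' @param fit_lags number of initial lags used in the linear fit.
#' @return object of class `msd_result`: list with `msd` (data frame
#'   `lag_s`, `msd_um2`, `n_pairs`), `D_um2_s`, `intercept_um2`,
#'   `residual_norm`, `per_track`, `n_trajectories`. When no trajectory
#'   qualifies, `n_trajectories` is 0 and `D_um2_s` is `NA` (explicit empty
#'   result).
#' @export
compute_msd <- function(tracks, frame_interval, max_lag = 10L,
                        min_length = 5L, fit_lags = 4L) {
  assert_positive(frame_interval, "frame_interval")
  tr <- split(tracks[, c("x_um", "y_um")], tracks$track_id)
  tr <- tr[vapply(tr, nrow, integer(1)) >= min_length]
  if (!length(tr)) {
    warning("no trajectory of length >= ", min_length, " frames",
            call. = FALSE)
    return(structure(list(msd = data.frame(lag_s = numeric(0),
                                           msd_um2 = numeric(0),
                                           n_pairs = integer(0)),
                          D_um2_s = NA_real_, intercept_um2 = NA_real_,
                          residual_norm = NA_real_,
                          per_track = data.frame(track_id = integer(0),
                                                 D_um2_s = numeric(0)),
                          n_trajectories = 0L),
                     class = "msd_result"))
  }
  max_lag <- min(max_lag, max(vapply(tr, nrow, integer(1))) - 1L)
  ssum <- numeric(max_lag); cnt <- integer(max_lag)
  per_track <- data.frame(track_id = as.integer(names(tr)),
                          D_um2_s = NA_real_)
  for (i in seq_along(tr)) {
    x <- tr[[i]]$x_um; y <- tr[[i]]$y_um
    len <- length(x)
    lag_max_i <- min(max_lag, len - 1L)
    msd_i <- numeric(lag_max_i)
    for (l in seq_len(lag_max_i)) {
      d2 <- (x[(1 + l):len] - x[1:(len - l)])^2 +
            (y[(1 + l):len] - y[1:(len - l)])^2
      ssum[l] <- ssum[l] + sum(d2)
      cnt[l] <- cnt[l] + length(d2)
      msd_i[l] <- mean(d2)
    }
    nl <- min(fit_lags, lag_max_i)
    if (nl >= 2) {
      ft <- lm(msd_i[1:nl] ~ I(seq_len(nl) * frame_interval))
      per_track$D_um2_s[i] <- unname(coef(ft)[2]) / 4
    }
  }
  msd <- data.frame(lag_s = seq_len(max_lag) * frame_interval,
                    msd_um2 = ssum / pmax(cnt, 1L), n_pairs = cnt)
  nl <- min(fit_lags, nrow(msd))
  fit <- lm(msd_um2 ~ lag_s, data = msd[seq_len(nl), ])
  structure(list(msd = msd,
                 D_um2_s = unname(coef(fit)[2]) / 4,
                 intercept_um2 = unname(coef(fit)[1]),
                 residual_norm = sqrt(sum(fit$residuals^2)),
                 per_track = per_track,
                 n_trajectories = length(tr)),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat("<msd_result>", x$n_trajectories, "trajectories; D =",
      signif(x$D_um2_s, 4), "um^2/s\n")
  invisible(x)
}
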