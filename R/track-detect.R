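#' Detect single-molecule spots in one frame
#'
#' Matched-filter detection followed by sub-pixel Gaussian fitting: the frame
#' is convolved with a Gaussian kernel of width `psf_sigma`, local maxima
#' exceeding `threshold_snr` times the robust background noise (MAD of the
#' filtered image) are retained, and each candidate is refined by
#' least-squares fitting of a 2D Gaussian (amplitude, background and sub-pixel
#' center free; width fixed at the PSF) in a window of +/- 3 sigma.
#' Duplicate detections within one PSF width are merged keeping the brighter.
#'
#' The reported `snr` is the fitted peak amplitude divided by the robust
#' (MAD-based) standard deviation of the raw frame background; `intensity` is
#' the integrated photon count `A * 2 * pi * sigma_px^2`.
#'
#' @param frame numeric matrix (row = y, col = x), photon counts.
#' @param pixel_size pixel size (um/px).
#' @param psf_sigma PSF standard deviation (um); must be at least half a
#'   pixel.
#' @param threshold_snr detection threshold in units of background noise.
#' @return data frame of localizations: `x_um`, `y_um`, `intensity`, `snr`.
#' @export
detect_spots <- function(frame, pixel_size, psf_sigma, threshold_snr = 5) {
  if (psf_sigma < pixel_size / 2)
    stop2("psf_sigma must be at least half a pixel")
  frame <- as.matrix(frame)
  sig <- psf_sigma / pixel_size
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), snr = numeric(0))

  sm <- as.matrix(EBImage::gblur(frame, sigma = sig))
  bg <- median(sm)
  noise <- mad(sm)
  # noiseless synthetic frames have MAD 0; fall back to the global sd so an
  # ideal spot on a flat background is still detectable
  if (noise <= 0) noise <- sd(sm)
  if (!is.finite(noise) || noise <= 0) return(empty)
  thr <- bg + threshold_snr * noise

  cand <- local_maxima(sm, thr)
  if (!nrow(cand)) return(empty)

  noise_raw <- mad(frame)
  if (noise_raw <= 0) noise_raw <- noise
  w <- max(2L, ceiling(3 * sig))
  fits <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    fits[[k]] <- fit_gaussian_2d(frame, cand$row[k], cand$col[k], sig, w)
  }
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || !nrow(fits)) return(empty)

  out <- data.frame(
    x_um = (fits[, "x0"] - 0.5) * pixel_size,
    y_um = (fits[, "y0"] - 0.5) * pixel_size,
    intensity = fits[, "A"] * 2 * pi * sig^2,
    snr = fits[, "A"] / noise_raw
  )
  out <- out[out$intensity > 0 & out$snr >= threshold_snr, , drop = FALSE]
  merge_duplicates(out, psf_sigma)
}

# 8-neighborhood local maxima above a threshold; the image is padded with
# -Inf so molecules on the border rim remain detectable
local_maxima <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  is_max <- m > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    is_max <- is_max & (m >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2])
}

# Gauss-Newton least-squares fit of b + A*exp(-((x-x0)^2+(y-y0)^2)/(2*sig^2))
# on a (2w+1)^2 window; sig fixed, coordinates in pixel-center units
# (pixel [r, c] center is at (c, r)).
fit_gaussian_2d <- function(frame, row0, col0, sig, w, n_iter = 12) {
  nr <- nrow(frame); nc <- ncol(frame)
  rows <- max(1L, row0 - w):min(nr, row0 + w)
  cols <- max(1L, col0 - w):min(nc, col0 + w)
  z <- as.vector(frame[rows, cols])
  X <- rep(cols, each = length(rows))
  Y <- rep(rows, times = length(cols))
  b <- min(z); A <- frame[row0, col0] - b
  if (A <= 0) return(NULL)
  x0 <- col0; y0 <- row0
  for (it in seq_len(n_iter)) {
    g <- exp(-((X - x0)^2 + (Y - y0)^2) / (2 * sig^2))
    r <- z - (b + A * g)
    J <- cbind(g, 1, A * g * (X - x0) / sig^2, A * g * (Y - y0) / sig^2)
    step <- tryCatch(qr.solve(crossprod(J) + diag(1e-9, 4), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    A <- A + step[1]; b <- b + step[2]
    x0 <- x0 + step[3]; y0 <- y0 + step[4]
    if (abs(x0 - col0) > w + 1 || abs(y0 - row0) > w + 1) return(NULL)
    if (max(abs(step[3:4])) < 1e-4) break
  }
  if (!is.finite(A) || !is.finite(x0) || !is.finite(y0) || A <= 0) return(NULL)
  cbind(A = A, b = b, x0 = x0, y0 = y0)
}

# keep the brighter of any pair closer than one PSF width
merge_duplicates <- function(loc, radius) {
  if (nrow(loc) < 2) return(loc)
  ord <- order(-loc$intensity)
  keep <- logical(nrow(loc))
  for (i in ord) {
    acc <- which(keep)
    if (!length(acc) ||
        all((loc$x_um[acc] - loc$x_um[i])^2 +
            (loc$y_um[acc] - loc$y_um[i])^2 > radius^2)) keep[i] <- TRUE
  }
  out <- loc[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a movie
#'
#' @param movie a `movie_stack`.
#' @param psf_sigma PSF standard deviation (um).
#' @param threshold_snr detection threshold (see [detect_spots()]).
#' @return data frame of localizations with a `frame` column (0-based).
#' @export
detect_movie <- function(movie, psf_sigma, threshold_snr = 5) {
  stopifnot(inherits(movie, "movie_stack"))
  out <- vector("list", length(movie$frames))
  for (f in seq_along(movie$frames)) {
    loc <- detect_spots(movie$frames[[f]], movie$pixel_size, psf_sigma,
                        threshold_snr)
    if (nrow(loc)) out[[f]] <- cbind(frame = f - 1L, loc)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  rownames(out) <- NULL
  out
}
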