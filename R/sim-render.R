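#' Render a synthetic sptPALM movie from a binding event log
#'
#' Emulates EMCCD acquisition of sparsely photoactivated molecules. Only a
#' seeded random subset of molecules is photoactivated, chosen so the
#' instantaneous visible density stays at or below
#' `config$activation_density`; the activation decision is made once, when a
#' molecule first appears, and bleached or unbound molecules free capacity for
#' newly appearing ones. Each visible molecule is rendered by integrating a
#' symmetric 2D Gaussian PSF (`psf_sigma`) over the pixel grid, scaled to
#' `photons_per_molecule`; `background_photons` is added per pixel, then
#' per-pixel Poisson shot noise and Gaussian read noise are applied.
#'
#' Pixel (0,0) covers the area `[0, pixel_size)^2`; images are stored as
#' matrices indexed `[row = y, col = x]`.
#'
#' @param log a `binding_event_log`.
#' @param config the [simulation_config()] used for the simulation.
#' @param noise apply Poisson + read noise (`TRUE`, default). With `FALSE`
#'   the expected photon image is returned (useful for testing).
#' @return object of class `movie_stack`: list with `frames` (list of numeric
#'   matrices, photon counts), `pixel_size`, `frame_interval`, and `truth`
#'   (per-frame table of the rendered molecules' ground-truth positions).
#' @export
render_movie <- function(log, config, noise = TRUE) {
  stopifnot(inherits(log, "binding_event_log"))
  config <- validate_config(config)
  npx <- round(config$field_size / config$pixel_size)
  if (npx < ceiling(6 * config$psf_sigma / config$pixel_size))
    stop2("pixel grid smaller than the PSF support")

  cap <- max(1L, floor(config$activation_density * config$field_size^2))
  pos <- log$positions[log$positions$observable, , drop = FALSE]
  pos_by_frame <- split(pos, factor(pos$frame, levels = 0:(config$n_frames - 1L)))
  max_id <- if (nrow(log$events)) max(log$events$molecule_id) else 0L

  activated <- rep(NA, max_id)  # NA = not yet decided
  with_substream(config$seed, "activation", {
    for (f in seq_along(pos_by_frame)) {
      pf <- pos_by_frame[[f]]
      if (!nrow(pf)) next
      ids <- pf$molecule_id
      known <- !is.na(activated[ids])
      vis_now <- sum(activated[ids[known]])
      new_ids <- ids[!known]
      if (length(new_ids)) {
        room <- max(0L, cap - vis_now)
        pick <- if (length(new_ids) <= room) seq_along(new_ids)
                else sample.int(length(new_ids), room)
        on <- logical(length(new_ids)); on[pick] <- TRUE
        activated[new_ids] <- on
      }
    }
  })
  activated[is.na(activated)] <- FALSE

  frames <- vector("list", config$n_frames)
  truth <- vector("list", config$n_frames)
  sig <- config$psf_sigma
  ps <- config$pixel_size
  edges <- (0:npx) * ps

  with_substream(config$seed, "noise", {
    for (f in 0:(config$n_frames - 1L)) {
      img <- matrix(config$background_photons, nrow = npx, ncol = npx)
      pf <- pos_by_frame[[f + 1L]]
      if (nrow(pf)) pf <- pf[activated[pf$molecule_id], , drop = FALSE]
      if (nrow(pf)) {
        for (k in seq_len(nrow(pf))) {
          img <- img + psf_pixel_integral(pf$x_um[k], pf$y_um[k], sig, edges,
                                          config$photons_per_molecule)
        }
        truth[[f + 1L]] <- data.frame(frame = f,
                                      molecule_id = pf$molecule_id,
                                      x_um = pf$x_um, y_um = pf$y_um)
      }
      if (noise) {
        img <- rpois(length(img), lambda = img) +
          rnorm(length(img), 0, config$read_noise_sd)
        img <- matrix(pmax(round(img), 0), nrow = npx, ncol = npx)
      }
      frames[[f + 1L]] <- img
    }
  })

  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), molecule_id = integer(0),
                        x_um = numeric(0), y_um = numeric(0))
  structure(list(frames = frames, pixel_size = ps,
                 frame_interval = config$frame_interval,
                 field_size = config$field_size, truth = truth),
            class = "movie_stack")
}

# Photon count per pixel for a Gaussian PSF at (x, y), integrated exactly over
# pixel areas via the error function; restricted to a +/- 4 sigma window.
psf_pixel_integral <- function(x, y, sigma, edges, photons) {
  npx <- length(edges) - 1L
  img <- matrix(0, npx, npx)
  ix <- range(pmin(pmax(findInterval(c(x - 4 * sigma, x + 4 * sigma), edges), 1L), npx))
  iy <- range(pmin(pmax(findInterval(c(y - 4 * sigma, y + 4 * sigma), edges), 1L), npx))
  cx <- ix[1]:ix[2]; cy <- iy[1]:iy[2]
  fx <- pnorm(edges[cx + 1L], x, sigma) - pnorm(edges[cx], x, sigma)
  fy <- pnorm(edges[cy + 1L], y, sigma) - pnorm(edges[cy], y, sigma)
  img[cy, cx] <- photons * outer(fy, fx)
  img
}

#' Write / read a movie as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Photon counts are stored as 16-bit grayscale (clipped at 65535); pixel
#' size, frame interval and field size are written to `<path>.json`.
#'
#' @param movie a `movie_stack`.
#' @param path TIFF file path.
#' @return `write_movie_tiff` returns `path`; `read_movie_tiff` returns a
#'   `movie_stack` (without ground truth).
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  pages <- lapply(movie$frames, function(m) pmin(m, 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(pixel_size_um = movie$pixel_size,
                  frame_interval_s = movie$frame_interval,
                  field_size_um = movie$field_size,
                  n_frames = length(movie$frames))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(m) round(m * 65535))
  structure(list(frames = frames, pixel_size = meta$pixel_size_um,
                 frame_interval = meta$frame_interval_s,
                 field_size = meta$field_size_um,
                 truth = NULL),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat("<movie_stack>", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "x", ncol(x$frames[[1]]), "px @",
      x$pixel_size, "um/px,", x$frame_interval, "s/frame\n")
  invisible(x)
}
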