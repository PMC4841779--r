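#' Normalize far-Western band intensities to the per-replicate maximum
#'
#' Each probe replicate is divided by its own maximum band intensity across
#' all protein bands and time points (so each replicate's maximum is exactly
#' 1), then replicates are averaged per probe. The operation is idempotent
#' and invariant to rescaling any replicate row.
#'
#' @param x either a numeric matrix (rows = probes, columns = band/time
#'   pairs; treated as a single replicate each) or a long data frame with
#'   columns `probe`, `replicate`, `protein`, `time_min`, `intensity`.
#' @return normalized matrix with probes as rows; for data-frame input the
#'   columns are labeled `protein@time_min` and replicates are averaged after
#'   normalization. An all-zero probe replicate is an error naming the probe.
#' @export
normalize_to_probe_max <- function(x) {
  if (is.matrix(x)) {
    if (any(x < 0)) stop2("intensities must be non-negative")
    mx <- apply(x, 1, max)
    zero <- mx <= 0
    if (any(zero))
      stop2("all-zero intensity row for probe(s): ",
            paste(rownames(x)[zero] %||% which(zero), collapse = ", "))
    return(x / mx)
  }
  stopifnot(is.data.frame(x),
            all(c("probe", "replicate", "protein", "time_min", "intensity")
                %in% names(x)))
  if (any(x$intensity < 0)) stop2("intensities must be non-negative")
  key <- interaction(x$probe, x$replicate, drop = TRUE)
  mx <- tapply(x$intensity, key, max)
  zero <- names(mx)[mx <= 0]
  if (length(zero))
    stop2("all-zero intensity for probe replicate(s): ",
          paste(zero, collapse = ", "))
  x$norm <- x$intensity / as.numeric(mx[as.character(key)])

  band <- paste0(x$protein, "@", x$time_min)
  band_levels <- unique(band[order(x$protein, x$time_min)])
  probes <- unique(as.character(x$probe))
  out <- matrix(NA_real_, length(probes), length(band_levels),
                dimnames = list(probes, band_levels))
  agg <- tapply(x$norm, list(as.character(x$probe), band), mean)
  out[rownames(agg), colnames(agg)] <- agg
  out[, band_levels, drop = FALSE]
}

#' Per-lane fractions of band intensities
#'
#' Expresses raw band intensities as fractions of the total signal in each
#' lane (column), the representation required by [relative_specificity()].
#'
#' @param mat numeric matrix, rows = bands, columns = lanes (time points).
#' @return matrix of the same shape with each column summing to 1.
#' @export
lane_fractions <- function(mat) {
  mat <- as.matrix(mat)
  tot <- colSums(mat)
  if (any(tot <= 0)) stop2("lane with non-positive total intensity")
  sweep(mat, 2, tot, "/")
}

#' Relative SH2 binding specificity per band
#'
#' The relative specificity of an SH2 probe for a band at a time point is the
#' band's fraction of the SH2 far-Western lane total minus the same band's
#' fraction of the anti-phosphotyrosine lane total. Positive values mark
#' binding above the motif-independent (total phosphorylation) expectation.
#' Within each lane the values sum to zero by construction.
#'
#' @param sh2_frac matrix of per-lane fractions for the SH2 probe (bands x
#'   lanes, each lane summing to 1 within 1e-6).
#' @param py_frac matching matrix of anti-pY fractions.
#' @return matrix of specificity values (same shape).
#' @export
relative_specificity <- function(sh2_frac, py_frac) {
  sh2_frac <- as.matrix(sh2_frac); py_frac <- as.matrix(py_frac)
  if (!all(dim(sh2_frac) == dim(py_frac)))
    stop2("fraction matrices must have identical shape")
  check <- function(m, nm) {
    if (any(abs(colSums(m) - 1) > 1e-6))
      stop2(nm, " lane totals must each sum to 1 (within 1e-6)")
  }
  check(sh2_frac, "sh2_frac"); check(py_frac, "py_frac")
  sh2_frac - py_frac
}
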