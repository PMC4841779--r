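#' Reference SH2 recruitment and binding-site kinetics
#'
#' Published compendium of per-SH2-domain kinetics in EGF-stimulated A431
#' cells: the in vivo membrane-recruitment time constant (exponential recovery
#' fit to TIRF fluorescence, minutes, with SEM and number of biological
#' replicates), the membrane diffusion coefficient from single-molecule
#' tracking (um^2/s, >3000 trajectories per cell, 40 min post-EGF), and the
#' binding-site creation time constant from far-Western total-binding time
#' courses (minutes). A negative far-Western time constant marks a signal that
#' decayed rather than recovered; its magnitude is the fitted time constant.
#' `fw_poor_fit` flags far-Western fits with R-squared < 0.5.
#' `invivo_class` distinguishes recovery-type traces ("recovery") from
#' domains whose membrane signal stayed constant, decreased, or was not
#' determined.
#'
#' @return data frame with columns `sh2_domain`, `tau_invivo_min`,
#'   `tau_invivo_sem`, `n_replicates`, `d_um2_s`, `tau_fw_min`,
#'   `tau_fw_sem`, `fw_poor_fit`, `invivo_class`.
#' @export
sh2_reference_kinetics <- function() {
  df <- data.frame(
    sh2_domain = c("SHIP2", "SHP2-N", "GRB14", "SHP2-NC", "SHP2-C", "EAT2",
                   "PLCg1-NC", "p85a-NC", "SHC PTB", "GRB7", "VAV2",
                   "SHC SH2", "GRB2", "PLCg1-N", "CRK", "RASGAP-NC",
                   "PLCg1-C", "ARG", "p85a-N", "RASGAP-N", "FYN", "NCK1",
                   "RASGAP-C", "ABL", "YES"),
    tau_invivo_min = c(0.55, 0.91, 0.99, 1.57, 1.85, 2.26, 2.44, 3.06, 3.25,
                       3.45, 4.27, 4.57, 4.58, 5.15, 5.54, 5.92, 6.48, 6.55,
                       6.88, 6.99, NA, NA, NA, NA, NA),
    tau_invivo_sem = c(0.15, 0.02, 0.47, 0.18, 0.49, 1.10, 0.18, 0.32, 0.08,
                       0.67, 0.52, 0.20, 0.41, 2.28, 0.64, 0.80, 1.27, 0.90,
                       0.78, 2.53, NA, NA, NA, NA, NA),
    n_replicates = c(3, 2, 2, 5, 8, 2, 2, 2, 4, 3, 2, 4, 11, 2, 2, 2, 5, 2,
                     2, 2, 2, 2, 2, 3, NA),
    d_um2_s = c(0.040, 0.187, NA, 0.081, 0.759, 0.097, 0.022, 0.004, 0.007,
                0.009, 0.034, 0.026, 0.021, 0.022, 0.016, 0.076, 0.043,
                0.010, 0.016, 0.011, 0.008, 0.009, NA, NA, NA),
    tau_fw_min = c(1.13, 0.60, -1.50, 1.57, NA, 0.64, 0.62, 0.51, 0.69,
                   0.77, 0.80, NA, 0.59, 0.75, -2.80, -1.27, 0.30, 0.54,
                   0.67, -2.51, 0.43, -0.83, 1.27, 0.70, -3.62),
    tau_fw_sem = c(0.81, 0.01, 0.08, 0.18, NA, 0.51, 0.19, 0.09, 0.08, 0.05,
                   0.17, NA, 0.03, 0.33, 0.29, 0.54, 0.03, 0.20, 0.10, 0.98,
                   0.04, 0.03, 0.54, 0.40, 1.48),
    fw_poor_fit = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                    TRUE),
    invivo_class = c(rep("recovery", 20), "constant", "decrease", "constant",
                     "constant", "nd")
  )
  df
}

#' Mean lag of in vivo recruitment behind binding-site creation
#'
#' For every SH2 domain with a numeric in vivo recruitment time constant and
#' a numeric far-Western site-creation time constant whose fit is not flagged
#' poor, forms the ratio `tau_invivo / |tau_fw|` and returns the mean. The
#' magnitude of the far-Western constant is used because its sign only
#' encodes the direction of the intensity change. The published comparison
#' states that recruitment time constants are about six times the
#' site-creation constants.
#'
#' @param table a reference table in the format of
#'   [sh2_reference_kinetics()] (the default).
#' @return list with `ratio` (the mean), `n` (rows used), and `per_domain`
#'   (data frame of the individual ratios).
#' @export
recruitment_lag_ratio <- function(table = sh2_reference_kinetics()) {
  ok <- is.finite(table$tau_invivo_min) & is.finite(table$tau_fw_min) &
    !table$fw_poor_fit
  ratios <- table$tau_invivo_min[ok] / abs(table$tau_fw_min[ok])
  list(ratio = mean(ratios), n = sum(ok),
       per_domain = data.frame(sh2_domain = table$sh2_domain[ok],
                               ratio = ratios))
}
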