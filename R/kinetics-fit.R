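#' Fit the first-order exponential recovery function
#'
#' Nonlinear least squares of `y = A * (1 - exp(-t / tau))`, the recovery
#' model used for membrane-recruitment and phosphorylation time courses. The
#' amplitude A is free by default or can be pinned to 1 for max-normalized
#' data. tau is initialized at the time to half-maximum divided by ln 2 and
#' bounded in (0, 10 * max(t)]; fitting uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Fits with R-squared below 0.5 carry a poor-fit
#' flag. tau is scale-equivariant in t and invariant to rescaling of y.
#'
#' @param t time vector (any unit; tau is returned in the same unit).
#' @param y response vector (baseline-subtracted).
#' @param pin_amplitude fix A = 1 instead of fitting it.
#' @return object of class `recovery_fit`: `tau`, `tau_se`, `A`,
#'   `r_squared`, `poor_fit`, `converged`, `model = "1-exp-recovery"`.
#'   Non-identifiable input (constant y) returns a non-converged, poor-fit
#'   result rather than an error; non-finite values are an error.
#' @export
fit_recovery <- function(t, y, pin_amplitude = FALSE) {
  if (length(t) != length(y)) stop2("t and y must have equal length")
  if (length(t) < 5) stop2("need at least 5 points")
  if (any(!is.finite(t)) || any(!is.finite(y))) stop2("non-finite values")
  if (any(t < 0)) stop2("t must be non-negative")

  failed <- structure(list(tau = NA_real_, tau_se = NA_real_, A = NA_real_,
                           r_squared = NA_real_, poor_fit = TRUE,
                           converged = FALSE, model = "1-exp-recovery"),
                      class = "recovery_fit")
  if (sd(y) == 0) return(failed)

  y_max <- max(y)
  half <- y_max / 2
  i <- which(y >= half)[1]
  t_half <- if (is.na(i) || i == 1) max(t[2], min(t[t > 0])) else t[i]
  tau0 <- max(t_half / log(2), min(t[t > 0]) / 10)
  t_max <- max(t)

  fit <- tryCatch({
    if (pin_amplitude) {
      minpack.lm::nlsLM(y ~ 1 - exp(-t / tau),
                        start = list(tau = tau0),
                        lower = 1e-12, upper = 10 * t_max,
                        control = nls.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)),
                        start = list(A = y_max, tau = tau0),
                        lower = c(-Inf, 1e-12), upper = c(Inf, 10 * t_max),
                        control = nls.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed)

  cf <- coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  tau_se <- if (!is.null(sm)) unname(sm$coefficients["tau", "Std. Error"])
            else NA_real_
  resid <- y - stats::fitted(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(tau = unname(cf["tau"]), tau_se = tau_se,
                 A = if (pin_amplitude) 1 else unname(cf["A"]),
                 r_squared = r2, poor_fit = r2 < 0.5,
                 converged = TRUE, model = "1-exp-recovery"),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("<recovery_fit> tau =", signif(x$tau, 4), "( se", signif(x$tau_se, 3),
      ") R^2 =", signif(x$r_squared, 4),
      if (x$poor_fit) "[poor fit]" else "", "\n")
  invisible(x)
}

#' Coefficient of determination between two matched time series
#'
#' R-squared of the ordinary least-squares line of `b` on `a`, as used to
#' compare normalized phosphotyrosine Western intensity with normalized SH2
#' far-Western binding intensity; equals the squared Pearson correlation.
#'
#' @param a predictor series (normalized), non-zero variance.
#' @param b response series (normalized), same length as `a`, >= 3 points.
#' @return R-squared (unitless, in \[0, 1\]).
#' @export
timeseries_r2 <- function(a, b) {
  if (length(a) != length(b)) stop2("series must have equal length")
  if (length(a) < 3) stop2("need at least 3 matched points")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop2("non-finite values")
  if (var(a) == 0) stop2("zero variance in the predictor series")
  unname(cor(a, b)^2)
}
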