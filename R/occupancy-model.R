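#' Membrane occupancy kinetics
#'
#' The number of membrane-bound SH2 molecules obeys the linear balance
#' `d[mem:SH2]/dt = gamma_on(t) - lambda_off(t) * [mem:SH2](t)`, where
#' gamma_on is the apparent recruitment rate (events per unit time) and
#' lambda_off the apparent dissociation rate. [integrate_occupancy()] solves
#' it numerically (adaptive lsoda); [analytic_occupancy()] evaluates the
#' integrating-factor solution
#' `mem(t) = c * exp(-L(t)) + exp(-L(t)) * integral(gamma(s) exp(L(s)) ds)`
#' with `L(t) = integral of lambda`, using high-order quadrature with the
#' exponentials combined in log space so large cumulated rates cannot
#' overflow.
#'
#' Measured rate time courses are interpolated piecewise-linearly between
#' window midpoints; both solvers consume the identical piecewise-linear
#' representation, so they can be cross-validated against each other.
#' gamma_on given in events/min must be converted to events/s (divide by 60)
#' before integration when the grid is in seconds; [rates_from_timecourses()]
#' does this.
#'
#' @param gamma_on recruitment rate: a function of time, a single number
#'   (constant rate), or a 2-column data frame `(t, rate)` in events/s.
#' @param lambda_off dissociation rate, same forms, in 1/s; must be
#'   non-negative.
#' @param initial initial occupancy (molecules or a.u.).
#' @param t_grid output time grid (s).
#' @return data frame of class `occupancy_curve`: `t_s`, `mem_sh2`,
#'   `provenance` ("numeric" or "analytic").
#' @name occupancy
NULL

# canonical piecewise-linear rate representation on a refined knot grid
as_rate_knots <- function(rate, t_grid, refine = 10L) {
  t_grid <- sort(unique(t_grid))
  if (is.numeric(rate) && length(rate) == 1L) {
    knots <- range(t_grid)
    return(data.frame(t = knots, r = rep(rate, 2)))
  }
  if (is.data.frame(rate)) {
    stopifnot(ncol(rate) >= 2)
    out <- data.frame(t = rate[[1]], r = rate[[2]])
    return(out[order(out$t), ])
  }
  if (is.function(rate)) {
    tt <- refine_grid(t_grid, refine)
    return(data.frame(t = tt, r = rate(tt)))
  }
  stop2("rate must be a constant, a function, or a (t, rate) data frame")
}

refine_grid <- function(t_grid, refine) {
  tt <- unlist(lapply(seq_len(length(t_grid) - 1L), function(i) {
    seq(t_grid[i], t_grid[i + 1L], length.out = refine + 1L)[-(refine + 1L)]
  }))
  c(tt, t_grid[length(t_grid)])
}

rate_fun <- function(knots) {
  approxfun(knots$t, knots$r, rule = 2)
}

#' @rdname occupancy
#' @export
integrate_occupancy <- function(gamma_on, lambda_off, initial = 0, t_grid) {
  stopifnot(length(t_grid) >= 2)
  gk <- as_rate_knots(gamma_on, t_grid)
  lk <- as_rate_knots(lambda_off, t_grid)
  if (any(lk$r < 0)) stop2("lambda_off must be non-negative")
  g <- rate_fun(gk); l <- rate_fun(lk)
  deriv <- function(t, y, parms) list(g(t) - l(t) * y)
  sol <- deSolve::ode(y = c(mem = initial), times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  out <- data.frame(t_s = sol[, "time"], mem_sh2 = sol[, "mem"],
                    provenance = "numeric")
  class(out) <- c("occupancy_curve", "data.frame")
  out
}

#' @param c_init integration constant of the analytic solution; equals the
#'   occupancy at the first grid point.
#' @rdname occupancy
#' @export
analytic_occupancy <- function(gamma_on, lambda_off, c_init = 0, t_grid) {
  stopifnot(length(t_grid) >= 2)
  t_grid <- sort(unique(t_grid))
  gk <- as_rate_knots(gamma_on, t_grid)
  lk <- as_rate_knots(lambda_off, t_grid)
  if (any(lk$r < 0)) stop2("lambda_off must be non-negative")
  g <- rate_fun(gk); l <- rate_fun(lk)

  # fine evaluation knots: output grid, rate knots, subdivided so that the
  # Gauss-Legendre panels resolve the integrating-factor exponential
  # (lambda * h <= 0.5 per panel)
  knots <- sort(unique(c(refine_grid(t_grid, 4L), gk$t, lk$t)))
  knots <- knots[knots >= t_grid[1] & knots <= t_grid[length(t_grid)]]
  max_h <- min(0.5 / max(max(lk$r), 1e-12),
               diff(range(t_grid)) / 100)
  knots <- sort(unique(unlist(lapply(seq_len(length(knots) - 1L), function(i) {
    h <- knots[i + 1L] - knots[i]
    m <- max(1L, ceiling(h / max_h))
    seq(knots[i], knots[i + 1L], length.out = m + 1L)
  }))))

  # 7-point Gauss-Legendre nodes/weights on [-1, 1]
  gl_x <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
            0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
  gl_w <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
            0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
            0.1294849661688697)

  ns <- length(knots) - 1L
  # cumulative integral of lambda at knots (trapezoid is exact for
  # piecewise-linear lambda once knots include the rate knots)
  lam <- l(knots)
  Lk <- c(0, cumsum(diff(knots) * (head(lam, -1) + tail(lam, -1)) / 2))

  # per-segment log of integral gamma(s) * exp(L(s)) ds, via GL quadrature
  # evaluated relative to the segment start to stay in a safe range:
  # I_seg = exp(L(a)) * integral gamma(s) exp(L(s) - L(a)) ds
  seg_log <- rep(-Inf, ns)
  for (i in seq_len(ns)) {
    a <- knots[i]; b <- knots[i + 1L]
    if (b <= a) next
    h <- (b - a) / 2
    s <- a + h * (gl_x + 1)
    # L(s) - L(a) on the segment: lambda linear between knots
    slope <- (lam[i + 1L] - lam[i]) / (b - a)
    Ls <- lam[i] * (s - a) + slope * (s - a)^2 / 2
    vals <- g(s) * exp(Ls)
    integ <- h * sum(gl_w * vals)
    seg_log[i] <- if (integ > 0) log(integ) + Lk[i] else -Inf
  }
  # cumulative log-sum-exp of segment integrals -> log I(t) at knots
  cum_log <- rep(-Inf, ns + 1L)
  for (i in seq_len(ns)) {
    m <- max(cum_log[i], seg_log[i])
    cum_log[i + 1L] <- if (is.finite(m))
      m + log(exp(cum_log[i] - m) + exp(seg_log[i] - m)) else -Inf
  }

  pos <- match_closest(t_grid, knots)
  mem <- c_init * exp(-Lk[pos]) +
    ifelse(is.finite(cum_log[pos]), exp(cum_log[pos] - Lk[pos]), 0)
  out <- data.frame(t_s = t_grid, mem_sh2 = mem, provenance = "analytic")
  class(out) <- c("occupancy_curve", "data.frame")
  out
}

match_closest <- function(x, table) {
  vapply(x, function(v) which.min(abs(table - v)), integer(1))
}

#' Piecewise-linear rate functions from measured rate time courses
#'
#' Converts `rate_timecourse` tables (gamma_on in events/min at window
#' midpoints, lambda_off constant or per window) into the (t, rate-per-second)
#' data frames consumed by [integrate_occupancy()] and
#' [analytic_occupancy()].
#'
#' @param gamma_tc a `rate_timecourse` from [estimate_gamma_on()].
#' @param lambda either a single lambda_off (1/s) or a data frame
#'   `(t_s, lambda_per_s)`.
#' @return list with `gamma` and `lambda` knot data frames (rates in 1/s).
#' @export
rates_from_timecourses <- function(gamma_tc, lambda) {
  g <- data.frame(t = gamma_tc$window_mid_s,
                  r = gamma_tc$gamma_on_per_min / 60)
  l <- if (is.data.frame(lambda)) {
    data.frame(t = lambda[[1]], r = lambda[[2]])
  } else {
    data.frame(t = range(g$t), r = rep(lambda, 2))
  }
  list(gamma = g, lambda = l)
}

#' Diffusion-limited on-rate from the off-rate and dissociation constant
#'
#' `k_on = k_off / K_d`. With the measured diffusion-limited off-rate of
#' order 1/s and K_d of order 1 uM this gives an effective on-rate of order
#' 1e6 per molar per second.
#'
#' @param k_off off-rate (1/s), positive.
#' @param K_d dissociation constant (M), positive.
#' @return k_on in 1/(M s).
#' @export
on_rate_from_kd <- function(k_off, K_d) {
  assert_positive(k_off, "k_off")
  assert_positive(K_d, "K_d")
  k_off / K_d
}

#' Smoluchowski upper bound on the per-phosphosite on-rate
#'
#' The diffusion-limited association rate to a cluster of radius `s`
#' containing `N` binding sites is about `4 * pi * D * s`; shared among the
#' N sites this bounds the per-site on-rate by `4 * pi * D * s / N`
#' (um^3/s), converted to molar units via 1e-15 L/um^3 and the Avogadro
#' constant.
#'
#' @param D diffusion coefficient (um^2/s), non-negative.
#' @param s cluster size (radius, um), positive.
#' @param N number of phosphosites in the cluster, positive.
#' @return upper-bound k_on in 1/(M s).
#' @export
smoluchowski_upper_bound <- function(D, s, N) {
  assert_nonneg(D, "D")
  assert_positive(s, "s")
  assert_positive(N, "N")
  (4 * pi * D * s / N) * 1e-15 * 6.02214076e23
}
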