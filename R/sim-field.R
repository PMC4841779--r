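#' Simulate phosphosite creation and clustering
#'
#' Generates the ground-truth binding-site field. Each site phosphorylates
#' independently at first-order rate `1/tau_phospho`, so the cumulative
#' probability of being phosphorylated by time t is `1 - exp(-t/tau_phospho)`.
#' A site is destined to join a cluster with probability
#' `clustered_fraction_max`; destined sites relocate from their initial
#' uniform position into one of `cluster_count` disc-shaped clusters at an
#' exponentially distributed relocation time with mean `tau_cluster`, so the
#' expected clustered fraction ramps as
#' `clustered_fraction_max * (1 - exp(-t/tau_cluster))`.
#'
#' The field is stored compactly as per-site event times rather than a
#' per-frame table; use [site_state()] to materialize positions and states at
#' any time point.
#'
#' @param config a [simulation_config()].
#' @return an object of class `phosphosite_field`: a list with `sites` (one
#'   row per site: dispersed and clustered coordinates, phosphorylation and
#'   relocation times, cluster id), `centers` (cluster centers) and `config`.
#' @export
simulate_phosphosite_dynamics <- function(config) {
  config <- validate_config(config)
  n <- config$n_sites
  with_substream(config$seed, "phospho", {
    x0 <- runif(n, 0, config$field_size)
    y0 <- runif(n, 0, config$field_size)
    t_phospho <- rexp(n, rate = 1 / config$tau_phospho)
    t_dephospho <- if (config$dephospho_rate > 0) {
      t_phospho + rexp(n, rate = config$dephospho_rate)
    } else rep(Inf, n)

    destined <- runif(n) < config$clustered_fraction_max
    m <- config$cluster_count
    r <- config$cluster_radius
    margin <- min(r, config$field_size / 2)
    centers <- data.frame(
      cluster_id = seq_len(m),
      cx = runif(m, margin, config$field_size - margin),
      cy = runif(m, margin, config$field_size - margin)
    )
    cluster_id <- rep(NA_integer_, n)
    xc <- x0; yc <- y0
    t_cluster <- rep(Inf, n)
    if (any(destined)) {
      k <- sum(destined)
      cluster_id[destined] <- sample.int(m, k, replace = TRUE)
      # uniform over the disc
      rr <- r * sqrt(runif(k)); th <- runif(k, 0, 2 * pi)
      xc[destined] <- centers$cx[cluster_id[destined]] + rr * cos(th)
      yc[destined] <- centers$cy[cluster_id[destined]] + rr * sin(th)
      t_cluster[destined] <- rexp(k, rate = 1 / config$tau_cluster)
    }
    sites <- data.frame(
      site_id = seq_len(n), x_disp = x0, y_disp = y0,
      x_clust = xc, y_clust = yc,
      t_phospho = t_phospho, t_dephospho = t_dephospho,
      t_cluster = t_cluster, cluster_id = cluster_id
    )
    structure(list(sites = sites, centers = centers, config = config),
              class = "phosphosite_field")
  })
}

#' Materialize the site field at a time point
#'
#' @param field a `phosphosite_field`.
#' @param t time after stimulation (s).
#' @return data frame with one row per site: `site_id`, `x_um`, `y_um`,
#'   `phosphorylated`, and `cluster_id` (NA while the site is still at its
#'   dispersed position or is never clustered).
#' @export
site_state <- function(field, t) {
  stopifnot(inherits(field, "phosphosite_field"))
  s <- field$sites
  moved <- s$t_cluster <= t
  data.frame(
    site_id = s$site_id,
    x_um = ifelse(moved, s$x_clust, s$x_disp),
    y_um = ifelse(moved, s$y_clust, s$y_disp),
    phosphorylated = s$t_phospho <= t & t < s$t_dephospho,
    cluster_id = ifelse(moved, s$cluster_id, NA_integer_)
  )
}

#' Number of phosphorylated sites over time
#'
#' @param field a `phosphosite_field`.
#' @param t vector of times (s).
#' @return integer vector of phosphorylated-site counts.
#' @export
n_phosphorylated <- function(field, t) {
  stopifnot(inherits(field, "phosphosite_field"))
  vapply(t, function(tt) {
    sum(field$sites$t_phospho <= tt & tt < field$sites$t_dephospho)
  }, integer(1))
}

#' Write the ground-truth site table as CSV
#'
#' Positions are the site positions at the end of the movie (after any
#' relocation into clusters).
#'
#' @param field a `phosphosite_field`.
#' @param path output CSV path.
#' @export
write_sites_csv <- function(field, path) {
  t_end <- field$config$n_frames * field$config$frame_interval
  st <- site_state(field, t_end)
  out <- data.frame(
    site_id = st$site_id, x_um = st$x_um, y_um = st$y_um,
    t_phospho_s = field$sites$t_phospho,
    cluster_id = st$cluster_id
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phosphosite_field <- function(x, ...) {
  cat("<phosphosite_field>", nrow(x$sites), "sites,",
      sum(is.finite(x$sites$t_cluster)), "destined for",
      nrow(x$centers), "clusters\n")
  invisible(x)
}
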