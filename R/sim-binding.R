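#' Simulate SH2 binding, diffusion, rebinding and unbinding
#'
#' Event-driven stochastic simulation on a fixed time grid (each camera frame
#' subdivided into 10 reaction-diffusion steps). Free phosphorylated sites
#' capture molecules from a well-mixed infinite cytosolic reservoir at
#' pseudo-first-order rate `k_on_intrinsic * sh2_concentration` per site. A
#' bound molecule performs Brownian motion with `D_bound` (reflective field
#' boundaries) and dissociates at `k_off_true`. Upon dissociation it attempts
#' to rebind free phosphorylated sites within `rebind_capture_radius` of its
#' current position, nearest site first, one Bernoulli(`rebind_probability`)
#' trial per site (its own site is excluded); on failure it returns to the
#' cytosol and the membrane dwell ends. Photobleaching times are drawn per
#' molecule at `k_bleach` and terminate observability, not the ground-truth
#' dwell.
#'
#' @param field a `phosphosite_field` from [simulate_phosphosite_dynamics()],
#'   generated with the same geometry as `config`.
#' @param config the [simulation_config()].
#' @return object of class `binding_event_log` with elements
#'   \describe{
#'     \item{events}{one row per molecule: `molecule_id`, `bind_time_s`,
#'       `unbind_time_s` (NA if censored at movie end), `censored`,
#'       `n_rebinds`, `bleach_time_s` (Inf if `k_bleach = 0`).}
#'     \item{positions}{per-frame positions of all ground-truth bound
#'       molecules with an `observable` flag (not yet bleached).}
#'     \item{occupancy}{per-frame ground-truth bound count, phosphorylated
#'       site count and cumulative binding events.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_sh2_binding <- function(field, config) {
  stopifnot(inherits(field, "phosphosite_field"))
  config <- validate_config(config)
  n_sub <- 10L
  dt <- config$frame_interval / n_sub
  n_steps <- (config$n_frames - 1L) * n_sub
  t_end <- (config$n_frames - 1L) * config$frame_interval
  s <- field$sites
  n <- nrow(s)
  L <- config$field_size

  p_bind <- 1 - exp(-config$k_on_intrinsic * config$sh2_concentration * dt)
  p_off <- 1 - exp(-config$k_off_true * dt)
  sd_step <- sqrt(2 * config$D_bound * dt)

  # site state
  site_x <- s$x_disp; site_y <- s$y_disp
  site_free <- rep(TRUE, n)
  reloc_order <- order(s$t_cluster)
  reloc_ptr <- 1L

  # molecule state, grown by doubling
  cap <- 256L
  mol_bind <- mol_unbind <- mol_bleach <- mol_x <- mol_y <- numeric(cap)
  mol_rebinds <- integer(cap)
  mol_site <- integer(cap)
  mol_first_site <- integer(cap)
  n_mol <- 0L
  bound_ids <- integer(0)

  grow <- function() {
    cap2 <- cap * 2L
    length(mol_bind) <<- cap2; length(mol_unbind) <<- cap2
    length(mol_bleach) <<- cap2; length(mol_x) <<- cap2
    length(mol_y) <<- cap2; length(mol_rebinds) <<- cap2
    length(mol_site) <<- cap2; length(mol_first_site) <<- cap2
    cap <<- cap2
  }

  frames_pos <- vector("list", config$n_frames)
  occ <- data.frame(frame = 0:(config$n_frames - 1L),
                    t_s = (0:(config$n_frames - 1L)) * config$frame_interval,
                    n_bound = NA_integer_, n_phospho = NA_integer_,
                    cum_bindings = NA_integer_)

  record_frame <- function(f, t) {
    phos_now <- sum(s$t_phospho <= t & t < s$t_dephospho)
    occ$n_bound[f + 1L] <<- length(bound_ids)
    occ$n_phospho[f + 1L] <<- phos_now
    occ$cum_bindings[f + 1L] <<- n_mol
    if (length(bound_ids)) {
      frames_pos[[f + 1L]] <<- data.frame(
        frame = f, t_s = t, molecule_id = bound_ids,
        x_um = mol_x[bound_ids], y_um = mol_y[bound_ids],
        observable = t < mol_bleach[bound_ids]
      )
    }
  }

  with_substream(config$seed, "binding", {
    record_frame(0L, 0)
    if (n_steps >= 1L) for (k in seq_len(n_steps)) {
      t <- k * dt
      # relocate sites whose clustering time has passed (only free sites move
      # instantly; an occupied site carries its molecule along)
      while (reloc_ptr <= n && s$t_cluster[reloc_order[reloc_ptr]] <= t) {
        j <- reloc_order[reloc_ptr]
        if (is.finite(s$t_cluster[j])) {
          site_x[j] <- s$x_clust[j]; site_y[j] <- s$y_clust[j]
        }
        reloc_ptr <- reloc_ptr + 1L
      }

      phos <- s$t_phospho <= t & t < s$t_dephospho

      nb <- length(bound_ids)
      if (nb) {
        # lateral diffusion with reflective boundaries
        mol_x[bound_ids] <- reflect01(mol_x[bound_ids] + rnorm(nb, 0, sd_step), L)
        mol_y[bound_ids] <- reflect01(mol_y[bound_ids] + rnorm(nb, 0, sd_step), L)

        # dissociation and local rebinding
        diss <- bound_ids[runif(nb) < p_off]
        for (i in diss) {
          own <- mol_site[i]
          site_free[own] <- TRUE
          captured <- FALSE
          if (config$rebind_probability > 0 && config$rebind_capture_radius > 0) {
            dx <- site_x - mol_x[i]; dy <- site_y - mol_y[i]
            r2 <- dx * dx + dy * dy
            cand <- which(phos & site_free & r2 <= config$rebind_capture_radius^2)
            cand <- cand[cand != own]
            if (length(cand)) {
              cand <- cand[order(r2[cand])]
              trials <- runif(length(cand)) < config$rebind_probability
              w <- which(trials)
              if (length(w)) {
                j <- cand[w[1L]]
                site_free[j] <- FALSE
                mol_site[i] <- j
                mol_x[i] <- site_x[j]; mol_y[i] <- site_y[j]
                mol_rebinds[i] <- mol_rebinds[i] + 1L
                captured <- TRUE
              }
            }
          }
          if (!captured) {
            mol_unbind[i] <- t
            bound_ids <- bound_ids[bound_ids != i]
          }
        }
      }

      # new binding from the cytosolic reservoir (after dissociation, so a
      # molecule's earliest possible unbinding is one step after it binds)
      if (p_bind > 0) {
        avail <- which(phos & site_free)
        if (length(avail)) {
          hit <- avail[runif(length(avail)) < p_bind]
          for (j in hit) {
            n_mol <- n_mol + 1L
            if (n_mol > cap) grow()
            mol_bind[n_mol] <- t
            mol_unbind[n_mol] <- NA_real_
            mol_bleach[n_mol] <- if (config$k_bleach > 0)
              t + rexp(1, config$k_bleach) else Inf
            mol_x[n_mol] <- site_x[j]; mol_y[n_mol] <- site_y[j]
            mol_rebinds[n_mol] <- 0L
            mol_site[n_mol] <- j
            mol_first_site[n_mol] <- j
            site_free[j] <- FALSE
            bound_ids <- c(bound_ids, n_mol)
          }
        }
      }

      if (k %% n_sub == 0L) record_frame(k %/% n_sub, t)
    }
  })

  events <- if (n_mol) {
    idx <- seq_len(n_mol)
    data.frame(
      molecule_id = idx,
      bind_time_s = mol_bind[idx],
      unbind_time_s = mol_unbind[idx],
      censored = is.na(mol_unbind[idx]),
      n_rebinds = mol_rebinds[idx],
      bleach_time_s = mol_bleach[idx],
      first_site_id = mol_first_site[idx]
    )
  } else {
    data.frame(molecule_id = integer(0), bind_time_s = numeric(0),
               unbind_time_s = numeric(0), censored = logical(0),
               n_rebinds = integer(0), bleach_time_s = numeric(0),
               first_site_id = integer(0))
  }
  positions <- do.call(rbind, frames_pos[!vapply(frames_pos, is.null, logical(1))])
  if (is.null(positions))
    positions <- data.frame(frame = integer(0), t_s = numeric(0),
                            molecule_id = integer(0), x_um = numeric(0),
                            y_um = numeric(0), observable = logical(0))
  structure(list(events = events, positions = positions, occupancy = occ,
                 t_end = t_end, config = config),
            class = "binding_event_log")
}

# reflective boundary map onto [0, L]
reflect01 <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Membrane dwell times from a ground-truth event log
#'
#' @param log a `binding_event_log`.
#' @param observed if `TRUE`, dwells are truncated at the per-molecule
#'   photobleaching time (what a tracking experiment observes); otherwise the
#'   ground-truth dwell is returned. Dwells of molecules still bound at the
#'   movie end are right-censored.
#' @return data frame with `dwell_s` and `censored`.
#' @export
dwell_times <- function(log, observed = FALSE) {
  stopifnot(inherits(log, "binding_event_log"))
  ev <- log$events
  end_true <- ifelse(ev$censored, log$t_end, ev$unbind_time_s)
  if (observed) {
    end_obs <- pmin(end_true, ev$bleach_time_s)
    censored <- ev$censored & ev$bleach_time_s > log$t_end
    data.frame(dwell_s = end_obs - ev$bind_time_s, censored = censored)
  } else {
    data.frame(dwell_s = end_true - ev$bind_time_s, censored = ev$censored)
  }
}

#' Write the ground-truth binding events as CSV
#'
#' @param log a `binding_event_log`.
#' @param path output CSV path.
#' @export
write_events_csv <- function(log, path) {
  ev <- log$events[, c("molecule_id", "bind_time_s", "unbind_time_s",
                       "censored", "n_rebinds")]
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.binding_event_log <- function(x, ...) {
  cat("<binding_event_log>", nrow(x$events), "binding events over",
      x$t_end, "s;", sum(x$events$n_rebinds), "rebinds\n")
  invisible(x)
}
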