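#' Simulation configuration
#'
#' Builds and validates the parameter set for a synthetic sptPALM/TIRF
#' experiment: a square membrane patch carrying `n_sites` receptor tyrosines
#' that phosphorylate with first-order kinetics (time constant `tau_phospho`),
#' progressively relocate into disc-shaped clusters (time constant
#' `tau_cluster`, asymptotic clustered fraction `clustered_fraction_max`),
#' and capture cytosolic SH2 domains from a well-mixed reservoir.
#'
#' Units are micrometers, seconds and molecules throughout. The per-site
#' pseudo-first-order binding rate is `k_on_intrinsic * sh2_concentration`
#' (1/s). A bound molecule diffuses laterally with `D_bound`, dissociates at
#' `k_off_true` and, upon dissociation, may rebind a free phosphosite within
#' `rebind_capture_radius` (nearest site first, one Bernoulli trial with
#' `rebind_probability` per free site in range) instead of returning to the
#' cytosol. Photobleaching (`k_bleach`) ends observability but not the
#' ground-truth dwell.
#'
#' @param field_size edge length of the square field (um).
#' @param pixel_size camera pixel size (um/px).
#' @param frame_interval camera frame interval (s). The stochastic engine
#'   subdivides each frame into 10 reaction-diffusion steps.
#' @param n_frames number of movie frames.
#' @param n_sites number of binding sites in the field.
#' @param tau_phospho first-order phosphosite creation time constant (s).
#' @param tau_cluster clustering ramp time constant (s).
#' @param cluster_count number of disc-shaped clusters.
#' @param cluster_radius cluster disc radius (um).
#' @param clustered_fraction_max asymptotic fraction of sites relocated into
#'   clusters, in \[0, 1\] (0 disables clustering).
#' @param k_on_intrinsic volumetric association constant per site (um^3/s).
#' @param sh2_concentration cytosolic SH2 concentration (molecules/um^3;
#'   1 uM is about 602 molecules/um^3).
#' @param k_off_true intrinsic dissociation rate (1/s).
#' @param D_bound lateral diffusion coefficient of bound molecules (um^2/s).
#' @param rebind_capture_radius rebinding capture radius (um).
#' @param rebind_probability per-site Bernoulli rebinding probability.
#' @param k_bleach photobleaching rate of activated fluorophores (1/s).
#' @param activation_density target density of simultaneously visible
#'   photoactivated molecules (molecules/um^2). Densities above 0.1/um^2 risk
#'   mistracking and trigger a warning.
#' @param psf_sigma Gaussian PSF standard deviation (um).
#' @param photons_per_molecule expected photon count per molecule per frame.
#' @param background_photons expected background photons per pixel per frame.
#' @param read_noise_sd Gaussian camera read noise (counts).
#' @param dephospho_rate optional first-order dephosphorylation rate (1/s);
#'   0 (default) disables it so the phosphorylated count is non-decreasing.
#' @param seed master integer seed; named substreams (phospho, binding,
#'   activation, noise) are derived from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
simulation_config <- function(field_size = 20.48,
                              pixel_size = 0.16,
                              frame_interval = 0.1,
                              n_frames = 600,
                              n_sites = 300,
                              tau_phospho = 60,
                              tau_cluster = 240,
                              cluster_count = 12,
                              cluster_radius = 0.3,
                              clustered_fraction_max = 0,
                              k_on_intrinsic = 2.5e-5,
                              sh2_concentration = 3914,
                              k_off_true = 1,
                              D_bound = 0.021,
                              rebind_capture_radius = 0.5,
                              rebind_probability = 0.3,
                              k_bleach = 0,
                              activation_density = 0.05,
                              psf_sigma = 0.16,
                              photons_per_molecule = 500,
                              background_photons = 10,
                              read_noise_sd = 2,
                              dephospho_rate = 0,
                              seed = 1L) {
  cfg <- list(
    field_size = field_size, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = n_frames, n_sites = n_sites,
    tau_phospho = tau_phospho, tau_cluster = tau_cluster,
    cluster_count = cluster_count, cluster_radius = cluster_radius,
    clustered_fraction_max = clustered_fraction_max,
    k_on_intrinsic = k_on_intrinsic, sh2_concentration = sh2_concentration,
    k_off_true = k_off_true, D_bound = D_bound,
    rebind_capture_radius = rebind_capture_radius,
    rebind_probability = rebind_probability, k_bleach = k_bleach,
    activation_density = activation_density, psf_sigma = psf_sigma,
    photons_per_molecule = photons_per_molecule,
    background_photons = background_photons, read_noise_sd = read_noise_sd,
    dephospho_rate = dephospho_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  if (cfg$activation_density > 0.1)
    warning("activation_density > 0.1 molecules/um^2: risk of mistracking ",
            "at this density", call. = FALSE)
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` or plain named list with the same fields.
#' @return the validated `sim_config`, invisibly usable in pipelines.
#' @export
validate_config <- function(cfg) {
  for (f in c("field_size", "pixel_size", "frame_interval", "tau_phospho",
              "tau_cluster", "cluster_radius", "psf_sigma",
              "photons_per_molecule", "activation_density"))
    assert_positive(cfg[[f]], f)
  for (f in c("k_on_intrinsic", "sh2_concentration", "k_off_true", "D_bound",
              "rebind_capture_radius", "k_bleach", "background_photons",
              "read_noise_sd", "dephospho_rate"))
    assert_nonneg(cfg[[f]], f)
  for (f in c("clustered_fraction_max", "rebind_probability"))
    assert_fraction(cfg[[f]], f)
  for (f in c("n_frames", "n_sites", "cluster_count")) {
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop2(f, " must be a positive integer")
  }
  if (cfg$clustered_fraction_max > 0 && cfg$cluster_count > cfg$n_sites)
    stop2("cluster_count exceeds n_sites: clusters cannot be populated")
  if (!is.finite(cfg$seed)) stop2("seed must be a finite integer")
  cfg
}

#' Read / write a simulation configuration as YAML
#'
#' The on-disk format is a flat YAML mapping of the `sim_config` fields;
#' unknown keys are rejected, missing keys fall back to the defaults of
#' [simulation_config()].
#'
#' @param path file path.
#' @return `read_config_yaml` returns a validated `sim_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop2("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, raw)
}

#' @param cfg a `sim_config`.
#' @rdname read_config_yaml
#' @export
write_config_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$field_size, "x", x$field_size, "um,",
      x$n_frames, "frames @", x$frame_interval, "s;",
      x$n_sites, "sites, tau_phospho =", x$tau_phospho, "s\n")
  invisible(x)
}
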