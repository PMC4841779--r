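# sh2spt

Single-molecule kinetics of SH2-domain membrane recruitment.

When a receptor tyrosine kinase such as EGFR is activated, cytosolic proteins
carrying SH2 domains are recruited to phosphotyrosine (pY) sites on the plasma
membrane. Live-cell single-particle tracking (sptPALM/TIRF) shows a puzzle:
total SH2 membrane binding keeps rising for ~10 minutes even though the
binding sites themselves are created within 1–2 minutes. `sh2spt` implements
the quantitative machinery needed to study this lag: recruitment is treated as
a kinetically controlled — not equilibrated — process in which progressive
clustering of pY sites slows the apparent dissociation rate through local
rebinding, so occupancy keeps integrating long after site creation has
plateaued.

The package is aimed at people analyzing (or simulating) single-molecule
membrane-binding experiments: it contains a full synthetic-data generator, so
every estimator can be validated against ground truth without any microscopy
data.

## The model

The number of membrane-bound SH2 molecules obeys the balance

    d[mem:SH2]/dt = gamma_on(t) - lambda_off(t) * [mem:SH2](t)

where `gamma_on(t)` is the apparent recruitment rate (newly appearing
molecules per unit time, measured in 0.8-min windows of tracked movies) and
`lambda_off(t)` the apparent dissociation rate (censored-exponential fit to
membrane dwell times, corrected for photobleaching). The integrating-factor
solution

    mem:SH2(t) = c e^{-∫λ dt} + e^{-∫λ dt} ∫ γ(s) e^{∫λ ds} ds

is evaluated by high-order quadrature and cross-validated against adaptive
numeric integration. Two back-of-the-envelope bounds for the diffusion-limited
per-site on-rate are provided: `k_on = k_off / K_d` and the Smoluchowski-type
bound `4πDs/N` for a cluster of radius `s` holding `N` sites.

What the modules do:

| area | functions |
| --- | --- |
| simulation | `simulation_config`, `simulate_phosphosite_dynamics`, `simulate_sh2_binding`, `render_movie`, `write_movie_tiff` |
| localization & tracking | `detect_spots`, `detect_movie`, `link_trajectories`, `compute_msd` |
| kinetics | `estimate_gamma_on`, `estimate_lambda_off`, `fit_recovery`, `timeseries_r2` |
| cluster analysis | `kmeans_threshold`, `segment_clusters`, `partition_trajectories`, `groupwise_gamma_on` |
| occupancy model | `integrate_occupancy`, `analytic_occupancy`, `on_rate_from_kd`, `smoluchowski_upper_bound` |
| far-Western tables | `normalize_to_probe_max`, `relative_specificity`, `hcluster_uncentered` |
| orchestration | `scenario_config`, `run_scenario`, `compare_scenarios` |

## Worked example

Run the two built-in matched scenarios — an EGF-like condition in which 80%
of sites progressively cluster, and a pervanadate-like condition with the same
site-creation kinetics but no clustering:

```r
library(sh2spt)
compare_scenarios(seed = 7)
```

```
       scenario tau_recruit_min tau_gamma_on_min tau_site_creation_min
1 egf-clustered        5.070258        0.6866999             0.9463901
2  pv-dispersed        1.123514        0.9727309             0.9874131
  lambda_off_per_s final_clustering_metric n_events
1        0.3702105                 3.39292     8174
2        0.7979226                 0.00000    13841
```

Reading the table: both conditions create binding sites with a ~1 min time
constant (`tau_site_creation_min`). In the dispersed condition, total
occupancy recovers with essentially the same constant (1.12 min — recruitment
tracks site creation). In the clustered condition, the apparent off-rate drops
to 0.37/s (the intrinsic rate is 1/s; local rebinding inside clusters
recaptures dissociating molecules), and total occupancy consequently lags with
a 5.1 min time constant — about five times slower than the binding-site
supply, and far slower than the rise of the recruitment rate itself
(`tau_gamma_on_min` below 1 min in both conditions).

A full movie-based analysis of one simulated experiment:

```r
cfg <- simulation_config(seed = 11)               # defaults: dispersed field
field <- simulate_phosphosite_dynamics(cfg)
log   <- simulate_sh2_binding(field, cfg)
movie <- render_movie(log, cfg)
loc   <- detect_movie(movie, psf_sigma = cfg$psf_sigma)
trk   <- link_trajectories(loc, suggest_max_displacement(cfg$D_bound,
                                                         cfg$frame_interval))
compute_msd(trk, cfg$frame_interval)
#> <msd_result> 390 trajectories; D = 0.02194 um^2/s
```

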