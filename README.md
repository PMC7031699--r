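# lipidkinetics

Quantitative analysis of protein–lipid interactions in coarse-grained
membrane simulations, aimed at the GPCR / membrane-protein simulation
community: given trajectories of a receptor embedded in a complex bilayer
(e.g. an asymmetric, in vivo-mimetic ten-species membrane), the package
turns raw frames into the standard repertoire of lipid-interaction
statistics — and ships a synthetic trajectory generator with *known*
binding kinetics so that every stage of the analysis can be validated
against ground truth without multi-microsecond MD data.

## What it computes

- **Dual-cutoff contact events.** A lipid–residue contact opens when the
  lipid centre of mass comes within 0.55 nm of the residue COM and closes
  only when it moves beyond 1.4 nm. The hysteresis suppresses boundary
  rattling, so a "continuous contact" is a single event even if the
  distance briefly fluctuates between the two cutoffs.
- **Residence-time kinetics.** Per-residue interaction-duration profiles,
  and the dissociation rate from the mono-exponential decay of the
  duration distribution, *N(t) = A e^(−k_off t)*, fitted by weighted
  nonlinear least squares with a case-resampling bootstrap CI and a
  closed-form 1/mean cross-check. Markovian unbinding makes residence
  times exponential, so k_off is the decay constant.
- **Binding-site mapping.** Residues with long mean durations are
  clustered into spatially connected patches (binding sites); bound poses
  are ranked by a per-bead 3D density score and a representative pose is
  extracted.
- **Lipid interplay.** Pearson correlation of per-repeat mean interaction
  durations between cohabiting species,
  `PCC = Σ(xᵢ−x̄)(yᵢ−ȳ) / sqrt(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²)`,
  classifying pairs as synergistic (PCC > 0) or competing (PCC < 0).
- **Spatial statistics.** Surface-referenced radial distribution
  functions with Monte-Carlo shell-area normalization, 2D in-plane
  density maps per leaflet, leaflet assignment (only cholesterol is
  allowed to flip), and Voronoi-tessellation area per lipid under
  periodic boundaries with receptor beads as additional generators.
- **Umbrella-sampling free energies.** Window extraction at 0.05 nm
  spacing along a pulled coordinate, a 1D WHAM solver, Bayesian-bootstrap
  (Dirichlet-weight) error bars, and a dissociation constant from the
  bound-region integral K_d = V° / (A ∫_bound e^(−W(ξ)/kT) dξ) with an
  explicit standard-state convention.
- **Synthetic membrane trajectories.** Lipids diffuse laterally in a
  periodic box around a static multi-helix receptor bead model and bind
  designed sites with exact exponential residence times (k_off in the
  2–14 μs⁻¹ regime); every transition is recorded in a ground-truth
  ledger. GRO topology + multi-frame GRO trajectory output.

## Worked example

Simulate four 10 μs repeats of a membrane patch with two designed sites —
a PIP2 site with true k_off = 4 μs⁻¹ and a GM3 site with 10 μs⁻¹ — then
recover the kinetics through the full detection pipeline:

```r
library(lipidkinetics)

comp <- default_composition()        # the 10-species asymmetric bilayer
sys  <- synthetic_binding_system(n_sites = 2, species = c("PIP2", "GM3"),
                                 k_off = c(4, 10), k_on = 500,
                                 capture_radius = 1.7, n_helices = 4)
events <- do.call(rbind, lapply(1:4, function(r) {
  cfg <- system_config(box_nm = c(10, 10, 10), stride_ns = 1,
                       total_time_us = 10, seed = 100 + r)
  run <- simulate_membrane_trajectory(comp, sys$receptor, sys$sites, cfg,
                                      n_upper = 30, n_lower = 30,
                                      exclusion_radius = 2.6)
  contact_events(run$trajectory, species = c("PIP2", "GM3"), run = r)
}))
profile <- residue_duration_profile(events)
profile
#> Duration profile: 6 residue/species entries, 1227 events
#>   strongest interactions:
#>     residue 2 / PIP2: 254.0 ns (n=125)
#>     residue 3 / PIP2: 254.0 ns (n=125)
#>     residue 4 / PIP2: 254.0 ns (n=125)
#>     residue 21 / GM3: 97.0 ns (n=284)
#>     residue 22 / GM3: 97.0 ns (n=284)

site_koff(profile, sys$sites[[1]], events)
#> Mono-exponential k_off fit: k_off = 3.93 /us (95% CI 3.27-4.76), A = 27.1, n = 125
#>   1/mean cross-check: 3.94 /us
```

The PIP2 site's anchor residues carry mean contact durations of ~254 ns
(the exponential mean 1/k_off = 250 ns), and the fitted k_off of
3.93 μs⁻¹ recovers the designed 4 μs⁻¹ within its bootstrap CI. A
config-driven end-to-end run (`run_pipeline()`) chains equilibration
detection, contacts, site identification, spatial statistics, interplay
and the PMF stage, writing every intermediate under a run directory.

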