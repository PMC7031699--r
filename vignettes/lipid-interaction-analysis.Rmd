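---
title: "Protein-lipid interaction analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-lipid interaction analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidkinetics)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The membrane model

The reference composition is an asymmetric, in vivo-mimetic bilayer of
ten lipid species: the upper (extracellular) leaflet carries
POPC 20%, DOPC 20%, POPE 5%, DOPE 5%, sphingomyelin (PSM) 15%, the
ganglioside GM3 10% and cholesterol 25%; the lower (cytoplasmic) leaflet
POPC 5%, DOPC 5%, POPE 20%, DOPE 20%, POPS 8%, DOPS 7%, the
polyanionic phosphoinositide PIP2 10% and cholesterol 25%. Fractions are
stored as fractions internally; configuration files may declare either
`fraction` or `percent` units. Discretization into molecule counts uses
largest-remainder rounding with an alphabetical tie-break, so counts are
deterministic and sum exactly to the requested leaflet size.

Each species carries a representative-bead rule used by the in-plane
analyses: the glycerol-bead midpoint (GL1/GL2) for glycerophospholipids
and PIP2, the sphingosine midpoint (AM1/AM2) for sphingomyelin and GM3,
and the hydroxyl bead (ROH) for cholesterol. Cholesterol is one species
present in both leaflets; it is the only species whose leaflet label is
re-evaluated every frame, because it is the only lipid expected to
flip-flop on simulation timescales.

## Contact kinetics

**Dual-cutoff events.** A contact between a lipid and a residue opens at
the first frame at which the lipid COM comes closer than the lower
cutoff (0.55 nm) to the residue COM, remains open while the distance
stays at or below the upper cutoff (1.4 nm), and closes at the first
frame beyond it. The event duration is `t_close − t_open`, with
`t_close` the first frame beyond the upper cutoff; this endpoint
convention is applied consistently, including when events are compared
with the generator's ground-truth ledger (agreement within one frame
stride at both endpoints). Events still open at the trajectory end are
flagged censored; they are excluded from mean durations and k_off fits
(uncensored exponential fitting is unbiased) but counted separately.
Distances are COM-to-COM over whole molecules and whole residues, with
the minimum-image convention in the periodic membrane plane; the box is
not treated as periodic along the membrane normal.

**k_off.** Under Markovian unbinding, residence times are exponential,
so the duration distribution is fitted as `N(t) = A exp(-k_off t)`. The
histogram uses a default bin width of `max(duration)/30` (configurable;
raw counts by default, a normalized density optionally). The fit is
weighted nonlinear least squares with Poisson weights taken from the
*model* after two reweighting passes — weighting by observed counts
over-pulls sparse tail bins and biases k_off upward by several percent
at a few hundred events. The closed-form exponential rate `1/mean` is
always reported alongside as a cross-check, and the confidence interval
comes from a 200-resample case bootstrap. Fits require at least 50
uncensored durations (configurable floor) and refuse degenerate
(all-equal) samples. Per-site rates pool the durations of the residue
with the largest mean duration within the site (top-1 by default),
mirroring how site rates are read off duration profiles.

**Occupancy and equilibration.** The first lipid shell is the region
within 1.0 nm of the receptor surface (minimum distance to any receptor
bead), the boundary indicated by the RDFs. Equilibration of shell
exchange is detected by block averaging (20 blocks by default): the
earliest block from which all later block means stay within 3 standard
errors of the final-half mean. The standard error assumes
frame-level independence within the final half; for strongly
autocorrelated occupancy series the tolerance should be raised — the
pipeline treats a failed plateau search as "use a conservative window"
(the last 5/8 of the span), mimicking the 3–8 μs analysis window used on
8 μs trajectories.

## Binding sites, poses and interplay

The per-residue duration profile is the central statistic: sites are its
spatial clusters. Residues with mean duration at or above a threshold
become nodes, nodes whose residue COMs lie within the adjacency radius
(1.0 nm default) are connected, and connected components of at least two
residues are sites, ranked by their maximum member duration. The
threshold defaults to 3x the profile-wide median positive duration: the
median captures the diffusive background (a free lipid needs roughly
`L²/4D` to wander a cutoff length away, ~16 ns at the default diffusion
coefficient), so the rule is scale-free in the units of the trajectory.
Both threshold and radius are explicit parameters because site
delineation is this package's formalization, not a published algorithm.

Bound poses are scored by bead-density: frames in which a lipid COM lies
within 1.0 nm of *all* basic residues of the site (the literal reading;
a union mode is provided because the intersection can be empty for wide
sites) contribute their bead positions to per-bead-index 3D histograms
on a 0.1 nm voxel grid (commensurate with CG bead size), and each pose's
score is the sum over its beads of the density at the bead position.
Ties rank toward the lower frame index, making the representative pose
deterministic.

Lipid interplay is the Pearson correlation of per-repeat mean
interaction durations of two species, computed exactly from the
definitional formula (validated against a brute-force evaluation to
1e-12). Pairs with |PCC| >= 0.5 are annotated synergistic or competing
by sign; the threshold is an annotation aid, not a hypothesis test.

## Spatial statistics

**Surface RDF.** g(r) is the distribution of lipid COM distances to the
receptor surface. The accessible in-plane area of a distance shell
around an irregular protein cross-section has no closed form, so shell
areas are estimated per leaflet by Monte Carlo (1e5 samples by default,
seedable), and the histogram is normalized by shell area times the bulk
(whole-box) species density, so g tends to 1 far from the protein. For
systems with an excluded zone the whole-box density slightly
underestimates the true bulk density; the flatness validation uses an
ideal-gas system where the two coincide.

**2D density maps.** COM counts per xy cell, averaged over frames and
normalized per cell area, per leaflet; the effective spacing divides the
box edge exactly so the conservation identity
`sum(density) x cell_area x frames = molecule-frames` is exact. The
receptor is static in these trajectories, so maps are already
receptor-referenced and no frame alignment is applied.

**Voronoi area per lipid.** Per leaflet, the representative points of
the lipids plus the xy projections of receptor beads in that leaflet's
z-slab (between the bilayer midplane and the leaflet midplane) generate
a periodic 2D Voronoi tessellation, computed by half-plane clipping
against the 3x3 tiling of periodic images. This is exact for cells that
do not span half the box — the documented limitation; with membrane-like
point densities it is never approached. Receptor beads stacked on one
helix axis project to a single generating point. The per-leaflet cell
areas sum to the box area to 1e-6 relative (validated on 1000 random
frames), and a lipid's APL is its cell area, with receptor cells
reported separately.

## Umbrella sampling and free energies

Windows are extracted from a pulled trajectory by first-crossing of
successive 0.05 nm multiples of the reaction coordinate; spacing and
window count are independent arguments. The WHAM solver iterates the
standard self-consistency equations on a default 100-bin grid over the
sampled range until window shifts change by less than 1e-6 kJ/mol,
anchoring the profile minimum at zero; bins without samples are NA.
Statistical errors use the Bayesian bootstrap: each replicate reweights
every sample with Dirichlet(1, ..., 1) weights within its window,
re-solves WHAM warm-started from the full-data shifts, re-anchors at its
minimum, and the per-bin SD across replicates is reported. The
validation generator draws window samples from the exact biased
Boltzmann density by inverse-CDF interpolation on a fine grid, with a
trapezoidal CDF (a rectangle-rule CDF leaves an O(grid step) bias that
visibly tilts a recovered flat profile).

K_d comes from the bound-region configurational integral of the profile
referenced to its bulk plateau (mean of the last 20% of bins), mapped to
a volume through an explicit cross-sectional area (1 nm² default) and
referenced to the 1 M standard state (1.661 nm³ per molecule). The bound
region defaults to the interval from the profile start to the first
point within 1 kJ/mol of bulk. Every K_d output records this convention
in full, because the number is meaningless without it. Temperature
defaults to 323 K throughout the CG analyses.

## The synthetic generator: what it emulates, and what it does not

The generator exists so that every analysis stage has a ground truth.
It emulates the *statistical* structure of equilibrium CG-MD of a
receptor in a mixed membrane: per-species lateral diffusion (2D
Brownian steps, periodic box, hard-core exclusion around the receptor),
leaflet structure (midplanes at ±2 nm; head-group beads define leaflet
membership), designed binding sites with first-order binding hazards and
*exactly* exponential residence times (event-driven draws, so the k_off
fit's central assumption holds by construction), cholesterol flip-flop
(0.05 μs⁻¹ hazard), and frame output on the 1–10 ns stride scale. A
bound lipid is tethered with clamped Gaussian jitter so its COM stays
within 0.45 nm of every anchor residue — safely under the 0.55 nm
detection cutoff, so detection depends on the analysis code rather than
marginal geometry — and on unbinding it is displaced 1.6 nm from the
anchor (beyond the 1.4 nm upper cutoff) within one frame, making ledger
and detected event ends comparable within one stride.

It is *not* a physical simulator: no forces, no thermostat, no Martini
interactions, no lipid internal dynamics (beads ride rigidly on the
COM), no membrane undulations or curvature, and a rigid receptor —
state dependence is emulated by supplying different site rate tables,
not by conformational dynamics. Passing validations therefore
demonstrate correctness of the *analysis* chain under the stated
kinetic model, not fidelity of any force field. Per-species diffusion
coefficients are not calibrated to any published system; the default,
30 nm²/μs, is a realistic magnitude for coarse-grained lipids (whose
effective dynamics are several-fold faster than atomistic) and is fully
configurable.

Two geometric choices in the bundled fixtures are deliberate. The
helix ring radius (2.0 nm) makes neighbouring anchor points more than
1.4 nm apart, so a lipid bound at one site cannot hold a contact at
another. For kinetics-recovery studies the hard-core radius is padded
0.6 nm beyond the anchor ring, so free lipids can never dip below the
lower cutoff at an anchor residue and every detected event corresponds
to a ledger binding; for site-mapping studies the default (snug) core is
used instead, precisely so that a diffusive contact background exists
for the threshold rule to discriminate against.

## Validation scales

The studies run by `scripts/acceptance.R` and the acceptance tests use
problem sizes chosen to give stable statistics on a single core within
minutes: 1000 random series for detector equivalence; thirty 10 μs
repeats of a 10x10 nm patch (60 lipids) for k_off recovery with >= 500
events per site across k_off in {2, 5, 9, 14} μs⁻¹; one 20 μs, 120-lipid
trajectory for nine-site recovery; twenty seeds of 50 windows x 5000
samples (k = 1000 kJ/mol/nm², 0.05 nm spacing) with 25 bootstrap
replicates for WHAM; 1000 random frames for Voronoi conservation; and
1e5 molecule-frames for RDF flatness. The multi-microsecond,
~1000-lipid scale of production CG-MD is intentionally out of scope
here: the statistics validated are scale-free in the relevant regimes
(events per site, samples per window), and the generator accepts larger
sizes where needed.

## Known limitations

- The periodic Voronoi construction is exact only for cells smaller
  than half the box; pathological near-empty leaflets should be
  tessellated with more generators or a larger margin.
- The RDF bulk-density normalization uses the whole-box density; in
  systems with a large excluded area, bulk g plateaus slightly above 1.
- The equilibration detector assumes weak within-block autocorrelation;
  for slowly exchanging shells, raise the tolerance or block count.
- Site delineation (threshold x adjacency clustering) is an explicit
  formalization with configurable parameters, not an attempt to
  reproduce any particular published site list; likewise, the K_d
  standard-state mapping must be quoted with its convention when
  compared across studies.
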