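---
title: "Models and methods: GABAergic volume transmission and metabotropic summation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: GABAergic volume transmission and metabotropic summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngfsum)
```

Neurogliaform cells (NGFCs) are cortical interneurons that inhibit their
neighborhood without classical synapses: GABA released from their dense
axonal boutons diffuses through the extracellular space and reaches
synaptic and extrasynaptic GABA~A~ and metabotropic GABA~B~ receptors
within a micrometer-scale radius (volume transmission). This package
implements, end to end, the quantitative machinery needed to study that
mode of signaling: quantal analysis of unitary connections, generative
models of NGFC axonal arbors and of the layer-1 NGFC population, coverage
and source-multiplicity mapping, postsynaptic summation metrics, calcium
imaging responsiveness classification, and a particle-based stochastic
simulator of the GABA~B~ &rarr; G&beta;&gamma; &rarr; GIRK cascade on a
dendritic membrane embedded in a tortuous extracellular space.

Every analysis can be driven by the package's synthetic-data generators,
which reproduce the statistical structure the methods assume; no external
recordings are required. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical choices, and states
what the synthetic experiments do and do not show about real data.

## Binomial-quantal model and Bayesian quantal analysis

A unitary connection is modeled with `n_sites` functional release sites
(Nfrs), each releasing independently with probability `p` (set by the
extracellular Ca^2+^/Mg^2+^ condition). Each released vesicle contributes
a gamma-distributed quantal amplitude with mean `q` (pA) and coefficient
of variation `quantal_cv`; Gaussian baseline noise (`noise_sd`) is added.
The gamma choice keeps amplitudes positive; recorded data are IPSC
magnitudes, so all amplitudes are positive in this package.
`simulate_quantal()` draws trials from this model and `quantal_moments()`
gives the exact mean `n p q` and variance
`n p (1 - p) q^2 + n p (q cv)^2 + noise^2` used as oracles in the tests.
Generator defaults (`quantal_cv = 0.3`, `noise_sd = 2` pA) are typical
values for cortical paired recordings.

`bqa_fit()` performs Bayesian quantal analysis over two or more
release-probability conditions that share `n_sites` and `q` but have
condition-specific `p`. The likelihood is a binomial mixture over the
released-site count; the k-site component density is the k-fold gamma
convolution plus Gaussian noise, evaluated exactly (Gauss–Hermite
quadrature over the noise) while the gamma shape `k / cv^2` is small
enough to be skewed and by a moment-matched normal otherwise (threshold
shape 30, where the two differ negligibly). Priors are weakly
informative: Nfrs uniform on 1..30, `q` log-uniform on 0.5–20 pA, `p`
uniform per condition, and small marginalization grids over `quantal_cv`
and `noise_sd`.

**Point estimates.** With ~33 trials per condition the joint likelihood
of (Nfrs, q) is a ridge (`Nfrs * q` nearly constant; the profile
log-likelihood is flat within ~1 nat from the true Nfrs up to the prior
bound). The median of the Nfrs marginal therefore inherits the arbitrary
upper prior bound and overestimates Nfrs systematically. The package
reports Nfrs at the joint posterior mode — invariant to that bound — and
`q` as the posterior mean conditional on the modal Nfrs, which removes
the ridge-induced skew and the grid quantization; marginal medians and
credible intervals are still available through `tidy()`. Even so, the
recovery of Nfrs from 33 trials is intrinsically limited: simulation
shows individual estimates spread by roughly ±30% around the truth,
which mirrors the large between-connection spread of published Nfrs
estimates.

`kmeans_event_separation()` reproduces the uniquantal cross-check:
K-means (k = 3, deterministic k-means++ initialization) on standardized
per-event initial slope, peak amplitude and area, with clusters labeled
failure / uniquantal / multiquantal by increasing amplitude centroid.
`stability_correlation()` screens epochs for rundown (Pearson r of
amplitude against elapsed time).

## Axonal arbors, Sholl calibration and boutons

`grow_axon()` expands fixed 10 µm elementary segments from the soma.
Realized total cable length and branch-point count are drawn per cell
from truncated normals; branch events are scattered uniformly over growth
steps; segment orientations follow the parent direction with a folded
normal polar deflection (`polar_sd`) and uniform azimuth, and daughters
deviate by `branch_angle` on average. The 10 µm step is a numerical
choice (no biological step size is implied); coordinates are
right-handed, in µm, with z the depth below the pia.

`sholl_analysis()` resamples the cable at 1 µm and bins length into
half-open 10 µm shells around the soma; the partition conserves total
cable length to better than 0.5% by construction.
`calibrate_growth()` tunes (`polar_sd`, `branch_angle`) by simulated
annealing so that pooled Sholl distance samples from a generated
population pass a two-sample Kolmogorov–Smirnov test against the target
profile. Two statistical points matter here. First, the annealing energy
is evaluated with a fixed RNG seed so the objective is deterministic;
the result is then re-checked on a fresh draw. Second, pooled Sholl
samples are strongly clustered within cells (a whole arbor shifts
together), so the comparison is run on a population (default 32 cells)
with a modest number of pooled samples (default 60 per side): treating
thousands of resampled points as independent would reject identical
parameter sets almost surely. With these defaults a self-consistent
target is recovered with passing probability ~0.9 and a clearly wrong
orientation parameter is rejected ~90% of the time.

`place_boutons()` decorates each maximal unbranched cable with boutons
whose consecutive spacings are gamma distributed with mean 3.36 µm and SD
2.54 µm (the measured interbouton statistics); the gamma is
parameterized by mean/SD so the spacing distribution is unbiased, unlike
a zero-truncated normal. Realized within-cable spacings are nevertheless
very slightly length-biased (~1–3% low) because a cable end truncates the
last spacing — the same censoring that affects spacings measured along
reconstructed axons; estimates in the tests therefore use on the order of
1,000–1,500 spacings, where the bias is well inside three standard
errors.

## Population model and coverage mapping

`sample_somata()` places 374 somata in a 354 × 354 × 140 µm³ volume,
uniform in the horizontal plane and following a depth-density profile
peaking at 50–150 µm below the pia (`depth_density_profile()` ships a
piecewise-constant stand-in and accepts measured histograms). `population_layout()` grows one arbor per
soma and pools all boutons; `build_coverage()` counts, for every 1 µm
voxel center, the boutons within the transmitter diffusion radius
(default 1.5 µm, the effective volume-transmission range) and the number
of distinct source cells among them. Voxels within one radius of a
volume face are flagged `edge` and excluded from multiplicity summaries
by default, because coverage there is deflated by the boundary.
`source_multiplicity()` optionally subsamples active cells
(Bernoulli `active_fraction`; 1 = full population-level cooperativity,
2/3 approximates the coactive fraction seen in vivo) and reports the
percentage of covered voxels reached by exactly 1, 2, 3 or ≥4 distinct
cells. At full scale the published split (67.7 / 15.34 / 8.5 / 8.45%)
depends on the deposited reconstructions; with the synthetic arbors the
package reproduces the qualitative structure (single- plus two-source
voxels dominate) at reduced scale, which is what the tests assert.

## Transmission range

`count_boutons_near_dendrite()` counts presynaptic boutons within
increasing radial distances of the postsynaptic dendrite polylines
(boundary-inclusive, centerline distance minus the local radius when
radii are available; the default radius grid 0.25–3.0 µm in 0.25 µm steps
covers the empirically relevant window). `estimate_range()` inverts the
monotone count curve at Nfrs mean ± SD by linear interpolation and
aggregates connections as the mean of the interval endpoints (the
aggregation across connections has no canonical definition; mean of
endpoints is this package's declared choice). `correlation_vs_radius()`
locates the radius at which bouton counts correlate best with Nfrs.

## Summation metrics

`measure_kinetics()` implements the standard conventions: peak as the
extremum of the baseline-subtracted trace in a window after the stimulus
(50 ms for fast, ~400 ms for slow signals; baseline = mean of the 50 ms
pre-stimulus window), 10–90% rise time, full width at half maximum, and
decay time measured at 67.3% decay (32.7% of peak remaining). All
crossings are linearly interpolated.

`summation_nonlinearity()` compares a measured compound response with the
arithmetic sum of its unitary responses. The peak nonlinearity is
`100 * (measured_peak - calculated_peak) / calculated_peak`; dividing by
the signed peak makes "smaller in magnitude than the sum" negative
(sublinear) for hyperpolarizing and depolarizing responses alike. The
time-resolved nonlinearity uses the same signed scalar denominator so the
trace remains interpretable in percent. `normalize_burst()` normalizes
burst-evoked peaks within each recording set to its own 1-AP response —
ratios of grand means across sets differ from the mean of per-set ratios,
and only the latter is computed.

`synth_ipsp()` generates unitary IPSP waveforms from target kinetics
using `(1 - exp(-t/tau_r))^n * exp(-t/tau_d)`. With `n = 1` this is the
classical difference of exponentials, which cannot produce half-width /
rise-time ratios below ~4.3; metabotropic IPSPs (rise ~87 ms, half-width
~252 ms, ratio 2.9) need the sigmoidal onset that `n > 1` provides,
consistent with a multi-step intracellular cascade. The three shape
parameters are calibrated numerically (Nelder–Mead from several starting
points) to match the requested rise and half-width within 5%.

## Calcium imaging

`delta_f_over_f()` computes `(F - F0)/F0` with `F0` a running 20th
percentile in a 3 s sliding window (both configurable); this removes slow
drifts while preserving transients. `classify_responsive()` averages the
trials and calls a cell responsive when the post-stimulus peak of the
averaged dF/F exceeds three times the SD of its pre-stimulus noise
(1 s window). The peak is searched within 300 ms after the stimulus,
bracketing the rise of a stimulus-locked transient; since the rule takes
a maximum over samples, widening this window would inflate the
false-positive rate of the 3×SD criterion (it is ~3% per 100 pure-noise
sets at the default frame rate).

## Extracellular space: volume fraction and tortuosity

`ecs_lattice()` builds the periodic obstacle geometry: 0.8 µm cubic cells
carrying a 0.4 × 0.4 µm, 0.34 µm deep dead-end cavity that opens on one
face, spaced 0.032 µm apart, tiling a 13.28 × 13.28 × 6.592 µm³ box
(1162.55 µm³). The extracellular fraction per unit cell is analytic —
`1 - (cube^3 - cavity volume)/pitch^3` = 0.205, i.e. 0.2 to one decimal —
and is cross-checked against a fine voxelization. The cavity depth axis
is degenerate with the cube edge in the printed geometry; the cavity is
assumed square in plan and opening on the +z face.

`estimate_tortuosity()` releases walkers at equilibrium (uniform over the
extracellular volume, which weights the dead-space cavities correctly),
steps them on an 8 nm lattice with steps into solid rejected (reflecting
boundaries), and fits the long-time MSD slope over the second half of the
walk; `lambda = sqrt(D_free/D_eff)` with the free-diffusion reference
known analytically for the same walk. With 10^4 walkers and 4 × 10^5
steps the estimate converges to ~1.55, inside the 1.6 ± 0.1 band expected
for cortical tissue; the residual gap to 1.6 reflects the single-opening
cavity orientation, which the stated cell and cavity dimensions leave open.

## Particle-based GABA~B~/GIRK cascade simulator

`run_simulation()` propagates:

* **GABA** in 3D inside a reflecting box, with effective diffusion
  `D_free / lambda^2` (default 0.5 µm²/ms free, lambda = 1.6). The
  homogenized coefficient stands in for explicit collisions with every
  lattice obstacle; the lattice enters through its tortuosity and
  bounding box. GABA is removed by a first-order sink calibrated so the
  free-GABA decay time constant is ~11.5 ms — the sink stands in for
  uptake processes outside the model's scope (the model deliberately
  contains no GABA transporters and no GABA~A~ receptors). Binding
  consumes the transmitter, so the free-GABA count is nonincreasing
  between release events.
* **Surface species** in a 2D parameterization of the dendritic membrane
  (axial coordinate × unrolled circumference, periodic), with spines as
  equal-area disk patches. GABA~B~ receptor clusters (1–8 receptors,
  laterally mobile) bind GABA within a 3D reaction radius of the
  membrane; active receptors catalyze nearby immobile G-protein
  heterotrimers into free G&beta;&gamma; (2D diffusion, default
  0.1 µm²/s); G&beta;&gamma; binds immobile GIRK channels (clusters of
  1–4) sequentially, and a channel counts as activated when all four
  binding sites are occupied; free G&beta;&gamma; reassociates into
  heterotrimers at a first-order rate.

Bimolecular events are resolved by reaction-radius sampling with per-pair
probabilities `k dt / (N_A V_rho)` (3D) and `k dt / (pi rho^2)` (2D),
which reproduces mass action exactly in the well-mixed limit — the test
suite verifies the match against an independent `deSolve` integration
within three Monte Carlo standard errors. When the dendrite volume is
excluded (the default), the accessible reaction volume at a surface
receptor is the half-sphere. The run aborts if any per-step event
probability exceeds 0.2 (time step too large for the fastest rate); the
default step is 1 µs, and the reduced-scale tests use 5 µs against that
criterion.

**Release schedule.** Four release sites at 1.2 ± 0.7 µm from the
dendrite, with consecutive releases 10 ms apart (100 Hz) and a constant
amount per event. `release_profile()` gives the configured peak
concentration versus distance as a piecewise log-linear curve through
1 mM at 0 µm, 60 µM at 0.5 µm and 1 µM at 2 µm, continuing the final
exponential slope beyond the last anchor.

**Cluster placement.** `place_surface_molecules()` follows the
seed-particle cascade: GIRK-producing secondary seeds nucleate in place;
GABA~B~-producing seeds diffuse for a calibrated delay plus an
exponential waiting time before nucleating, which sets the
receptor-to-channel cluster distance distribution.
`calibrate_cluster_placement()` recovers (delay, forward rate) from a
target distance sample by simulated annealing on a flat test surface,
with a K-S distance energy evaluated on fixed draws (deterministic
objective, averaged over three draws to avoid fitting a single draw's
noise) and a Nelder–Mead polish. On spines the two cluster types descend
from shared primary seeds (colocalized); on the shaft their primaries are
independent (segregated), mirroring the compartment-dependent pattern
seen with replica immunolabeling.

**Calibrated defaults and reduced scale.** None of the cascade's rate
constants or surface densities is experimentally pinned down at this resolution; the
shipped defaults are literature-scale values calibrated once so that, at
the default reduced geometry (a 6 µm dendrite with six spines in a 6 µm
box, 3,000 molecules per release), a single release activates ~5–6
GABA~B~ receptors and ~4 GIRK channels with a free-GABA decay of
~11.5 ms, and they are flagged as calibrated, not measured. The tests
run this reduced scale: a 2-release train opens close to twice the
single-release channel count (the mean deviation across seeds is within
±15%), and colocalized spine layouts outperform segregated shaft layouts
in per-receptor effectiveness in the large majority of seeds. The
reduced-scale channel densities for the linearity experiment are chosen
so the per-release opening fraction of reachable channels stays low, as
in the full-scale tissue — at much smaller channel counts the
distinct-channel metric saturates and the deviation becomes strongly
negative for purely combinatorial reasons. These synthetic results
demonstrate the mechanisms (supply-limited G&beta;&gamma; production,
cooperative gating, compartment-dependent coupling), not the exact
published numbers, which depend on an electron-microscopic membrane
reconstruction and unpublished density tables.

## Reproducibility plumbing

Every stochastic function takes an explicit integer seed; there is no
hidden global RNG state (seeds are applied in a scoped way and the
caller's RNG state is restored). `run_stage()` executes named pipeline
stages from validated configurations (lists or YAML), writes artifacts
plus a manifest with parameter values, seed, package version and MD5
checksums, and rejects unknown configuration keys. Problem sizes in the
test suite (tens of cells, 10^4 walkers, 30-seed simulator ensembles,
20 BQA replicates) are the package's chosen reduced scales for these
experiments; all of them are documented at the call sites.

## Known limitations

* The arbors are stochastic-geometry stand-ins calibrated at the Sholl
  level; they do not reproduce layer-specific arborization anisotropy.
* The simulator's membrane parameterization flattens spines onto the
  shaft surface for the purpose of 3D GABA binding, and receptor cluster
  compartment labels are assigned at placement.
* The sink-based GABA clearance has no spatial structure, so
  concentration gradients at late times are milder than with explicit
  transporters.
* Recovery of Nfrs from ~33 trials per condition is diffuse by nature;
  point estimates should always be read together with the credible
  intervals from `tidy()`.
* No short-term synaptic depression is modeled anywhere; release amounts
  are constant across a train by design.
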