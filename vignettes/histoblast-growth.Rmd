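---
title: "Models and methods: histoblast growth, arrest and tissue mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: histoblast growth, arrest and tissue mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histogrowth)
```

This vignette is the package's own account of the quantitative machinery it
implements: the statistical conventions used on tracked-cell lineages, the
stochastic growth model and its defaults, the elastic-foundation continuum
model and its discretization, and the synthetic-data generators that make
everything testable without imaging data. Wherever a methodological choice
was genuinely open, the choice made here and its rationale are stated.

## The biological setting

Histoblasts are nests of progenitor cells that build the adult *Drosophila*
abdominal epidermis during pupal development (times are in hours after
puparium formation, hAPF). Their proliferation has four phases: fast
*cleavage* divisions without tissue growth; a *pause* while the tissue's
basal extracellular matrix is remodelled; an *expansion* phase of
growth-coupled divisions; and a rapid, stochastic transition of newborn
cells to proliferative (G0/G1) *arrest* that terminates growth. Two
signatures make this system quantitatively distinctive: the division rate
oscillates during expansion because cycle times are narrowly distributed
and the pause releases the population synchronously, and growth ends by a
sharp rise in the arrest probability rather than by cycle-time lengthening.

## Lineage statistics

**Containers.** A `lineage_forest` holds one row per tracked cell
(`cell_id`, `parent_id`, `birth_time`, `end_time`, fate `divided` /
`extruded` / `censored`, SOP flag) plus optional long-format per-frame
areas (μm²) and centroids (μm). Validation enforces the forest invariants
(binary divisions, daughter births at the mother's end time, acyclic
parent links) and names the first offending cell.

**Cycle times.** `cycle_times()` returns `end_time - birth_time` for
divided, non-SOP cells only. `cycle_time_summary()` uses the sample (n−1)
standard deviation; per-movie sample sizes are small enough that the
population estimator would bias the CV noticeably.

**Per-capita division rate.** At grid time *t*, the rate is the number of
divisions in the top-hat window `[t − w/2, t + w/2)` divided by
`w · N̄(t)`. The published convention says only "relative to total cell
number", which leaves the denominator open; the default here is the
*time-averaged* alive-cell count over the same window, which makes the
windowed event count and the population measure commensurate and gives the
exact identity that tiling windows integrate back to the total division
count. `denominator = "instantaneous"` switches to `N(t)`. The default
window is 0.875 h on a 0.125 h grid.

**Spectra.** `division_rate_spectrum()` takes the DFT of the rate before
`t_max` (default 28.5 hAPF) and normalizes by the zero-frequency value. No
zero padding is applied by default: the rate has a large mean, and the
rectangular-window leakage of that DC component vanishes exactly at the
DFT bin frequencies, whereas padding interpolates the spectrum and raises
DC sidelobes that can mask the ~0.25 h⁻¹ oscillation peak.
`dominant_frequency()` returns the largest strictly-positive-frequency
local maximum, which by construction excludes the monotone DC lobe.

**Peak counting.** `count_peaks()` uses topographic prominence (each
peak's height above the higher of its two bounding valleys, valleys
delimited by higher terrain or the ends of the trace). Prominences are
computed on the *full* series supplied and peaks are then selected inside
the requested window: a window-truncated prominence would misjudge a peak
whose valley lies just outside the window, as happens for the third
oscillation peak near 27.5 hAPF when counting in 16–28 hAPF. Supply a
series extending a few hours past the window.

**Growth decomposition.** Writing total apical area `A = N · ā`, each
frame interval's `Δln A` is split exactly as
`ln((N+d)/N) + ln(N'/(N+d)) + Δln ā` — the division, extrusion (negative)
and mean-cell-area contributions — and accumulated. The split is an
algebraic identity, so closure holds to floating-point accuracy on any
exact-area forest; it is the isotropic part of tissue deformation only
(no shear/rearrangement accounting). Censored cells count as present on
their final frame.

**Pair correlations.** Mother–daughter pairing emits one pair per
(mother, daughter) combination; sister pairing emits one pair per sibling
couple with the within-pair order randomized under the supplied seed,
because the Pearson coefficient of unordered pairs depends on how they are
laid out. Only divided cells enter. `birth_window` restricts both members'
birth times, which matters when pooling phases with different mean cycle
times: a slowly varying mean induces spurious positive correlation across
pooled pairs.

**Arrest.** A cell is *arrested* when it is censored at `movie_end`
without dividing, is not an SOP and was not extruded. Cells censored
within one cycle time of the movie end are still labelled arrested — the
plain movie-end definition — and a `min_followup` option excludes them
when a conservative estimate is wanted (default off).
`arrest_probabilities()` bins divisions into left-closed 1 h bins anchored
at integer hAPF and estimates `p̂` (≥1 arrested daughter) and `α̂` (2
arrested | ≥1). Hill curves `plateau · tⁿ/(t_halfⁿ + tⁿ)` with plateau
bounded in [0, 1] are fitted by least squares weighted by per-bin counts
(binomial weighting); the Hill form is evaluated as
`plateau / (1 + (t_half/t)ⁿ)` so exponents of 40+ do not overflow. Fit
failure is reported as a flag alongside the empirical curves, never as an
exception.

## The growth simulator

`simulate_growth()` is an event-driven simulation of a well-mixed cell
population; there is deliberately no spatial or mechanical coupling, since
cycle times show no dependence on cell geometry or position in this
system.

**Cycle-time law.** Sister cells draw their cycle times *at birth* from a
bivariate normal with identical marginals `N(m(t_birth), (cv·m)²)` and
correlation ρ. Indexing the distribution by birth time (rather than
re-evaluating it during the cell's life) is the simplest reading of
"take a cycle time at birth" and keeps draws independent across
generations. Three phases:

- cleavage (birth < 3.3 hAPF): mean 2.7 h, CV 0.10 — cleavage-type
  divisions are highly regular, so a tight CV is the realistic choice;
- bridge (3.3 ≤ birth < 14.7 hAPF): mean pinned to the expansion curve's
  starting value at 15 hAPF, CV 0.22;
- expansion (birth ≥ 14.7 hAPF): mean given by a cubic polynomial of
  birth time centred at 22 hAPF, CV 0.22, sister correlation 0.55.

**The expansion cubic.** The default coefficients
`c(4.42, -0.0703, 0.0017, 0.0032)` (powers of `t − 22`) were calibrated
once, then frozen, against the study's anchor statistics: a pooled
expansion-phase mean cycle time of ~4.5 h with CV 0.22 and a shallow
minimum near 22 hAPF; roughly three cleavage-phase doublings by 10 hAPF
(which pins the curve's 15 hAPF value near 3.9 h through the bridge rule);
and a ~4 h division-rate oscillation with three prominent peaks before
28 hAPF. With these defaults the simulated statistics come out at 4.39 h,
CV 0.220, 2.8 doublings, peak mode 3 and spectral peak 0.24 h⁻¹.

**Pause semantics.** Divisions due inside `[12.5, 14.7)` hAPF are deferred
to 14.7 hAPF: cells keep ageing during the pause and all overdue cells
divide together on release, producing the division burst just after
15 hAPF that seeds the oscillation. The alternative — freezing each cell's
cycle clock — was rejected because paused cells demonstrably still age.

**Arrest and SOPs.** At a division at time *t*, with probability `p(t)` at
least one daughter is arrested; conditionally with probability `α(t)` both
are, otherwise the arrested side is chosen uniformly. Defaults use Hill
curves with `t_half = 26` hAPF and exponent 40 for both, which rise from
≈0 at 24 hAPF to ≈1 at 28 hAPF — an exponent near 12 would already put
p ≈ 0.23 at 23.5 hAPF and only 0.71 at 28, too gradual for the observed
switch. Non-arrested newborns inside the SOP window (16–22 hAPF) become
SOPs with probability 0.02; both values are fixture-level choices exposed
in the configuration, set so the final SOP fraction is a few per cent.
Arrested cells and SOPs persist without dividing.

**Numerics.** Founders draw independent cycle times from the law at
`t_start` (they share no mother). Sister pairs with either component below
`min_cycle = 0.5` h are redrawn jointly, which preserves the correlation
while excluding non-positive cycle times (at the default CV this touches
~4σ tails and is statistically invisible). A single seeded generator with
a deterministic event order (ties broken by cell id) makes identical seed
and configuration produce bitwise-identical forests.

## Laser-ablation analytics

Excised-disc outlines are fitted with the numerically stable direct
least-squares conic fit constrained to an ellipse; this is robust to
outline noise, whereas the minimum-area enclosing ellipse (available as
`method = "enclosing"`, Khachiyan iteration) is governed by extreme
points. The fitted shape tensor `S = R·diag(a², b²)·Rᵀ` (eigenvalues =
squared semi-axes, μm²) is rotated to the lab frame, and full axis lengths
(diameters) along the AP (x) and DV (y) axes are read off its diagonal —
diameters, because the experimental annulus geometry is specified as
diameters (inner 45.54 μm, outer 57.96 μm). The normalized off-diagonal is
reported as a shear component, expected near zero.

Hencky (true) strain `ε = ln(L/L_r)` compares the non-ablated to the
relaxed axis length; it is additive along a deformation path and
antisymmetric in its arguments, which the tests exercise directly. Recoil
velocities are signed finite differences between successive frames (a
relaxing stretched disc gives negative values; a `speed` column carries
magnitudes, since published recoil values are magnitudes). The relaxation
time is `1/|slope|` of the OLS line of velocity against *mid-frame* length
— velocity is an interval quantity, and the mid-frame regressor makes the
discrete estimator second-order accurate: for an exact exponential with
τ = 30 s sampled every 5 s it returns 30.07 s, converging to τ as the
frame interval shrinks. Below a slope tolerance the relaxation time is
reported as `NA` rather than a spurious huge number. For single-junction
recoil both a first-interval estimator (default) and an exponential-fit
initial slope `(d∞ − d0)/τ` are provided; the underlying vertex-tracking
methodology admits either reading, so both are exposed and the fit falls
back to the first interval with a warning if it diverges.

## The continuum model

**Model.** The excised disc is 2D linear elastic with stress
`σ = K̄ (tr ε) I + 2μ̄ ε_dev + diag(ζx, ζy)`, tethered to the substrate by
elastic links: mechanical equilibrium reads `∇·σ = k u` in the disc and
`σ·n = 0` on the rim (the ablation frees the boundary, so the elastic
traction balances the released active tension). Lengths are normalized by
the disc radius R and stresses by K̄; the free parameters are
`k̂ = kR²/K̄`, `ζ̂x`, `ζ̂y`, with `μ̂ = μ̄/K̄` fixed at 1 by default (fitting
it is exposed but off). This nondimensionalization is self-consistent, but
the normalization of published parameter axes may differ by a fixed
factor; fitted *ratios and orderings* across conditions are the
comparable quantities. The model fits the total elastostatic relaxation
(deformation measured minutes after ablation), not the viscous transient,
which is handled empirically by the recoil analytics.

**Discretization.** Linear-triangle finite elements on a structured polar
mesh (default 32 radial rings, 64 angular sectors; ~2,000 nodes). The
foundation term uses a lumped mass matrix; the uniform active stress
enters as the volume load `−∫ σ_a : ε(v) dA`. At `k̂ = 0` the operator has
rigid-body null modes, so the exact uniform-strain free-disc solution
(`tr ε = −ζ_iso/K̄`, `ε_xx − ε_yy = −ζ_dev/μ̄`) is returned instead.
The solver is gated against an independently derived closed form: for
isotropic tension the axisymmetric equilibrium reduces to the modified
Bessel equation of order one, `u_r = A·I₁(λr)` with `λ = √(k/(K̄+μ̄))` and
A fixed by the rim traction; agreement is required below 0.5% relative L2
error and measures ≤0.2% at the default resolution across `k̂` from 0.5
to 20. Strains are element-wise constant; fields are sampled at element
centroids, and arbitrary points take the nearest centroid's values.

**Observables and fitting.** Deformation fields are summarized as radial
profiles: angular averaging cleanly separates the components, because the
isotropic response contributes the mean relative area change per radius
while the deviatoric (cos 2θ) response contributes the mean of
`ε_xx − ε_yy` and cancels from the area profile. The rim ("ring")
displacement — the model's mean radial boundary displacement — anchors the
overall scale. `fit_continuum()` minimizes the stacked residual of the
three blocks, each normalized by the empirical spread of its observed
values (the blocks have heterogeneous units). Because the forward model is
linear in `(ζx, ζy)`, the tensions are profiled out by linear least
squares at each candidate `k̂`; `k̂` itself is found by a coarse
logarithmic grid (10⁻² to 10²) refined by one-dimensional optimization,
with forward solutions cached per `k̂`. When the objective is nearly flat
in `k̂` (uniform deformation makes the foundation unidentifiable), the fit
is flagged `k_flat` rather than failing. Percentile bootstrap over sample
points gives confidence intervals on request. Round trips on noiseless
synthetic fields recover parameters to well under 1%; at 10%
multiplicative noise on 200 points, within 15%.

`edge_localization_index()` — mean |area change| in the outer quarter
annulus over the inner half-radius disc — quantifies the stiff-foundation
signature (contraction confined to the rim); it equals 1 for homogeneous
fields and grows monotonically with `k̂`.

## Intensity quantification

Junction orientation is axial and measured from the DV axis, folded into
[0°, 90°]; intensities are binned every 5° and summarized by median and
IQR with linear-interpolation quantiles. Pre-pupal ECM series are divided
by their value at 13 hAPF (first post-head-eversion time point). The
pupal ECM normalization sentence in the source protocol is ambiguous
("subtracted and normalized to the mean value of the five frames with the
lowest mean intensity under the LECs"); it is resolved here as: subtract
the background B (mean of the five lowest LEC frames) from both series,
then scale both by the initial LEC value so that series starts at 1 and
bottoms out near 0. The alternative reading (divide the subtracted series
by B) sits behind `method = "divide"`. All normalizations are invariant
under a global gain change, and the pre-pupal one is idempotent.

FUCCI phase calling normalizes each nucleus by the per-frame mean over all
nuclei per channel and thresholds the ratio r = RFP/GFP: `r < 0.5` → G1,
`r > 2` → S, otherwise G2/M. The thresholds are configuration-exposed
defaults calibrated on synthetic mixtures (the original threshold values
are not recoverable from the source text). One caveat follows directly
from the mean normalization: in a (hypothetical) single-class population
the normalization cancels the class signature (r ≈ 1 for every nucleus),
so phase calling is only meaningful for mixed populations — which real
frames are.

## Synthetic data: what it does and does not emulate

The generators produce every input format the analyses consume, with the
statistical structure the analyses assume, and always retain the ground
truth (generator parameters, class labels) for recovery tests:

- `gen_forest()` adds geometry to simulated forests. The area model is a
  bookkeeping fixture: daughters start with exactly half the mother's
  final area and relax exponentially (timescale 2 h) toward a 20 μm² set
  point, so division-time area conservation is exact by construction.
  Centroids place founders on a jittered hexagonal packing and daughters
  beside their mothers. None of this models mechanics.
- `gen_deformation()` samples the forward continuum solution at element
  centroids and perturbs observables with additive or multiplicative
  Gaussian noise.
- `gen_fucci()` draws class-conditional log-normal channel intensities,
  8-fold separated in the median with `sdlog = 0.15`, so classes are
  cleanly separated on the ratio scale and recovery is limited by
  composition, not channel overlap. Class counts are deterministic
  (rounded fractions), so recovered fractions differ from the preset only
  through classification error.
- `gen_ablation_series()` is the Kelvin–Voigt exponential
  `L(t) = L∞ + (L0 − L∞)e^{−t/τ}` plus optional noise;
  `gen_junctions()` draws uniform axial angles with an angular intensity
  profile.

What passing tests on these fixtures **does** show: the estimators recover
the generating parameters of their own models at realistic sizes and noise
levels, the algebraic identities hold exactly, and the full pipeline is
internally consistent (simulator → lineage statistics → fitted schedules
is a closed loop). What they **cannot** show: robustness to segmentation
and tracking errors, to spatially structured biological variability
(boundary effects, mechanical coupling, T1 rearrangements — all outside
the model class), or that the continuum model's constitutive assumptions
are the right description of real tissue.

## Problem sizes and reproducibility

The test suite and the acceptance script run base-case simulations with 16
founders to 33 hAPF (~6,000 cells each) across 20 seeds, 10,000-pair
correlation draws, 500-nucleus FUCCI populations, 200-point deformation
fields at the default 32-ring mesh, and 100 randomized forests for the
decomposition-closure property — sizes chosen so the full run completes in
a few minutes on one CPU while keeping Monte-Carlo error well inside the
assertion tolerances. Every stochastic step takes an explicit seed, and
identical seeds reproduce results bitwise.

## Known limitations

- The simulator is non-spatial; SOP probability/window and the FUCCI ratio
  thresholds are calibrated fixtures, not measured values, and are exposed
  in the configuration.
- The continuum constitutive law is the standard linear isotropic choice
  with additive uniform active pre-stress; the model normalization may
  differ from other parameterizations by a fixed factor.
- The growth decomposition is isotropic only; anisotropic (tensorial)
  shear decomposition is out of scope.
- The division-rate denominator convention and the pupal-ECM normalization
  arithmetic are documented choices among defensible readings, with the
  alternatives exposed as options.
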