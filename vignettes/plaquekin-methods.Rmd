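---
title: "Models and methods behind plaquekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plaquekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquekin)
```

plaquekin bundles three quantitative procedures used around amyloid-β
pathology — aggregation kinetics, plaque zonation, and expression
quantification — together with seeded generators that produce synthetic
data with known ground truth. This vignette explains the models, the
defaults and why they were chosen, the numerical choices, and what the
synthetic data do and do not establish about real measurements.

## 1. Aggregation kinetics

### The model

Unseeded amyloid formation is described by the moment equations of
filamentous growth. With monomer concentration $m(t) = m_0 - M(t)$, fibril
number $P(t)$ and fibril mass $M(t)$:

$$\frac{dP}{dt} = k_n m^{n_c} + k_2 m^{n_2} M, \qquad
  \frac{dM}{dt} = 2 k_+ m P,$$

where $k_n, n_c$ govern primary nucleation from monomers, $k_2, n_2$
secondary nucleation on the fibril surface, and $k_+$ elongation (the
factor 2 counts both fibril ends). The sigmoidal mass fraction
$M(t)/M(\infty)$ admits the standard closed-form fixed-point solution in
terms of the two combined rates

$$\lambda = \sqrt{2 k_+ k_n m_0^{n_c}}, \qquad
  \kappa = \sqrt{2 k_+ k_2 m_0^{n_2+1}}.$$

`closed_form_mass_fraction()` implements that solution;
`moment_ode_oracle()` integrates the moment equations numerically
(deSolve, `lsoda`) and serves as the independent check. The closed form is
an analytical approximation: against the oracle its relative RMS error is
typically 0.1–0.9 % in the secondary-dominated regime
($\kappa/\lambda \ge 10$), which is where unseeded Aβ42 kinetics live. The
test suite asserts the sub-1 % agreement over randomized parameter sets.

Two numerical details matter. $B_- = (k_\infty - \bar k_\infty)/(2\kappa)$
is evaluated in rationalized form to avoid catastrophic cancellation when
$\kappa \gg \lambda$, and the time dependence is expressed through
$e^{-\kappa t}$ rather than $e^{+\kappa t}$ so late times cannot overflow.

### Normalization and half-times

Raw ThT fluorescence is mapped to $[0,1]$ by
$(I - \text{baseline})/(\text{plateau} - \text{baseline})$ with the
baseline estimated from the first 5 reads and the plateau from the last 5
(`normalize_trace()`). Small windows are robust for completed sigmoids;
both are arguments. The half-time (`half_time()`, reported in hours) is
the first upward 0.5-crossing with linear interpolation — by construction
invariant under any positive-gain affine transform of the raw signal. A
dye-only blank can optionally be subtracted first (`subtract_blank()`,
off by default).

### Global fitting

Only $\lambda$ and $\kappa$ are identifiable from unseeded data (any
$(k_n, k_2, k_+)$ with the same products fits identically), so
`fit_secondary_nucleation()` fixes $m_0$, $n_c$ and $n_2$ and fits exactly
those two parameters jointly to all replicates by least squares. Defaults
$n_c = n_2 = 2$ are the conventional choice for Aβ42; both are
overridable. Optimization is multi-start: 25 starting points drawn
log-uniformly over $[10^{-8}, 10^{-1}]\,\mathrm{s^{-1}}$ from a seeded
stream, each refined by bounded quasi-Newton (`optim`, L-BFGS-B) on the
log10 scale. This is a deterministic counterpart of stochastic
basin-hopping global optimization: given the seed, the fit is
bit-reproducible, which the tests assert. The identifiable products
$k_n k_+$ and $k_2 k_+$ are reported alongside $\lambda, \kappa$.

The trace generator (`simulate_tht_plate()`) emulates the assay the
kinetics module targets: 5 µM monomer, reads every 400 s, triplicates,
baseline 100 a.u., amplitude 900 a.u., Gaussian noise with SD 1 % of the
amplitude. Inhibitory conditions are modelled as multipliers on $k_2$
(optionally also $k_n$) — the mode of action attributed to
aggregation-delaying proteins. `params_for_half_time()` inverts the model
so conditions can be specified by their half-time; it exploits the fact
that at a fixed $\kappa/\lambda$ ratio the solution's time axis scales as
$1/\kappa$. The default ratio $\kappa/\lambda = 50$ keeps the kinetics
secondary-dominated.

## 2. Plaque zonation

### Detection and profiling

`detect_plaques()` is Gaussian smoothing (σ = 2 px), a global Otsu
threshold, and connected components (EBImage), with two exclusion rules:
components below a minimum equivalent diameter, and components touching
the image border (their diameter profiles are incomplete). Detection is
deliberately plain — the scientific content of this module is the
zonation, not the segmentation.

`diameter_profile()` samples the plaque channel by bilinear interpolation
along evenly rotated lines through the intensity-weighted centroid and
averages them per position, the "plot profile across the diameter"
quantification.

### The border/center fraction and the zone rule

`derive_zone_threshold()` estimates, per profile, the center level (mean
of the central 20 % of positions) and the border level (mean of the outer
plateau, located past the steepest drop of a 3-point-smoothed radial
profile, skipping one position to clear the ramp and trimming the outer
10 % to avoid the fade into background). The across-profile mean of
border/center is the empirical zone fraction — about 0.60 for zinc-stained
plaque cores with their characteristic steep drop. Profiles without a
detectable drop (relative drop < 10 %) are excluded with a warning; ties
in the steepest-gradient search break toward the centroid.

`partition_zones()` applies the fraction per plaque: the reference is the
mean plaque-channel intensity over the central 20 % of the region, and the
cut is applied to background-corrected intensities,

$$\text{center} = \{\,x : I(x) - F \ge f \cdot (I_\text{ref} - F)\,\},$$

where $F$ is the detection floor (median intensity outside the region)
and $f$ the threshold fraction. Background correction makes the rule
invariant under offset as well as gain changes of the channel — without
it, an additive camera offset silently shifts the effective fraction.
Pixels at or below the floor belong to neither zone, which prevents
background from inflating the border zone. The reference is per-plaque
rather than per-image; a global cut can be emulated by passing the same
precomputed fraction to every plaque, but per-plaque referencing is the
default because center brightness varies between deposits.

### Enrichment testing

`quantify_marker_zones()` reports mean marker intensity per zone and their
ratio (scale-invariant by construction). `zone_enrichment_test()` is a
two-sided t test of center vs border means across plaques, paired by
default since both zones are measured within the same plaque; an unpaired
mode exists. Plaques are pooled across animals by default; per-animal
aggregation can be performed on the record table before testing. A zero
variance of differences is an error, not a p value.

### What the image generator emulates — and a knife edge

`simulate_plaque_field()` builds radially structured deposits: an inner
plateau (fraction 0.6 of the outer radius), a 2-px linear ramp, a border
plateau at a configurable fraction of center intensity (default 0.6), and
a 2-px fade to background, over a uniform background (50 a.u.) with
Gaussian noise (SD 5 a.u.). Default radii are 18–30 px on a 512×512 field,
i.e. deposits roughly 40–60 µm across at ~1 µm/px. The marker channel is
flat over the plaque and ratio-fold higher over the true center zone, so
the generating center/border marker ratio is exact. Ground-truth masks are
defined by the zone rule itself applied to the noiseless profile — the
principled definition, since the zone boundary *is* the rule.

One degenerate configuration deserves a note: if the border plateau sits
*exactly* at the threshold fraction (both 0.6), every border pixel lies on
the cut and noise classifies them at random — no analysis can recover
masks from such a field, and the generator then defines the true boundary
at the ramp midpoint instead. Recovery studies therefore use fields whose
border plateau (e.g. 0.5) is strictly below the cut, while the 0.6
fraction itself is derived from profile data generated at the 0.6 study
condition. On such fields the pipeline recovers masks with Jaccard ≥ 0.9
and the marker ratio within a few percent.

Record-level simulation (`simulate_zone_records()`) drives the power and
calibration studies of the enrichment test: border means log-normal across
plaques (CV ≈ 20 %), independent log-normal measurement noise per zone
mean (CV ≈ 10 %) — plausible magnitudes for per-plaque mean intensities.
At 25 plaques and ratio 1.5 the paired test rejects at p < 0.01 in
essentially every run; under the null its rejection rate sits at the
nominal 5 %.

The generators do not attempt photorealism: no cell bodies, vessels,
autofluorescence, uneven illumination, or Poisson photon statistics
(noise is Gaussian throughout). Passing tests establish that the
*procedures* are correct and well-calibrated on data satisfying their
assumptions — not that segmentation would survive arbitrary real-tissue
artifacts.

## 3. Expression quantification

The qPCR conversion implements both readings of the published virtual-mRNA
formula: the *literal* arithmetic $10 \times (ct_t - ct_s)/\text{slope}$
exactly as printed (the default, honoring the source), and the
conventional *exponential* standard-curve back-calculation
$10^{(ct_t - ct_s)/\text{slope}}$. The literal form is dimensionally odd
and can go negative; the exponential form is the one the qPCR simulator
inverts exactly. The mode is always recorded in the output, and no attempt
is made to guess which was intended. Technical-replicate ct values are
averaged before conversion. Densitometry bands are normalized by division
with the matched reference band.

Group statistics follow classic practice: one-way ANOVA (`aov`) with all
pairwise t tests Bonferroni-adjusted (raw p × number of pairs, capped at
1), and equal-variance t tests by default (Welch available). The test
suite checks the ANOVA against a from-definitions sums-of-squares oracle
to 10⁻¹⁰ relative tolerance, and the identity $F = t^2$ for two groups.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated data at
modest sizes chosen to exercise every code path with comfortable
statistical margins: 20 parameter sets for the closed-form/ODE comparison,
triplicate traces at half-times 0.5–4 h, 10-plaque 512×512 fields, 50
diameter profiles, 100 alternative and 500 null runs for the enrichment
test's operating characteristics. Every generator takes a mandatory seed
and is a bit-exact function of (configuration, seed); the multi-start fit
is seeded likewise, so all simulate→analyze round trips are reproducible
to the bit, which is itself asserted in the tests.

## Known limitations

* The closed form covers the unseeded primary + secondary nucleation
  model only — no seeding, fragmentation, or saturating elongation; in a
  primary-dominated regime ($\kappa \lesssim \lambda$) its accuracy
  degrades and the ODE oracle should be preferred.
* Unseeded data identify only $\lambda$ and $\kappa$; individual rate
  constants require complementary (e.g. seeded) experiments.
* Zonation is strictly 2-D and single-plaque; overlapping deposits are
  merged by connected components and border-touching deposits are
  dropped.
* The literal virtual-mRNA formula is reproduced as printed; its output
  should not be interpreted as a fold change.
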