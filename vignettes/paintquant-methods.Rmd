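---
title: "Quantitative DNA-PAINT analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DNA-PAINT analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`paintquant` implements the quantitative analysis chain of DNA-PAINT
single-molecule localization microscopy — qPAINT molecular counting with
internal harmonic calibration, density-cluster size quantization,
localization-precision metrics (CRLB mode, NeNA, the 2.35-sigma
resolution rule), pair-distance and cross-section profiling, and RESI
super-localization averaging — together with a blinking-kinetics
simulator that generates localization tables from known ground truth so
that every stage can be validated by parameter recovery. This vignette
records the models, the estimator choices, and the reasoning behind the
decisions that were genuinely open.

# The forward model

## Binding kinetics

DNA-PAINT contrast comes from transient hybridization of a dye-labelled
imager strand to a docking strand on the target. Each docking site is
modelled as an alternating renewal process: exponentially distributed
dark dwells with mean `tau_dark = 1/(k_on * c)` (association rate
constant `k_on`, imager concentration `c`) alternate with exponentially
distributed bright dwells with mean `tau_bright`. The process starts in
the dark state; because the exponential is memoryless, the start-state
choice only affects the censored first interval. Simultaneous occupancy
of one docking strand by two imagers is excluded.

The kinetic constants are not measurable from a localization table
alone, so the generator's defaults place the simulation in the regime of
the quantitative experiments this package targets:
`tau_bright = 0.5 s`, `k_on = 2.2e6 /M/s`, `c = 1 nM`, giving
`tau_dark = 454.5 s` — i.e. a single-site qPAINT index of exactly
0.0022 per second. Structure-resolving experiments (origami, nuclear
pores) conventionally run at higher imager concentration; the analysis
scripts use 5–10 nM there, which shortens `tau_dark` proportionally and
is the only kinetics change they make.

## Localization emission

For every camera frame overlapping a bright interval, the collected
photons are Poisson with mean `mean_photons` times the fractional
overlap of the interval with the frame (linear proration — the simplest
physically sensible model; events shorter than a frame may fall below
the detection threshold). A detected frame yields one localization at
the true site position plus isotropic Gaussian error with
`sigma_loc = psf_sigma / sqrt(photons)`, the photon-limited precision,
which is recorded per axis exactly as a CRLB-style per-localization
precision would be. Fiducial sites are always bright at a 10-fold
photon budget, emulating gold nanoparticles.

Units and conventions, used consistently everywhere: coordinates in nm
with the origin at the field-of-view corner, x rightward along camera
columns and y downward along rows; frames are 0-based; camera pixels are
`pixel_size` nm (default 108); times in seconds; dark times in seconds;
qPAINT indices in 1/s.

## What the generator does and does not emulate

It emulates: sparse transient binding with concentration-set dark times;
photon-limited localization error with per-localization precision;
partial-frame photon loss; the benchmark geometries (three-pair origami
with 10/17/10 nm separations over a 53 nm extent, 6 nm pairs, eightfold
rings of 12 nm pairs, ~300 nm vesicles with tens of molecules plus
isolated calibration sites); acquisitions of 15,000–18,000 frames at
300 ms; drift and fiducials.

It does not emulate: 3D point-spread functions or any optics of the
acquisition hardware, photobleaching or depletion of docking strands,
nonspecific binding backgrounds, or camera artefacts beyond Poisson
noise. Passing recovery tests therefore demonstrates the correctness of
the estimators under the stated stochastic model, not robustness to
every nuisance in real data.

# Estimators

## Density clustering and cluster geometry

Clustering uses DBSCAN semantics: a point with at least `min_pts`
neighbours (itself included) within `eps` is a core point; clusters are
the connected components of the core-point graph; a non-core point with
a core neighbour is a border point, deterministically assigned to the
cluster of its lowest-index core neighbour; the rest is noise
(label 0). The implementation uses an eps-sized grid cell list, and the
test suite verifies it against an independent brute-force implementation
built on the full distance matrix and graph components. Defaults follow
the two quantitative analyses: `eps = 10.8 nm, min_pts = 15` for
adhesion-foci sizing and `eps = 20 nm, min_pts = 10` for vesicle
analysis.

The cluster diameter (maximum intracluster distance) is computed on the
convex hull for large clusters, which is exactly the pairwise maximum.

## The harmonic multi-peak Gaussian

Both the foci-size histogram and the qPAINT calibration histogram are
fit with

    f(x) = a1 exp(-((x - b1)/c1)^2) + a2 exp(-((x - 2 b1)/c2)^2)
         + a3 exp(-((x - 3 b1)/c3)^2)

— up to three Gaussians whose centers are locked to integer multiples
of the first. The fit is Levenberg–Marquardt least squares of bin
counts at bin centers (Freedman–Diaconis bins by default, never fewer
bins than free parameters), with non-negative amplitudes.

This model has a structural identifiability trap: any density is equally
representable with the first center halved and the mass moved to the
higher components, and for noisy, skewed single peaks that
representation often has a *lower* residual. Three measures resolve it,
all deterministic:

* multi-start initialization of `b1` over the histogram mode, half the
  mode, and `median/3, median/2, median` of the values;
* candidate selection that prefers fits whose **first** component
  carries the dominant effective contribution (amplitudes weighted by
  their in-range support, so a component centered beyond the data cannot
  dominate nominally) with `b1` near the dominant histogram peak;
* a canonicalization pass that refits with `b1 -> j*b1` when component
  `j > 1` dominates and keeps the refit if it fits comparably.

The selection encodes one scientific assumption, true in both analyses
this statistic serves: **the minimal unit is the most populated class**
(single docking sites outnumber multi-site small clusters; minimal foci
outnumber their multiples). Data violating that assumption would need
the unconstrained best-residual fit, which remains reachable via
`b1_init`. Components whose center lies beyond the data range have
unidentified amplitudes and are reported as absent.

## Dark times and qPAINT

Dark times of a cluster are reconstructed from the pooled frame indices
of its localizations: bright periods are maximal runs of consecutive
frames with at least one localization, and each dark interval is the
frame gap between successive bright periods times the exposure.
Leading and trailing censored gaps are excluded, and the result depends
only on the sorted unique frame set.

Two mean-dark-time estimators are provided. `cdf_lsq` fits the
exponential CDF `1 - exp(-t/tau_d)` to the empirical normalized
cumulative distribution by least squares, using the Hazen plotting
position `(i - 0.5)/n` (the naive `i/n` pins the fit to F = 1 at the
largest observation and biases `tau_d` low). `mle_mean` is the
exponential maximum-likelihood estimate, the sample mean. On hundreds
of intervals the two agree to a few percent.

The per-cluster pipeline defaults to `mle_mean` with a minimum of two
complete dark intervals. This differs from the standalone `cdf_lsq`
default deliberately, for two measured reasons at the target operating
point (a single calibration site yields only ~11 complete dark
intervals in a 5,400 s acquisition): unweighted CDF least squares is
strongly biased at that sample size, and any high minimum-interval
requirement inside a fixed window preferentially discards clusters whose
dark times ran long, biasing the surviving indices upward by tens of
percent.

The qPAINT index is `xi = 1/tau_d`, proportional to the number of
docking strands because the pooled event rate of `N` identical
independent sites is `N` times the single-site rate. Calibration fits
the harmonic multi-peak Gaussian to the index histogram of small
clusters (diameter at most 55 nm) and takes `xi_1 = b1`; counts are
`N = xi / xi_1`, with an approximate standard error
`N / sqrt(n_intervals)`.

One filter was added to the calibration population beyond the diameter
cutoff: calibration clusters must be **isolated** (no other cluster
centroid within 500 nm, configurable). Dense assemblies shed small
boundary fragments under density clustering; these pass the diameter
cutoff while carrying arbitrary site multiplicities and flood the index
histogram into a featureless continuum. Genuine calibration sites —
isolated single molecules — satisfy the filter trivially, and the
simulator places them at least 1 µm apart for coherence.

When scoring recovery on simulated vesicles, counts are pooled per
ground-truth structure (`counts_by_structure`): qPAINT indices are
additive over docking sites, so a structure that clustering split into a
main cluster plus satellites is counted as the sum of its parts.

## Precision metrics

`sigma_SMLM` is the average of the per-axis modes of the
per-localization precision distributions. The mode is estimated as the
argmax bin center of a Freedman–Diaconis histogram, ties broken toward
the smaller value — "mode" needs an operational recipe and this one is
deterministic and testable.

NeNA collects, for every localization, the distance to its nearest
neighbour in the next frame (150 nm cap by default). Repeated
localizations of one molecule in adjacent frames produce a 2D
displacement with distance density
`p(d) = d/(2 sigma^2) exp(-d^2/(4 sigma^2))`; unrelated neighbours
contribute an approximately linear background `B*d`. Both components
are fit to the distance histogram and the correlated component's sigma
is returned; if most fitted mass sits in the background the estimate is
flagged unreliable. Degenerate noise-free input short-circuits to the
root-mean-square-based estimate.

Resolution is reported as `2.35 * sigma` (the FWHM rule). The function
takes sigma explicitly, since either the CRLB mode or the NeNA sigma can
meaningfully feed it.

## Spot fitting

The camera model per pixel is Poisson with mean
`N * DEx * DEy + b` where `DEx`, `DEy` are pixel-integrated marginals of
a symmetric Gaussian PSF. Candidates are local maxima of the
background-subtracted box sum above a photon threshold; each window
(odd side of about six PSF sigmas) is fit by minimizing the Poisson
negative log-likelihood over position, photons, background and PSF
width, and the per-axis precision is the Cramér–Rao lower bound of the
same model, computed from the Fisher information with the background
included (numerical derivatives of the pixel means). Non-convergent
fits are dropped and counted. The acceptance suite verifies that the
empirical scatter of fitted positions matches the mean reported CRLB
within 10% at 5,000 photons.

## Drift

Fiducial-based correction estimates per-frame drift as the mean
displacement of fiducial localizations relative to each fiducial's
time-average position, interpolates frames without fiducial
localizations, smooths with a centered moving average (default 100
frames) whose edge windows shrink symmetrically — an asymmetric edge
window lags a linear drift by up to half a window — and subtracts the
trajectory anchored to zero at frame 0. Drift is applied and corrected
in sample coordinates (nm), before any pixelation.

## Pair distances, cross sections, RESI

Pair distances project the localizations onto an axis (the first
principal axis by default, sign fixed toward positive x), histogram the
projection, and fit one and two Gaussians by least squares. The pair is
reported only if the two-Gaussian model wins a residual F-test at
`alpha = 0.05` *and* the fitted sum is genuinely bimodal (it must dip
between the means); otherwise a typed `paintquant_unresolved` condition
carries the single-mode sigma. Exactly-two-valued projections (the
noise-free limit) return their separation directly. Cross sections
select a rectangle around a segment, histogram the perpendicular
offsets, and reuse the same two-Gaussian machinery for wall-to-wall
distances.

RESI grouping reuses the density-clustering engine per imaging round;
each group of at least five localizations collapses to the
inverse-variance-weighted mean with
`sigma_resi = (sum sigma_i^-2)^(-1/2)` per axis — exactly
`sigma/sqrt(K)` for homoscedastic input, a ten-fold improvement at
K = 100.

# Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen to keep each stage's statistical power meaningful: the vesicle
benchmark uses 50 vesicles of 46 molecules plus 100 calibration sites
over 18,000 frames (~75,000 localizations, the largest single run);
index linearity uses 60 clusters per site-count; distance recovery uses
20 origami per design and 16 aligned nuclear-pore pairs; the spot
fitter and RESI scatter checks use 1,000 repeats/targets. Every
simulation takes an explicit integer seed and restores the RNG state
afterwards; identical configuration and seed reproduce bit-identical
tables. Fits use deterministic initialization throughout, so the
analysis half of the pipeline is seed-free.

A note on attainable calibration accuracy: at the benchmark conditions a
calibration site yields ~12 binding events, so a single dataset's
100-site calibration carries an irreducible ~5% standard error on the
unit index before any estimator bias; recovery within 10% is the
realistic expectation, not a deficiency of the harmonic fit.

# Known limitations

* The DBSCAN implementation targets ~10^5–10^6 localizations; it is
  pure R and not tuned for whole-cell fields beyond that.
* The calibration's dominant-first-peak assumption fails if single
  units are a minority of small clusters; `b1_init` overrides it.
* The NeNA background model is linear in distance, adequate below the
  150 nm cap but not for long-range clustering of unrelated molecules.
* The spot fitter handles isolated spots; overlapping emitters are not
  deconvolved (multi-emitter fitting is out of scope).
* File I/O covers the native nm-based CSV dialect and a Picasso-style
  pixel-unit CSV dialect; HDF5 containers are not read or written.
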