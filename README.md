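# paintquant

Quantitative analysis of DNA-PAINT single-molecule localization
microscopy data, with a ground-truth simulator for validation.

DNA-PAINT produces blinking by transient hybridization of dye-labelled
imager strands to docking strands on the target. Because the waiting
time between binding events (the dark time, τ_d) of a cluster of
localizations is exponential with rate proportional to the number of
docking strands present, counting molecules reduces to estimating
1/τ_d — the qPAINT index ξ — and dividing by the index ξ₁ of a single
docking site, calibrated internally from small isolated clusters whose
index histogram peaks at integer multiples of ξ₁. This package
implements that counting chain and the surrounding quantitative toolkit
used in high-resolution DNA-PAINT studies:

* **simulator** — DNA-origami docking-site designs (10/17/10 nm
  three-pair, 6 nm pair), nuclear-pore-like rings of eight 12 nm pairs,
  molecule-filled ~300 nm vesicles with isolated calibration sites;
  alternating-renewal blinking kinetics (exponential dark/bright dwells,
  dark time set by imager concentration via τ_dark = 1/(k_on·c));
  photon-limited localization emission; drift and fiducials; optional
  synthetic camera frames;
* **clustering** — deterministic DBSCAN with per-cluster geometry
  (centroid, diameter = maximum intracluster distance), and the
  harmonic multi-peak Gaussian
  `f(x) = a₁e^{-((x-b₁)/c₁)²} + a₂e^{-((x-2b₁)/c₂)²} + a₃e^{-((x-3b₁)/c₃)²}`
  whose first center b₁ is the minimal-unit size of a quantized
  histogram;
* **qPAINT** — dark-time reconstruction from frame gaps, exponential
  fits (empirical-CDF least squares and the exponential MLE), unit-index
  calibration on small isolated clusters (≤ 55 nm diameter), molecule
  counts as ξ/ξ₁;
* **precision** — σ_SMLM (mean of the per-axis modes of the
  per-localization CRLB precisions), NeNA nearest-neighbour precision,
  and the 2.35σ resolution rule;
* **structure metrics** — projected two-Gaussian pair distances with
  model selection, cross-section profiles (e.g. microtubule wall
  separations), and RESI super-localization: inverse-variance averaging
  of K grouped localizations to σ/√K precision;
* **spot fitting** — Poisson maximum-likelihood Gaussian fitting of
  camera frames with CRLB-derived per-axis precisions;
* **I/O** — self-describing nm-based CSV tables and a Picasso-style
  pixel-unit CSV dialect, Gaussian rendering, and a YAML-configured
  `run_pipeline()`.

## Worked example: counting molecules in vesicles

Simulate ten vesicles of 46 molecules each plus 60 isolated single-site
calibration structures, 18,000 frames at 300 ms with 1 nM imager
(single-site dark time 454.5 s, i.e. ξ₁ = 0.0022 s⁻¹), then run the
full counting pipeline:

```r
library(paintquant)

fov   <- c(20000, 20000)                     # nm
model <- make_vesicle_layout(10, 46, diameter = 300,
                             n_calibration_singles = 60,
                             fov = fov, seed = 7)
kin   <- kinetics_params()                   # 1 nM imager: tau_dark = 454.5 s
acq   <- acq_config(n_frames = 18000, exposure = 0.3, fov = fov)
sim   <- simulate_paint(model, kin, acq, seed = 8)

res <- qpaint_analyze(sim$locs, exposure = 0.3)  # DBSCAN eps 20 nm, minPts 10
print(res$calibration$fit)
#> Harmonic 3-peak Gaussian fit (n = 60 values)
#>   first center b1 = 0.002397 (peaks at 0.002397, 0.004794, 0.007191)
#>   amplitudes: 12.2, 0, 0
#>   ...

pv <- counts_by_structure(res, sim$truth$sites)
mean(pv$n_molecules); sd(pv$n_molecules)
#> [1] 41.2
#> [1] 1.2
```

The calibration histogram of the 60 isolated small clusters peaks at
b₁ = 0.0024 s⁻¹ — the fitted unit qPAINT index, within ~9% of the
generating 0.0022 s⁻¹ — and the per-vesicle counts (each vesicle's
clusters pooled, since ξ is additive over docking sites) average
41.2 ± 1.2 against a ground truth of 46. Larger benchmarks (50 vesicles,
100 calibration sites) recover both quantities more tightly; see
`analysis/05_qpaint_vesicle_counting.R`.

## Analysis scripts

The `analysis/` directory holds numbered, self-contained drivers that
reproduce the package's benchmark analyses end to end and write their
tables under `results/`:

1. `01_origami_pair_distances.R` — 6/10/17 nm origami pair recovery and
   σ_SMLM;
2. `02_npc_pairs_and_resi.R` — 12 nm nuclear-pore pair cross-sections
   and four-round RESI averaging;
3. `03_localization_precision.R` — σ_SMLM, NeNA, 2.35σ, and the spot
   fitter's CRLB consistency;
4. `04_foci_size_quantization.R` — DBSCAN foci diameters fit with the
   harmonic multi-peak Gaussian (minimal unit 230 nm);
5. `05_qpaint_vesicle_counting.R` — the full 50-vesicle counting
   benchmark.

Each runs in seconds to ~2 minutes with `Rscript analysis/<name>.R`.

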