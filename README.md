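# sptkit

Single-particle tracking (SPT/SMT) analysis for rod-shaped bacterial
cells, as an R package: diffusion-population fitting from displacement
distributions, confinement and dwell-time analysis, standardized-cell
occupancy and speed maps, fluorescence-based molecule counting, and a
ground-truthed simulator that validates every analysis end to end.

## Who this is for

Labs doing live-cell single-molecule microscopy of bacteria: you track
fluorescently tagged proteins (with any upstream tracker), segment cells
(with any segmentation tool that can emit outline polygons), and want
reproducible, scriptable answers to questions like *how many diffusive
states does my protein have, and how do their sizes change under
perturbation? Where in the cell does it pause? How long does it dwell?
How many copies are there per cell?*

## The models at the core

For 2-D Brownian motion the squared jump `u = r²` over a lag `τ` is
exponential with mean `4Dτ`, so a protein with `k` diffusive states has

    F(u) = Σᵢ fᵢ (1 − exp(−u / (4 Dᵢ τ + 4 σ²))),   Σᵢ fᵢ = 1

which `fit_sqd_mixture()` fits to the empirical CDF of pooled squared
displacements (up to three populations; `σ` is the localization error,
fitted optionally). The same physics as a zero-mean Gaussian mixture on
per-axis displacements is in `fit_gmm_displacements()`; BIC
(`select_model()`) picks `k`; `joint_fit_shared_D()` holds `D` fixed
across experimental conditions so treatment effects appear purely as
fraction shifts; `crossval_fit()` reports errors by a 70/30 split with
ten training folds. MSD tools (`ensemble_msd()`, `fit_msd_linear()`,
`fit_anomalous()`, `apparent_diffusion()`, `cluster_tamsd()`) cover the
ensemble slope, the localization-error intercept, the anomalous exponent
`MSD ∝ τ^α`, and per-track classification.

Spatial tools project localizations into a standardized 3 × 1 µm cell:
confinement detection (8 steps within 106 nm of a window centroid),
dwell-time scoring and 1–2-component exponential decay fits, occupancy
heat maps (50 nm bins) and binned speed maps (per-step apparent diffusion
`r²/4dt`, 100 nm bins). Molecule counting calibrates the intensity of a
single fluorophore from the bleached-down tail of a movie and divides the
bleaching-corrected initial cell fluorescence by it, with illumination
and autofluorescence corrections, dimer detection (a second intensity
population at ≈ 2 × I₁), and a +15% correction of counts ≥ 20, where
spot photometry systematically undercounts.

## Worked example

Simulate a two-population reference scenario (slow complex-bound fraction
`D₁ = 0.031 µm²/s`, mobile fraction `D₂ = 0.3 µm²/s`, 48.2% slow,
40 ms frames), then recover the populations:

```r
library(sptkit)

ts <- simulate_tracks(scenario_config("degradosome", n_tracks = 1200, seed = 2))
d  <- compute_displacements(ts, lag = 1)
fits <- lapply(1:3, function(k) fit_sqd_mixture(d, k = k))
best <- select_model(fits)
best
#> SQD mixture fit: k = 2 populations (n = 10834, tau = 0.04 s)
#>   D1 = 0.03185 +- 4.5e-05 um^2/s   f1 = 0.447 +- 0.00045
#>   D2 = 0.3062 +- 0.00035 um^2/s   f2 = 0.553 +- 0.00045
#>   sigma_loc = 0 um
#>   SSE = 0.01322, BIC = -58548.76
```

The fit recovers the ground-truth coefficients (`D = 0.031/0.3`) within
a few percent and the slow fraction within a few points of `f₁ = 0.482`
(about 1,200 tracks carry roughly as much fraction information as their
track count, not their displacement count, so per-dataset scatter of a
few points is expected; the CIs printed above understate this, which is
why cross-validation is the recommended error estimate). The BIC of the
two-population model beats `k = 1` and `k = 3`, so `select_model()`
returns it. Cross-validated errors and a condition contrast:

```r
cv <- crossval_fit(d, k = 2, seed = 1)        # 70/30 split, 10 folds
rif <- compute_displacements(simulate_tracks(
  scenario_config("degradosome_rif", n_tracks = 1200, seed = 3)))
joint_fit_shared_D(list(untreated = d, rif = rif), k = 2)
#> Shared-D fit: k = 2, conditions = 2
#>   D: 0.03177, 0.305 um^2/s
#>   untreated: f = 0.445, 0.555
#>   rif: f = 0.096, 0.904
ks_compare(d, rif)$stars
#> [1] "***"
```

The transcription-arrest condition (`f₁ = 0.0984` ground truth) is
recovered as a pure fraction shift at shared `D`, and the jump-distance
distributions differ at `p < 0.001`.

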