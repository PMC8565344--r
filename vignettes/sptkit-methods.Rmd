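---
title: "Models and methods in sptkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sptkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptkit)
```

`sptkit` analyses single-molecule tracking (SMT) experiments in rod-shaped
bacteria. This vignette explains the models behind each tool, the tunable
parameters and their defaults, what the built-in simulators emulate, and
the numerical choices and limitations a user should know about.

## Diffusion analysis from displacement distributions

For a molecule undergoing two-dimensional Brownian motion with diffusion
coefficient $D$, the displacement over a lag $\tau$ has per-axis variance
$2D\tau$, and the squared jump $u = r^2$ is exponentially distributed with
mean $4D\tau$. A mixture of $k$ diffusive states (e.g. complex-bound versus
freely diffusing enzymes) therefore has the squared-displacement CDF

$$F(u) \;=\; \sum_{i=1}^{k} f_i\left(1 - e^{-u/(4 D_i \tau + 4\sigma^2)}\right),
\qquad \sum_i f_i = 1,$$

where $\sigma$ is the localization error, which adds $2\sigma^2$ of variance
per axis. `fit_sqd_mixture()` fits this CDF to the empirical CDF of pooled
squared displacements by Levenberg–Marquardt nonlinear least squares. We fit
the CDF rather than a binned histogram because the fit is then independent
of any bin-width choice; a Freedman–Diaconis histogram remains available for
display. `fit_gmm_displacements()` fits the same physics as a zero-mean
Gaussian mixture on pooled per-axis displacements ($v_i = 2D_i\tau +
2\sigma^2$) by direct maximum likelihood; the two routes agreeing on common
data is itself a useful internal control, and a test asserts agreement
within 15% on a 10,000-step simulation.

Key choices:

* **Localization error.** By default `model_sigma = FALSE`, so the reported
  $D$ are *apparent* coefficients with the noise folded in, i.e.
  $D_\text{app} = D + \sigma^2/\tau$. This matters most for the slow
  fraction: with a 40&nbsp;ms frame interval and a typical 30–45&nbsp;nm
  localization error, a true $D_1 \approx 0.01\ \mu m^2/s$ can appear several
  times larger. The shared-$\sigma$ fit is exposed for users who want
  noise-corrected coefficients.
* **Lag convention.** Default lag 1, with overlapping displacement windows;
  overlapping pairs maximize sample size at the cost of within-track
  correlation.
* **Multi-start.** The optimizer is started from a deterministic grid of
  eight quantile-anchored scale combinations; the best sum of squares wins.
  Convergence tolerances are $10^{-12}$ on the relative SSE.
* **Model selection.** BIC is computed from the exponential-mixture
  log-likelihood of all pooled displacements, with $2k-1$ parameters
  ($+1$ when $\sigma$ is fitted): $\mathrm{BIC} = -2\log L + p\log n$.
  A least-squares "BIC" built from the CDF residuals would not be
  comparable across $k$, because neighbouring ECDF residuals are strongly
  correlated (they follow a Brownian bridge), which makes SSE differences
  between nested models look far more significant than they are; the
  likelihood form does not have this defect. Ties break toward smaller $k$.
* **Uncertainties.** Per-parameter 95% CIs come from the fit covariance via
  the delta method. Because displacements are treated as independent, these
  CIs understate the true error; `crossval_fit()` is the recommended error
  estimate: a random 70/30 train/test split, ten random folds of the
  training part, one fit per fold, and the reported error is the standard
  error of the fold mean plus the mean per-fold CI half-width. The held-out
  30% provides a generalization SSE for the fold-mean model.
* **Condition comparison.** `joint_fit_shared_D()` fits all conditions with
  one shared set of $D_i$ and per-condition fractions, so that a treatment
  effect is expressed purely as fraction shifts — the standard device for
  comparing occupancies between, say, exponentially growing and
  transcription-arrested cells. `ks_compare()` applies the two-sample
  Kolmogorov–Smirnov test to jump distances with the conventional
  0.001/0.01/0.05 star ladder.

MSD-based tools complement the mixture fits: `ensemble_msd()` pools
overlapping pairs per lag; `fit_msd_linear()` extracts $D$ from the slope
and the localization error from the intercept ($b = 4\sigma^2$, clamped at
zero with a warning when the fitted intercept is negative);
`fit_anomalous()` regresses $\log \mathrm{MSD}$ on $\log\tau$ and labels
$\alpha < 0.9$ subdiffusive, $0.9 \le \alpha \le 1.1$ Brownian, and
$\alpha > 1.1$ superdiffusive (the bands are configurable);
`apparent_diffusion()` fits each track's time-averaged MSD through the
origin over its first four lags; and `cluster_tamsd()` classifies tracks by
K-means on standardized log-TAMSD features at lags 1–4, with labels ordered
by ascending mobility and a fixed seed for reproducibility.

## Spatial analysis in the standardized cell

All population-level maps live in a standardized $3 \times 1\ \mu m$ cell,
the average size of an exponentially growing rod cell. The transform is
affine: the cell's area centroid goes to the origin, the principal axis of
the outline's second moments becomes horizontal, and the two axes are
rescaled independently to the standard length and width. The non-mirrored
transform is a bijection (and is tested as such); mirroring folds
coordinates into one quadrant and reflects the map for display, appropriate
when no cell polarity is expected.

* **Confinement** (`detect_confinement()`): a window of consecutive
  localizations is confined when every point lies within a radius of the
  window *centroid* — anchoring at the centroid avoids sensitivity to the
  window's first point, which is just another noisy localization. Maximal
  windows of at least 8 steps within 106&nbsp;nm (one camera pixel, about
  2.5 localization errors) are merged into segments; a track is `confined`
  if one segment covers it, `free` if none exists, `mixed` otherwise.
* **Dwell times** (`dwell_events()`, `fit_dwell()`): an event starts at an
  anchor localization and persists while the track stays within the radius
  of the anchor — the simplest exit rule, and the one least sensitive to
  where inside the zone the molecule wanders. The radius is either
  user-set or three times the localization error from the MSD intercept.
  Events shorter than 4 steps are discarded; events cut off by the track
  end are flagged censored and excluded from decay fitting by default
  (they are lower bounds, not durations) while still contributing to the
  sample mean. Survival curves are fitted with one or two exponential
  components after shifting the time origin to the shortest retained
  duration, which is how the minimum-step cutoff enters the model. The
  curve fit (log-survival residuals on a uniform time grid) supplies
  starting values that a maximum-likelihood refinement finishes: plain
  least squares on the survival curve gives the minority slow component
  almost no weight and can miss its time constant badly, while the
  likelihood is efficient for exactly that tail. BIC compares the
  component counts.
  Because molecules also photobleach, fitted dwell times underestimate true
  residence times, increasingly so at higher bleach rates — a property we
  assert in a test rather than hide.
* **Maps**: `heat_map()` is a normalized 2-D histogram (default 50&nbsp;nm
  bins); `binned_speed_map()` assigns each consecutive-frame step an
  apparent diffusion $r^2/(4\,dt)$ at the step *midpoint* (the least biased
  single choice for a quantity that belongs to the whole step) and averages
  per 100&nbsp;nm bin; empty bins are reported missing, never zero.
  Mirrored maps are exactly four-fold symmetric by construction, and an
  invariant test checks that the speed map's count-weighted mean equals the
  plain mean of all step estimates. Optional Gaussian smoothing is for
  display only. `distance_to_references()` summarizes localization
  distances to named presets (poles, midcell, membrane) or arbitrary
  reference points with median and IQR.

## Molecule counting from fluorescence movies

The counting pipeline estimates per-cell copy numbers in four corrections:

1. **Illumination**: temporal median of a cell-free movie, smoothed with a
   10-pixel Gaussian and normalized to mean 1; data frames are divided by
   this profile.
2. **Autofluorescence**: from a movie of cells expressing no fluorescent
   protein, the mean in-cell excess over the extracellular background per
   pixel (a difference model; the in/out ratio is also reported). The
   extracellular background itself is taken from the same no-fluorophore
   field: the data movie's own background pixels contain PSF spill from
   in-cell fluorophores and would bias the estimate upward with copy
   number.
3. **Unit intensity**: integrated intensities of single-molecule spots —
   3-pixel-radius discs at detected or tracked positions — collected from
   the movie tail where at most a few molecules remain unbleached (located
   by scanning detection counts backwards from the movie end). A Gaussian
   mixture on these intensities gives the monomer intensity $I_1$; with two
   components, a second population at $I_2/I_1 \in [1.7, 2.3]$ is flagged
   dimer-consistent. Samples may be pooled across movies of one
   acquisition before fitting, which is also how scarce tails (cells whose
   molecules all bleach early) are handled.
4. **Counts**: the cell's fluorophore-derived intensity at $t=0$ is the
   frame-0 value of an exponential decay fitted over the first 20 frames
   (guarding the estimate against noise in any single frame), divided by
   $I_1$.

Two photometry routes are provided. The default route integrates the union
of 3-pixel discs centred on the frame-0 spot positions, exactly the
quantity the unit-intensity calibration is built from. At low copy numbers
it is nearly exact — the discs travel with the spots and recover the PSF
tails that spill across the cell outline — and on noiseless,
non-overlapping test constellations the counts are exact up to $N = 10$
across seeds. At high copy numbers, spots merge and some are missed, so
flux is lost and the route *underestimates*; on the package's own synthetic
benchmark (below) the mean underestimation stabilizes around 15% from 20
molecules per cell upward, which is why raw counts at or above 20 are
corrected by +15% (`bias_threshold = 20`, `bias_factor = 0.15`). The
whole-cell alternative (`method = "intensity"`) sums the cell mask instead;
it is insensitive to crowding but permanently forfeits the boundary spill
(a few percent at this cell size), and it does not show the low-/high-
density transition. Counts remain underestimates in an absolute sense for
an additional reason the pipeline cannot correct: a fraction of fluorescent
proteins is never excitable; an optional user-supplied maturation factor is
the only remedy.

## The simulators: what they emulate, and what they do not

`simulate_tracks()` generates multi-state Brownian trajectories: uniform
starts in a $3 \times 1\ \mu m$ rod box, Gaussian steps with per-axis
variance $2D\,dt$, specular reflection at the wall, optional Markov state
switching with per-second rates, Gaussian localization noise, and
geometric (bleaching-limited) track lengths with the 5-step minimum
applied. An optional membrane shell of distinct $D$ supports two-zone
(slow periphery / fast interior) experiments. "Static" molecules are
modelled as slow Brownian states ($D \sim 0.02$–$0.09\ \mu m^2/s$, as
fitted coefficients of complex-bound enzymes suggest), not as zero-motion
points; hard confinement discs are emulated through the shell mechanism.

Two deliberate scenario choices deserve emphasis. First, the reference
("degradosome") scenarios simulate with `sigma_loc = 0`: their $D$ values
are *apparent* coefficients taken from fitted data, which already fold the
localization error in, so adding noise on top would double-count it.
Second, the parameter-recovery scenarios use a free (unreflected) boundary:
specular reflection in a 1-µm-wide cell depresses the one-lag MSD of a
$0.3\ \mu m^2/s$ population by roughly 10–16%, so confined simulations do
not satisfy the Rayleigh-mixture model that the fits (correctly, for real
pooled data spanning many cells and orientations) assume. The rod geometry
is used wherever space matters — maps, confinement, cell assignment. The
scenario bleaching probability is 0.1 per frame (mean ten-step tracks),
the realistic regime for continuously illuminated single-fluorophore
imaging. What the track simulator does not emulate: motion blur within a
frame, anisotropic localization error, non-Markov state memory, and 3-D
effects; conclusions that depend on those features cannot be validated
with it.

`simulate_movie()` renders fluorophores as pixel-integrated Gaussian PSFs
($\sigma = 1$ pixel at 106&nbsp;nm pixels) at static uniform positions
inside the cell, with single-step bleaching at a geometric frame, a flat or
vignetted illumination profile multiplied in, in-cell autofluorescence,
and camera noise modelled as Poisson photon noise with the EM-CCD excess
factor approximated by doubling the Poisson variance plus Gaussian read
noise. Defaults: $48 \times 48$ pixels, 500 photons per fluorophore per
frame, background 20 and autofluorescence 5 photons per pixel, read noise
2, bleaching probability 0.02 per frame, 600 frames. Static positions are
a simplification: totals and calibration are motion-invariant, but a
diffusing molecule's motion blur (not rendered) would slightly widen real
PSFs.

The counting benchmark ships as the package's acceptance computation
(`scripts/acceptance.R`): it renders movies at 20–100 molecules per cell
(ten seeds each), runs the full pipeline without the bias correction, and
reports the mean relative underestimation. Numbers quoted in this vignette
for that benchmark are the ones that script computes.

## Numerical choices and degenerate inputs

* Polygons are validated (≥ 3 distinct vertices, no self-intersection,
  non-zero area and width); degenerate cells raise errors rather than
  producing NaN maps.
* Mixture fractions are parameterized through logits (softmax) and
  diffusion coefficients through logs, so constraints hold exactly at any
  optimizer iterate; populations are reported in ascending-$D$ order.
* Map bin sizes must divide the standardized cell evenly with an even bin
  count per axis, so no bin straddles a mirror axis.
* All simulations are reproducible from a single integer seed; K-means and
  cross-validation take explicit seeds.
* Degenerate samples (all dwell durations equal, zero-variance intensity
  samples, fewer distinct trajectories than clusters) produce warnings and
  well-defined fallbacks instead of optimizer crashes.

## Known limitations

* SQD/GMM confidence intervals understate errors (within-track
  correlation); use cross-validation errors for reporting.
* Dwell times are biased low by photobleaching; between-condition
  contrasts are reliable, absolute values are lower bounds.
* Hidden-Markov state-transition inference and confined-diffusion MSD
  closed forms are out of scope; dedicated tools exist for both.
* The counting bias correction is calibrated on the synthetic benchmark's
  conditions (diffraction-limited PSF, moderate background); other optical
  regimes warrant re-running the benchmark with matched `movie_config()`
  settings before trusting the +15% figure.
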