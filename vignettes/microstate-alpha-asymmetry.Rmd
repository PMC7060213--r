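---
title: "Microstate-based frontal alpha asymmetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate-based frontal alpha asymmetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msasym)
```

## The problem

Resting frontal alpha asymmetry — the difference in log alpha-band (8–12 Hz)
power between homologous right and left frontal electrodes — is a classic
electrophysiological index of approach/withdrawal disposition and affect.
Its conventional estimate treats the whole resting recording as one
stationary signal. `msasym` implements an alternative that first reduces
the EEG to its *quasi-stable microstates* — brief periods (tens of
milliseconds) during which the scalp topography holds one of a few
prototype shapes — and computes the asymmetry from the recording
re-expressed through those prototypes. The package also carries the index
forward to hemodynamics: a TR-locked asymmetry regressor for
parametric-modulation models of simultaneously acquired BOLD data, blind
per-voxel estimation of the hemodynamic response function (HRF), a
hemodynamic lateralization index (HLI) for paired left/right regions, and
a robust-correlation battery linking all of these to behavioral scores.

## Models and procedures

### Microstate segmentation

Global field power at sample $t$ is the population standard deviation of
the average-referenced potential across the $C$ channels,
$\mathrm{GFP}(t) = \sqrt{\sum_i (X_i(t)-\bar X(t))^2 / C}$. Topography is
best defined at GFP maxima, so clustering operates on the maps at local
GFP peaks, thinned to a minimum spacing of 20 ms and kept only above 1 SD
of the GFP series (`select_gfp_peaks()`; both the multiplier and the
direction of the threshold are configurable because the 1-SD rule can be
read as an inclusion floor or an artifact ceiling — we default to the
floor reading, which selects prominent, high-SNR maps).

The modified K-means (`fit_modified_kmeans()`) clusters peak maps with
the polarity-invariant distance
$D^2_{kn} = x_n^\top x_n - (x_n^\top z_k)^2$ against unit-norm zero-mean
prototypes $z_k$, re-estimating each prototype as the sign-aligned
average of its assigned maps (an eigenvector update is available behind
`update = "eigen"`). Iteration stops when the relative change of
$\sum_n D^2$ falls below `tol` (default 1e-6, capped at 1000 iterations),
and the best of `n_restarts` seeded initializations is kept. Goodness of
fit uses the global explained variance
$\mathrm{GEV} = \sum_n (\mathrm{Corr}(x_n, z_{\tau_n})\,\mathrm{GFP}_n)^2
/ \sum_n \mathrm{GFP}_n^2$ and the residual-noise criterion
$\mathrm{CV} = \sigma^2 (C-1)/(C-K-1)$ with
$\sigma^2 = \sum_n (x_n^\top x_n - (x_n^\top z_{\tau_n})^2)/(N(C-1))$.
We implement the CV penalty in its linear form; the classic squared form
is available via `cv_squared_correction = TRUE`. `select_active_k()`
chooses the active microstate count by minimum CV over K = 2..8, since
the number of active classes is an empirical property of the data rather
than a fixed constant.

Back-fitting (`backfit()`) labels every sample with the prototype of
minimal global map dissimilarity
$\mathrm{GMD}_{kn} = \lVert x_n/\mathrm{GFP}_n - z_k/\mathrm{GFP}(z_k)
\rVert / \sqrt{C} \in [0, 2]$. The clustering distance is
polarity-invariant while the literal GMD is polarity-sensitive; for
internal consistency back-fitting defaults to the polarity-invariant
minimum over $\pm z_k$ and records the winning sign (the literal mode is
available with `polarity_invariant = FALSE`). Flat samples (zero GFP)
receive a sentinel label, are re-expressed as zero vectors and are
excluded from GEV and $\sigma^2$ sums. `reexpress()` rebuilds the
recording as $z_{\mu_n}\cdot\mathrm{GFP}_n\sqrt{C}$, which preserves each
sample's GFP exactly and discards within-state topographic fluctuation.
The re-expression defaults to GFP scaling: the alternative reading (raw
prototype amplitude) is available via `scale = "prototype"`, but GFP
scaling is what makes the re-expressed signal carry the field-strength
dynamics that the alpha-power estimate needs.

### Asymmetry indices

Both indices are $\ln(\alpha^{\mathrm{right}}) -
\ln(\alpha^{\mathrm{left}})$ for the mid-frontal pair F4/F3 (FA) and
lateral-frontal pair F8/F7 (FTA). The *standard* branch computes alpha
power on current-source-density (CSD) re-referenced data — a
spherical-spline surface Laplacian (order m = 4, 50 Legendre terms,
regularization 1e-5, the common CSD-toolbox defaults) — which suppresses
distant sources. The *microstate* branch computes it on the re-expressed,
average-referenced recording. Band power is a Hann-windowed Welch
estimate (2 s segments, 50 % overlap) integrated over 8–12 Hz. For the
TR-locked regressor, instantaneous alpha power is the squared Hilbert
envelope of the 8–12 Hz band-passed signal (Welch has no per-sample
meaning), reduced to one value per 2 s scan window by the median;
partial trailing windows are rejected rather than padded.

### EEG-informed fMRI, deconvolution and HLI

Resting acquisitions have no task events, so the parametric-modulation
design (`build_parametric_design()`) treats every scan as an event: a
base regressor of per-scan impulses convolved with the canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32 s support,
unit peak height), three columns in which the mean-centered asymmetry
series weights the same impulses convolved with the canonical HRF and its
temporal and dispersion derivatives, and an intercept. First-level
estimation is ordinary least squares with a partial F test over the three
modulated columns; the per-voxel amplitude summary is the signed
root-sum-of-squares of the three modulation betas (sign from the
canonical beta). Group inference is intercept-only IRLS with Tukey
bisquare weights (c = 4.685, via `MASS::rlm`), and maps are thresholded
by Benjamini–Hochberg FDR at q < 0.05 followed by removal of connected
components of 20 voxels or fewer (face adjacency by default). Voxels are
treated independently — no spatial autocorrelation model — which is a
stated desk-scale simplification.

Blind deconvolution (`deconvolve_hrf()`) standardizes a voxel series,
takes local maxima above 1 SD as pseudo-events, chooses the
peak-to-onset lag on a TR grid over 0–8 s by least squares, and fits the
three-basis HRF on the original scale with an intercept. Because the
canonical basis has unit peak, the fitted curve's peak height reads
directly as response height in BOLD units. The HLI of a paired region is
the median right-hemisphere amplitude minus the median left-hemisphere
amplitude, with flagged voxels (no pseudo-events) excluded.

### Robust correlations

`robust_correlate()` runs Pearson, Spearman, the 20 % percentile-bend
correlation (winsorized deviations around the percentile-bend location;
one-pass recipe, standard for beta = 0.2) and skipped correlations
(minimum-covariance-determinant center, per-point projection directions,
ideal-fourths boxplot rule; MCD with 0.75 subsample fraction and 500
seeded resamples). Each estimate carries a seeded percentile bootstrap
confidence interval at level $1 - \alpha/m$ and a Bonferroni-adjusted
p-value, with the family size m defaulting to the number of
(pair × score) tests requested in the run. For Pearson's r at the
standard 95% level the interval uses Wilcox's sample-size-adjusted
percentile cutoffs (the reference toolbox's default): the plain
symmetric percentile interval is known to undercover for r (we measure
~92–94% at n = 40, ρ = 0.5), and the adjusted order statistics restore
nominal coverage (~95.5% in the same simulation). For skipped methods the
outlier screen runs once on the original sample and the bootstrap
resamples the cleaned points — re-running the MCD inside every resample
is both unstable at small n and not what the reference toolbox does.
t statistics use $t = r\sqrt{(n-2)/(1-r^2)}$ on the retained sample size.

## The synthetic cohort: what it emulates and what it does not

`generate_microstate_eeg()` produces a 32-channel, 250 Hz recording whose
topography alternates among K quasi-stable prototypes (geometric segment
durations, mean 80 ms — the empirical microstate duration scale) while an
amplitude-modulated 10 Hz carrier drives global field power, plus white
sensor noise. The F4/F3 and F8/F7 prototype entries are pinned so the
clean signal's alpha-power log-ratios equal the planted values exactly
(the right channel of each pair is a signed multiple of its left partner,
making the two time courses proportional and the ratio carrier-independent).
`generate_bold_dataset()` plants left/right response heights on a sparse
common event train (mean spacing 24 s, so individual responses stay
resolvable) convolved with the unit-peak canonical HRF, plus AR(1) noise
(coefficient 0.3). `generate_behavioral_scores()` plants `target_rho` as
the *realized in-sample* correlation by projecting the noise component
orthogonal to the driver before mixing: recovery tests then measure the
pipeline's measurement error rather than the score-sampling noise, which
at cohort sizes of 20 would otherwise dominate everything downstream.
Optional gross outliers (±10 on the standardized scale) support
contamination studies.

What the generators deliberately omit: volume-conduction forward
modeling, gradient/cardioballistic/ocular artifacts, 1/f background
spectra, spatially correlated BOLD noise, and motion. Passing tests
therefore demonstrate algorithmic correctness and calibration under the
stated noise models, not robustness to real acquisition artifacts —
preprocessing is assumed done upstream.

Because each synthetic subject draws its own prototype set, the pipeline
defaults to fitting prototypes per subject before back-fitting
(`prototype_level = "subject"`); the two-level group scheme
(`"group"`) — one prototype set fit on the concatenated peak maps of the
whole cohort, then back-fitted per subject — is the right choice for real
cohorts whose microstate classes are shared, and is what the group
prototype set in the result bundle reports in either mode.

## Numerical choices and degenerate inputs

* K-means ties in the assignment step break toward the lowest cluster
  index; empty clusters are re-seeded on the worst-fit map.
* Convergence uses the relative residual change, with an absolute floor
  at machine precision times the total map energy so that exactly
  representable perfect fits terminate.
* CV is undefined (NA with a warning) when K ≥ C − 1.
* Zero-GFP samples: sentinel label, zero re-expression, excluded from all
  sums; `asymmetry_index()` refuses non-positive band powers by name.
* The spline system for CSD is solved with an explicit zero-sum
  constraint on the coefficients plus Tikhonov regularization `lambda`;
  below 8 electrodes a conditioning warning is raised.
* Bootstrap quantiles use type 6; all resampling is seeded through
  `derive_seed()`, one master seed per run.

## Problem sizes used by the shipped tests

The automated checks run at desk scale, chosen to finish in minutes while
leaving the measured quantities' Monte-Carlo error well below the bounds
they assert: microstate recovery uses 10 subjects × 12 s; CV selection 10
cohorts of 4 × 20 s; asymmetry recovery 30 s of clean signal; the
correlation battery 200–500 simulations (n = 40 for bootstrap coverage,
n = 1000–4000 for contamination-shift bounds, sized so sampling noise is
an order below the 0.1 bound); HLI recovery 100 runs of 205 scans; and
the end-to-end study 20 cohorts of 20 subjects × 120 s EEG with 60 scans
at TR 2 s. The end-to-end run correlates the planted association
(microstate FA vs negative affect) as a single-test family; a wider
battery at n = 20 subjects would have essentially no Bonferroni-corrected
power at ρ = 0.5, so significance there would measure the family size,
not the pipeline.

## Known limitations

* The microstate branch's subject asymmetry is only informative when
  prototypes are fitted at a level that can express subject differences
  (see above); with shared group prototypes, between-subject variation is
  carried solely by occupancy and GFP weighting.
* The percentile-bend correlation has a population value slightly below
  Pearson's ρ under clean normality (≈ 0.478 at ρ = 0.5) and bounds — but
  does not remove — outlier influence; the skipped estimators are the
  ones that recenter on the uncontaminated association.
* Blind deconvolution assumes resolvable spontaneous events; when events
  cluster within an HRF width, single-voxel amplitudes can inflate by
  tens of percent, which is why region summaries use medians.
* No AR-whitened GLM inference: first-level p-values are exact only for
  white noise and slightly liberal under AR(1) noise; group inference is
  carried by the robust one-sample stage.
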