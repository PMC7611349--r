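---
title: "Models and methods behind retinotwin"
author: "retinotwin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retinotwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinotwin)
```

`retinotwin` implements a twin-design analysis of retinotopic map
organization: simulated cohorts of population receptive field (pRF) maps,
a forward model and fitter for wedge-and-ring pRF mapping, and the
inferential machinery that contrasts monozygotic (MZ) and dizygotic (DZ)
twin pairs. This vignette explains the models, the tunable parameters and
their defaults, the design decisions that were genuinely open, and the
limits of what the simulations can show.

## The synthetic cohort model

Every subject's map is a shared template plus an individual deviation
field. The template (`generate_template_map`) carries the global
retinotopic structure that all human observers share: eccentricity follows
a logarithmic gradient along one lattice axis (up to 8.5 degrees, the
maximal stimulus eccentricity), polar angle progresses along the other,
and pRF size grows linearly with eccentricity (default
`sigma = 0.5 + 0.15 * ecc` degrees, a typical early-visual-cortex
relation).

Deviations are pair-correlated Gaussians: for a target intra-pair
correlation `rho`, each twin's field mixes a shared and a unique
i.i.d. component with weights `sqrt(rho)` and `sqrt(1 - rho)`, which gives
the exact expected correlation and keeps the construction transparent.
Polar-angle deviations are added on the angle with wrap-around into
`(-pi, pi]`, eccentricity deviations are additive, and pRF-size deviations
are multiplicative (Gaussian on the log scale) so sizes stay positive.
Because angle and eccentricity are perturbed separately and `(x0, y0)` is
recomputed from them, the heritability of each parameter is independently
controllable. Near the fovea an additive eccentricity deviation can cross
zero; the centre then flips through the origin, which is geometrically
coherent but means stored eccentricities are exact Gaussian deviations
only away from the fovea — the recovery tests therefore check correlations
on vertices with template eccentricity above 2 degrees.

Defaults mirror the study design the package targets: 19 MZ and 14 DZ
pairs, three regions with V3 the smallest at 3409 vertices, and intra-pair
correlations `rho_mz = 0.6`, `rho_dz = 0.4` — a moderately heritable
scenario (true correlation difference 40%, `h2 = 0.4`) that the recovery
tests exercise. Noise SDs default to 0.3 rad (polar), 0.5 deg
(eccentricity), 0.2 log-units (size), 0.15 (curvature) and 0.25 mm
(thickness): large enough that per-pair correlations dominate the
analysis, small enough that maps remain recognisably retinotopic.

Two features of real data are deliberately simplified. First, individual
deviation fields are spatially white by default; real pRF estimates are
spatially autocorrelated (point-spread of the BOLD signal, gradient
structure), and no published value pins down that correlation length. An
optional smoothing kernel (`smoothing_fwhm`) makes deviations smooth when
wanted; the de-meaning and the 8-mm subsampling control are exactly the
analyses designed to cope with such structure. Second, region
delineations are simulated by jittering the template region boundaries
with the same pair-correlated construction (`boundary_jitter_sd`, default
2 mm) — enough to make the overlap analysis non-degenerate, with no claim
of anatomical realism. Passing tests on these cohorts validate the
statistical machinery, not the biology of any particular dataset.

Alignment displacements (`generate_alignment_coordinates`) model the
native-to-template transformation: native coordinates are the aligned
(template) ones plus Gaussian displacements whose per-subject magnitude
has a configurable twin coupling; the default coupling of 0 reproduces the
negative control in which co-twins' transformation magnitudes are
uncorrelated.

## The pRF forward model and fitter

Apertures (`build_apertures`) are binary masks on a square pixel grid
(default 101 pixels across 18 degrees): a 12-degree wedge rotating in 60
one-second steps (6 cycles) unioned with a ring expanding or contracting
over 36 logarithmic radius steps (10 cycles), in four stimulation quarters
each followed by 30 s of fixation — 480 frames, matching 490 acquired
volumes minus 10 dummies. Whether wedge and ring should be combined as a
union or modelled separately is not fixed by the description the package
follows; union is used because both components are on screen together,
and either component can be disabled.

The neural drive of a pRF `(x0, y0, sigma)` is the Gaussian mass over the
stimulated pixels; it is convolved with a double-gamma HRF (peak 6 s,
undershoot 16 s, unit dispersions, ratio 1:6 — conventional "canonical"
values), scaled by the amplitude, linearly detrended and z-normalized,
mirroring the preprocessing of measured series. A numerically constant
series z-normalizes to all zeros (the zero-variance contract), with
constancy judged relative to the series' magnitude so detrending residue
is not amplified.

Because the masks are binary, the drive converges under pixel-grid
refinement only at roughly order `h^1.5` (boundary-pixel quantization,
worst for the thin inner ring annuli): the area-normalized drive changes
by about 5% from 51 to 101 pixels and about 2% from 101 to 201; sub-1%
changes per halving require roughly 300 pixels per side. The tests assert
this convergence law; users needing finer accuracy should raise
`resolution`.

Fitting is coarse-to-fine (`coarse_fit`, `fine_fit`). The coarse stage
smooths the data on the surface (FWHM 5 mm), grid-searches `x0, y0` (0.5
degree steps over ±9) and `sigma` (0.25–8 degrees, doubling steps; grid
ranges are a package choice, recorded in `fit_config`), and keeps the
parameters with maximal Pearson correlation — its R² is that correlation
squared, ties broken at the first grid point. The fine stage refines
`(x0, y0, sigma, amplitude)` per vertex with Nelder–Mead (relative
tolerance 1e-6, 500 iterations; non-convergence keeps the best iterate) on
the unsmoothed series, seeded at the coarse solution with the amplitude
seeded by least squares — so the residual sum of squares can only improve
— and only for vertices whose coarse R² exceeds 0.05; its R² is
`1 - SSres/SStot`. Final parameter maps are smoothed at FWHM 3 mm
(circular quantities re-derived from smoothed Cartesian centres). One run
is simulated; averaging multiple runs is equivalent to lowering the noise
SD.

## Twin statistics

Before any correlation, the vertex-wise sample-mean map of the whole
participant sample is subtracted (`demean_maps`); for polar angle this
uses the circular mean and wrapped residuals, a choice the package makes
explicit since plain subtraction is ill-defined on the circle. De-meaning
removes any component shared by all subjects — otherwise the global
retinotopic gradients alone would correlate every pair of maps.

Intra-pair correlations use Spearman's coefficient for linear parameters
and the Jammalamadaka–SenGupta circular correlation for polar angle
(rotation invariant; "circular correlation" alone does not pin down a
coefficient, so the choice is recorded here and in the output metadata).
The correlation between the two twins of a pair is computed directly;
no intra-class symmetrization is applied, matching the within-pair
correlation the design describes. Group means average in Fisher-z space
and back-transform by default; whether the correlation difference should
be formed from back-transformed means or in z-space is ambiguous, so both
are implemented (`transform = "back"` / `"z"`, identical p-values since
tanh is monotone).

The correlation difference `delta_r = 200 (M(r_MZ) - M(r_DZ))` percent is
tested by resampling pairs with replacement within each group (default
10,000 draws): percentile 95% CIs and `p` = the proportion of draws at or
below zero, judged against Bonferroni-corrected alphas — families of 9
(three pRF parameters × three regions), 6 (two morphology parameters ×
three regions) and 3 (one hierarchy trend per pRF parameter). The
hierarchy trend regresses each iteration's three regional draws on region
rank 1–3 and reports the share of non-positive slopes. Permutation nulls
re-pair participants within a group (derangement-style: true pairs are
never re-created, resampled each permutation) and report the share of
permutations whose mean statistic reaches the observed one; the plain
proportion is reported as specified, with an add-one smoothed variant by
flag. The subsampling control greedily keeps vertices at least 8 mm apart
in a seeded random visiting order.

The multidimensional heritability estimator works from the phenotypic
similarity matrix (correlations between subjects' de-meaned vertex
vectors) and the kinship matrix (1 / 0.5 / 0). The exact equations of the
published estimator it stands in for are not reproduced in the package's
sources, so a transparent moment estimator is used and validated purely by
parameter recovery: off-diagonal similarities are regressed on kinship
plus a co-twin indicator. The co-twin indicator is essential — without
it, shared-environment resemblance loads on the kinship slope and a
0.6/0.4 scenario would return `h2` near 0.63 instead of 0.4; with it the
kinship coefficient estimates `2 (r_MZ - r_DZ)`, the Falconer quantity,
and is clipped to [0, 1]. CIs resample pairs within groups; resampled
cohorts exclude similarity entries that would compare a subject with its
own duplicate or mislabel duplicated co-twins as unrelated.

## Power analysis

The power module reduces maps to what the test consumes: per-pair sample
correlations of bivariate-Gaussian vertex data (3409 points per pair, the
size of V3). Scenario "midpoint" moves MZ and DZ correlations apart
symmetrically around 0.5 (up to 0.53/0.47, i.e. a 12% difference);
scenario "lowbase" fixes the DZ correlation at 0 and raises only the MZ
one (to 0.06 at 12%), probing the power floor at low baselines. Each grid
point runs replicate cohorts through the production `bootstrap_delta_r`
code path and counts detections at `p < 0.05/9`. The default grid
evaluates a handful of representative differences (0, 2, 4, 8, 12%) rather
than every 0.001 step of the sweep — the step size is a sweep resolution,
not a result — and the full grid is one argument away.

## Numerical choices and degenerate inputs

* Angles are wrapped into `(-pi, pi]`; circular means use the resultant
  direction.
* A zero mean pRF distance (identical maps) raises an error rather than
  returning an infinite similarity; noisy data never hits it and silent
  infinities would corrupt the ANOVA.
* ANOVA limit cases are made finite: zero between-group variance yields
  `F = 0`, a noiseless effect yields a large finite `F` with `p = 0`.
* Correlations of zero-variance series are `NA` with a warning; Fisher-z
  averaging refuses `|r| = 1`, while permutation internals clamp at
  `1 - 1e-12` because degenerate unit correlations can arise there by
  construction.
* One master seed expands into independent substreams per stage
  (`derive_seed`), keeping every stage reproducible and independent.
* All draw counts (10,000 bootstrap, 1000 permutations, 1000 power
  replicates) are configurable; the test suite runs reduced but honest
  sizes — e.g. 300-replicate power checks, 50-replicate recovery checks,
  a 200-vertex noise-free refit at 51-pixel apertures — chosen so the
  Monte-Carlo error stays well inside each asserted tolerance.

## Known limitations

* The percentile-bootstrap test of the correlation difference is mildly
  anti-conservative at these sample sizes: with 19 + 14 pairs its null
  rejection rate at a corrected alpha of 0.0056 is about 0.011, because
  the bootstrap deflates the group SEs by `(n-1)/n` and the SEs are
  estimated from few pairs (a t-like effect). This is a property of the
  published procedure itself, visible in the package's null-calibration
  check; interpret borderline p-values accordingly.
* Spearman correlations on Gaussian data run about 1.5% below the Pearson
  value, and de-meaning against the sample mean slightly attenuates
  per-pair correlations in small samples; both effects largely cancel in
  the MZ-DZ difference but bias `delta_r` a point or two below
  `200 * (rho_mz - rho_dz)` in absolute terms.
* Binary aperture masks quantize at pixel boundaries (see above).
* The generator makes no claim of anatomical realism: no folding
  geometry, no cortical magnification beyond the log gradient, no scanner
  artifacts or motion, and white deviation fields by default.
* No ACE/ADE structural-equation modelling is provided; the package
  implements the Falconer-style difference and the similarity-matrix
  moment estimator only, and makes no claims about real-brain
  heritability values.
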