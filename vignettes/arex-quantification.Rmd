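---
title: "MT-corrected, relaxation-compensated CEST quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MT-corrected, relaxation-compensated CEST quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arexcest)
```

## The measurement and its confounds

A CEST experiment saturates the magnetization of exchangeable solute
protons at their chemical shift and reads out the transferred saturation
as a dip in the water signal. The normalized readout is the z-spectrum
$Z(\Delta\omega) = S(\Delta\omega)/S_0$, sampled here at 43 offsets
between $-5$ and $+5$ ppm with glutamate's amine protons at $+3.0$ ppm as
the target. Three large nuisance effects sit under the small amine dip:

* **direct saturation (DS)** of water itself — a narrow symmetric
  Lorentzian at 0 ppm;
* **semisolid MT** — a very broad, *asymmetric* baseline from
  macromolecular protons, peaking near $-2.4$ ppm and strongest in
  myelinated white matter;
* **T1 weighting** — saturation transfer accumulates over the water
  pool's longitudinal relaxation time, so tissues with different $R_1$
  show different apparent contrast at equal exchange rates.

The package's chain removes them in sequence: spline drift correction and
normalization, B0 recentring, a two-pool Lorentzian fit whose MT
component is removed from the measured spectrum, an inverse-difference
(spillover-compensating) contrast, and finally multiplication by $R_1$:

$$\mathrm{MTR_{Rex}} = \frac{1}{Z_\mathrm{corr}(+3)} -
  \frac{1}{Z_\mathrm{corr}(-3)}, \qquad
  \mathrm{AREX} = \mathrm{MTR_{Rex}} \times R_1 .$$

## Model and sign conventions

The labeled spectrum is modeled as a baseline minus Lorentzian
components,

$$Z(\Delta\omega) = Z_\mathrm{base} - \sum_i L_i(\Delta\omega), \qquad
  L_i(\Delta\omega) =
  \frac{A_i}{1 + 4\left((\Delta\omega - \Delta\omega_i)/\sigma_i\right)^2},$$

with $\sigma$ the full width at half maximum. Amplitudes are fractions of
$Z$ (percent scales divided by 100); $Z_\mathrm{base} = 1$ with perfect
saturation efficiency, and the package fixes it at 1 by default with an
option to fit it in $[0.9, 1]$. Chemical shifts are never fitted: DS sits
at 0 ppm and MT at $-2.4$ ppm.

Because the MT pool enters $Z$ with a negative sign, *removing its
contribution* means adding the fitted component back:
$Z_\mathrm{corr} = Z + L_\mathrm{MT}$. On a pure DS+MT spectrum this
restores $Z_\mathrm{base} - L_\mathrm{DS}$ exactly, corrected spectra
move toward the baseline, asymmetry contrasts shift toward positive
values, and a phantom without a $+3$ ppm pool yields exactly zero
corrected contrast — the properties the test suite asserts. An
alternative inverse-space correction
($1/Z_\mathrm{corr} = 1/Z - 1/Z_\mathrm{refMT}$ with
$Z_\mathrm{refMT} = Z_\mathrm{base} - L_\mathrm{MT}$, the fitted MT-only
spectrum) is available as a flagged variant; the two forms are not
algebraically equivalent and the Z-space form is the default.

## Fitting: parameters, bounds, numerics

The two-pool fit is a bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, function/step tolerance $10^{-10}$, at most 500
iterations) with the standard bound box and starting values
(`defaultFitBounds()`):

| parameter | lower | upper | start |
|---|---|---|---|
| DS amplitude (fraction) | 0.20 | 1.00 | 0.60 |
| MT amplitude (fraction) | 0.00 | 0.90 | 0.35 |
| DS width (ppm) | 0.1 | 5 | 2.55 |
| MT width (ppm) | 10 | 100 | 55 |

A single deterministic start is used. When the solution lands on a bound
— the signature of the degenerate amplitude–width ridge the two
overlapping pools create — the fitter retries from a fixed 8-point grid
of alternative starts and keeps the lowest residual; the procedure
remains fully deterministic and is what lets noiseless in-bounds truths
be recovered to machine precision across the whole box (one in 200 random
draws otherwise converges to an `mtW`-at-bound ridge with ~10% amplitude
error). Voxels whose DS amplitude sits at the 0.20 lower bound are
flagged as likely non-tissue.

Parameters are validated against an exhaustive grid-search oracle that
enumerates the full bound box at 0.005 amplitude / 0.25 ppm width
resolution (made tractable by solving the convex quadratic in the DS
amplitude analytically at each node). One caveat discovered this way: for
truths whose width falls off the oracle's grid, a 0.05 ppm quantization
of the DS width trades against several ppm of MT width along the ridge,
so oracle agreement "within grid resolution" is only meaningful for
on-grid truths — the test fixtures are chosen accordingly.

**Model-mismatch limitation.** The two-pool baseline absorbs part of any
extra pool into its parameters. With a small amine pool
($A \le 0.01$) the corrected reference side at $-3$ ppm moves by under
$2\times10^{-4}$; at $A = 0.03$, $\sigma = 1.5$ ppm the *global* optimum
pushes the MT width to its bound and the leakage grows to $\sim 6\times
10^{-3}$. This is a property of the published two-pool procedure itself
(multi-pool decomposition is explicitly out of scope), and it is why the
dose–response ratio of `MTR_Rex` under amine doubling is near, but not
exactly, 2.

## Field maps

**B0 (WASSR).** A low-power water-only saturation spectrum is acquired at
51 offsets (0.05 ppm steps inside $\pm 1$ ppm, 0.1 ppm outside, to
$\pm 1.5$ ppm). The voxel shift is estimated by maximum-symmetry center
finding: the $\delta$ minimizing
$\sum_x (Z(\delta + x) - Z(\delta - x))^2$ on a cubic-spline
interpolant, via coarse (0.01 ppm) then fine (0.001 ppm) grids and a
final continuous refinement. This is more robust to noise than taking
the minimum sample. Flat spectra (range below 0.02) are flagged and get
shift 0. Spectra are then resampled at `offset + shift` so every voxel
shares one grid; edge samples that would need extrapolation become `NA`
and are counted.

**B1 (dual-TR AFI).** With $n = TR_2/TR_1$ the steady-state ratio
$r = S_2/S_1$ inverts in closed form,
$\alpha = \arccos\big((rn - 1)/(n - r)\big)$; the protocol values are
$TR_1/TR_2 = 35/160$ ms at a 60° nominal flip. Ratios outside $(1/n, 1]$
are flagged (small noise overshoots above 1 are clipped). The B1 map is
computed and reported but deliberately **not** applied to the CEST
contrast: no published correction algorithm accompanies the acquisition,
so a pass-through hook exists for future use.

## R1 mapping and slice collapsing

The inversion-recovery series (14 TIs from 6 to 8000 ms) is fitted
voxel-wise with the three-parameter magnitude model
$|m_0 (1 - (1 + e)\,e^{-TI \cdot R_1})|$, where $e \in [0, 2]$ is the
inversion efficiency. Magnitude data lose the sign, so polarity is
restored by trying sign flips at the candidate null positions around the
signal minimum and keeping the best residual. The mono-exponential
free-water $R_1$ is what the AREX correction consumes.

The $R_1$ maps come as five 2 mm slices against a single 10 mm CEST
slice: maps are collapsed by voxel-wise mean over valid slices; binary
masks by *k*-of-*n* voting — at least 2 of 5 slices for GM/WM/WM-lesion
masks, any slice for small cortical lesions — after which lesion voxels
are removed from the normal-appearing masks.

## Statistics

ROI summaries report mean, median and a histogram (64 uniform bins over
the robust 1st–99th percentile range). Group comparisons use the classic
pooled-variance two-sample t-test (Welch by flag) and paired t-tests.
Associations with covariates use a partial Spearman correlation:
midranks, linear adjustment of the ranked variables for the ranked
covariates, Pearson correlation of the residuals, and a two-sided p from
the t approximation with $n - 2 - k$ degrees of freedom (the common
rank-then-residual estimator; the p-value method is a documented choice).
No multiplicity correction is applied by default; `bonferroniThreshold()`
reports $\alpha/m$ for post-hoc use.

## The synthetic phantom: what it emulates, and what it does not

The generator builds a 2D single-slice digital phantom (concentric
CSF/WM/GM geometry with one WM and one cortical lesion) whose spectra
follow the same multi-pool Lorentzian forward model the analysis fits,
shifted per voxel by a smooth B0 field, with multiplicative linear S0
drift, additive Gaussian noise on magnitude images (Rician by flag), and
AFI/IR/WASSR series generated from the same ground truth. Per-class
parameters are fixed once at values a 7T neuroimaging practitioner would
call typical:

* $R_1$ (1/s): GM 0.50, WM 0.83, CSF 0.23, WM lesion 0.70, cortical
  lesion 0.55 ($T_1 \approx$ 2.0 s, 1.2 s, 4.3 s respectively);
* MT amplitude: WM 0.25 > WM lesion 0.18 (demyelination) > GM 0.10 >
  CSF 0; MT width 55 ppm;
* DS: amplitudes 0.55–0.85, widths 1.4–2.6 ppm (narrowest/deepest in
  CSF);
* amine at $+3$ ppm: GM 0.030 > WM 0.020, $\sigma = 1.5$ ppm; an
  optional rNOE pool at $-3.5$ ppm exercises model mismatch;
* noise SD 0.005 of $S_0$, drift 1.00 → 0.97 across the series,
  $Z_\mathrm{base} = 1$.

Every simulator takes an explicit seed; there is no global random state.

Because the phantom's spectra come from the same Lorentzian family the
pipeline fits, passing tests demonstrate correctness of the estimation
chain — normalization, field mapping, bounded fitting, contrast algebra,
statistics — not robustness to real-tissue physics. Deliberately absent:
Bloch–McConnell exchange dynamics, pulse-shape saturation physics,
realistic anatomy, motion, k-space artifacts, and registration (inputs
are generated pre-aligned; transform hooks default to identity, matching
the scope where alignment is handled by external tools).

## The synthetic cohort study

The end-to-end validation simulates 15 patients whose WM-lesion amine
amplitude is elevated by 0.008 over their own WM (subject WM amine
jittered with SD 0.002 across the cohort), runs each subject through
assembly → two-pool fit → IR $R_1$ with slice collapsing → AREX, and
applies the paired lesion-vs-NAWM t-test. Subjects are simulated with a
flat B0 field — recentring accuracy is established separately and
omitting the per-subject WASSR stage keeps the study compact (32×32
grids). With these settings the test rejects at $p < 0.05$ with an
effect size above 1 SD, a qualitative analogue of elevated lesion
glutamate; the numbers are produced by the test suite and the acceptance
script at run time, never stored.

## Degenerate inputs and tie-breaks

Non-positive interpolated $S_0$ drops a voxel (counted); background is
excluded at 5% of the robust (99th percentile) mean-$S_0$ maximum.
Flat WASSR spectra get shift 0 with a flag; AFI ratios outside the
invertible domain, non-positive corrected spectra at either $\pm 3$ ppm
sample, missing fits and invalid $R_1$ all invalidate the voxel rather
than being clipped, so ROI means are not biased by reciprocal blow-ups.
Cubic interpolation everywhere uses the FMM spline, which reproduces
polynomials up to degree 3 exactly — hence drift of that order is removed
to numerical precision, and sampling at grid offsets returns stored
values bitwise. Problem sizes in the tests (8–64 voxel grids, 200 fit
draws, 100 noisy $R_1$ draws, a 15-subject cohort) were chosen as the
smallest sizes at which each property is stable and meaningful.
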