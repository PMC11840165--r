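---
title: "Five-pool Z-spectrum decomposition and NOE contrast analysis: methods"
author: "zspecfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-pool Z-spectrum decomposition and NOE contrast analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zspecfit)
```

## Scope and model

`zspecfit` analyses chemical exchange saturation transfer (CEST) and
nuclear Overhauser effect (NOE) brain MRI at ultra-high field. The measured
quantity per voxel is a Z-spectrum: the water signal after off-resonance
saturation, normalized by a far off-resonance (100 ppm) reference
acquisition, as a function of saturation offset $\Delta\omega$ in ppm. The
package decomposes each voxel's Z-spectrum into five Lorentzian pools,

$$Z(\Delta\omega) = Z_{base} - \sum_{i} L_i(\Delta\omega), \qquad
L_i(\Delta\omega) = A_i\,\frac{\Gamma_i^2/4}{\Gamma_i^2/4 +
(\Delta\omega - \delta_i)^2},$$

with the baseline $Z_{base}$ fixed at 1 (a free baseline would absorb
constant signal loss into every pool). The pools and their nominal centers
are: direct water saturation (DS, 0 ppm), semi-solid magnetization transfer
(MT, $-2$ ppm), amide ($+3.5$ ppm), amine ($+2.2$ ppm) and relayed NOE
(rNOE, $-3.5$ ppm). The MT center of $-2$ ppm follows the convention of the
study this package operationalizes; parts of the CEST literature place it
nearer $-2.5$ ppm, and the value is configurable in `fitConfig()`.

The derived scalar contrast is the NOE magnetization transfer ratio,

$$\mathrm{NOE}_{MTR} = \frac{S_0 - S(-3.5\ \mathrm{ppm})}{S_0}\times 100,$$

with $S_0$ the 100 ppm reference signal. One wrinkle is worth stating
plainly: the standard acquisition grid runs $-5$ to $+5$ ppm in steps of
0.2 ppm, whose samples fall at even multiples of 0.1 ppm — $-3.5$ ppm is
*between* two samples. `noeMtr()` itself is pure arithmetic on whatever
$-3.5$ ppm signal it is given; the voxel-wise map in `fitVolume()` obtains
that signal by cubic Lagrange interpolation over the four nearest sampled
offsets ($-3.8\ldots-3.2$ ppm), which for spectra this smooth is accurate
to well below the noise floor.

## Fitting

`fitVoxel()` minimizes the summed squared difference between the observed
normalized spectrum and $1 - \sum_i L_i$ by Levenberg–Marquardt least
squares with box constraints (`minpack.lm::nls.lm`), using an analytic
Jacobian. The reference point takes no part in the residual; it is a
normalizer only. Bounds and initial values (all overridable via
`fitConfig()`):

| pool  | $A$ bounds | $A$ init | $\Gamma$ bounds (ppm) | $\Gamma$ init | $\delta$ bounds (ppm) |
|-------|-----------|----------|----------------------|---------------|----------------------|
| DS    | 0–1       | $0.8(1-\min Z)$ | 0.3–10  | 2   | $\pm 0.2$   |
| MT    | 0–0.5     | 0.10     | 10–60                | 25            | fixed $-2$  |
| amide | 0–0.3     | 0.05     | 0.4–3                | 1             | 3.4–3.6     |
| amine | 0–0.3     | 0.03     | 0.4–4                | 1.5           | 2.1–2.3     |
| rNOE  | 0–0.5     | 0.10     | 1–5                  | 3             | $-3.7$–$-3.3$ |

The data-driven DS start (80% of the spectral depth) makes the dominant dip
immediately attributable to water, which stabilizes the remaining pools.
The narrow center floats on the CEST/NOE lines absorb residual
off-resonance after B0 correction; the broad MT line is kept at its nominal
center because its width makes its center weakly identifiable on a
$\pm 5$ ppm window. Whether the original analysis fixed or floated centers
is not documented; the floats are this package's choice and can be frozen
through `fitConfig(free = ...)`.

Convergence tolerances are `ftol = ptol = 1e-10` with at most 100
iterations. A voxel is QC-flagged when it fails to converge or its residual
norm exceeds 5 times the in-mask median; flagged voxels are excluded from
ROI statistics. `fitVolume()` visits voxels in fixed array order with no
shared state, so results are deterministic and independent of any
scheduling or worker count.

## Preprocessing chain

The per-subject chain runs in a fixed order: denoise → normalize → B0 →
fit → B1 → statistics. The source protocol lists denoising before fitting
and both field corrections before analysis but not their mutual order;
this ordering is a package decision.

**Normalization.** $Z = S(\Delta\omega)/S_0$ voxel-wise; voxels with
non-positive reference signal are masked out.

**B0.** A low-power water saturation shift referencing (WASSR) acquisition
($-1$ to $+1$ ppm, 0.1 ppm steps) locates the water resonance per voxel:
a second-order polynomial is fit to a 5-point window centered on the
discrete minimum and the parabola's vertex is the B0 shift. Five points
stabilize the vertex under noise while staying local; windows are clipped
at grid edges. Degenerate voxels (edge minima, non-convex local fits) fall
back to the discrete argmin and are flagged. The spectrum is then resampled
at (nominal offsets + shift) by piecewise-cubic interpolation back onto the
nominal grid. On noiseless synthetic lines the vertex recovers shifts up to
$\pm 0.5$ ppm within 0.02 ppm, and shift-then-correct restores interior
points within $10^{-3}$.

Offsets that the shift pushes outside the measured range deserve care. The
single-spectrum `correctB0()` fills them with the nearest edge value and
flags them. For volume stacks we found that those filled end points,
entering the residual as data, bias exactly the pools with power near the
window ends — MT and rNOE, and through them amine — by up to ~5% in regions
where the B0 field concentrates at one shift. The stack-level correction
therefore marks extrapolated ends as missing by default
(`fill = "na"`), and the fitter simply drops missing offsets from the
residual (requiring at least 20 valid points). With at most 0.3 ppm of
shift this costs one or two of 51 points.

**B1.** Transmit-field inhomogeneity scales saturation efficiency. The
correction divides fitted pool amplitudes by the voxel's relative B1
(1 = nominal) and clips to [0, 1] — a first-order linear model applied
after fitting, matching the phantom's generative model so the whole chain
is recovery-testable. Whether the original analysis corrected raw images or
fitted amplitudes is not stated; this is a documented package decision, and
the B1 map is an input (as in practice, where it comes from a separate
mapping sequence). Voxels with relative B1 below 0.3 are masked.

**Denoising.** The published pipeline used BM4D, an established external
algorithm that is out of scope here. `denoiseHook()` provides an identity
method, a separable Gaussian, and accepts any user function
`function(stack) stack`, so an external BM4D implementation can be plugged
in unchanged.

## The digital phantom

`phantomSpec()`/`simulateCohort()` generate multi-subject volumetric
datasets with known ground truth. The generator's defaults encode the
study conditions: 15 MS and 10 control subjects; MS age
$43.7 \pm 14.7$ y resampled into [21, 70], control $40.9 \pm 16.9$ y into
[23, 71]; sex ratios 10F/5M and 5F/5M; disease duration $6.5 \pm 6.6$ y
and in-slab lesion volume $1.2 \pm 1.4\ \mathrm{cm}^3$, both truncated at
zero (and identically zero for controls). Truncated draws are resampled,
not clipped, so prior means are preserved inside the bounds.

Tissue pool-amplitude and T1 priors (per subject, mean ± SD across
subjects) encode the published group values for WM, NAWM, lesion and GM
rNOE/amine/DS/T1. Quantities the study reports only graphically or not at
all carry package defaults, documented in `defaultTissuePriors()`: MT
$0.10 \pm 0.02$ (WM), amide $0.05 \pm 0.01$, the GM DS/T1 rows, the entire
CSF row, and generative line widths (DS 2, MT 25, amide 1, amine 1.5,
rNOE 3 ppm). These are plausible 7T values chosen once; they are inputs,
not fitted claims.

Geometry is an ellipsoidal brain at desk scale — default
$64 \times 64 \times 10$ voxels at $1 \times 1 \times 2$ mm, emulating the
acquired slab's matrix at reduced size — with an outer GM shell, WM
interior and central CSF compartment, so T1-based segmentation is
non-trivial. Lesions are spheres at uniformly drawn deep-WM centers (the
source data say only that slabs were placed superior to the corpus
callosum; uniform placement is a package decision), grown until the lesion
voxel count matches the subject's drawn volume exactly; grids too small
for the drawn lesion are rejected with the required size. Optional
coupling adds the published lesion-T1/duration slope (24.34 ms/y) to the
lesion T1 prior, off by default.

Per voxel, amplitudes are the subject-level tissue draw plus Gaussian
jitter (SD 0.002, clipped to [0, 1]). Fields are smooth low-order random
polynomials: B0 scaled to at most 0.3 ppm, relative B1 mapped into
[0.7, 1.15] and acting multiplicatively on pool amplitudes before spectrum
synthesis. Noise is additive Gaussian on normalized Z (SD 0.002), the
simple high-SNR error model the fitter assumes — not Rician magnitude
noise. The WASSR series is a narrow DS-only line (amplitude 0.9, FWHM
0.5 ppm) sharing the voxel's B0 shift. The seed fully determines a cohort.

What the phantom does *not* emulate — realistic anatomy, partial-volume
mixing, motion and drift, Rician noise, pulse-level saturation physics
(spectra come directly from the Lorentzian forward model, not
Bloch–McConnell simulation) — bounds what passing tests show: they
validate the estimation machinery against its own generative assumptions,
not the biology of real scans.

## Statistics

`cohortStats()` reproduces the published analysis plan on per-subject ROI
means: two-sample t-tests and age/sex-adjusted linear regressions
(`contrast ~ group + age + sex`) for whole-brain and GM contrasts between
groups; pairwise t-tests among control WM, NAWM and lesion with Bonferroni
correction for the family of three ($p_{adj} = \min(1, 3p)$, per-contrast
families, matching how the comparisons are reported); and simple linear
regressions of each contrast on disease duration and lesion volume within
the MS group. The t-tests default to Welch's unequal-variance form — the
source says only "two-sample t-tests", and the pooled variant is available
via `varEqual = TRUE`. $\alpha = 0.05$ throughout. The whole-brain ROI is
GM ∪ WM, excluding CSF, including lesions for MS subjects. Tissue volume
is voxel count times voxel volume.

Segmentation thresholds (WM < 1450 ms < GM < 2600 ms < CSF) bracket the
phantom's T1 priors; lesion masks are pipeline *inputs* that override the
T1 labels, mirroring manual lesion segmentation — note lesion T1
(~1600 ms) falls inside the GM band, so lesions are not recoverable from
T1 thresholds alone.

Percent changes are reported as $100(\bar{x}_{comparison} -
\bar{x}_{reference})/\bar{x}_{reference}$, recomputed from means rather
than transcribed: a few published percent strings are inconsistent with
their own printed (rounded) means — e.g. GM rNOE is quoted as a 10.6%
decrease while the printed means 0.094 → 0.085 give 9.6%, and whole-brain
amine as 14.8% while 0.037 → 0.031 gives 16.2% — implying unrounded
source values. This package reports what the numbers it holds imply.

## Problem sizes and numerical choices

Test and acceptance runs use the phantom at its default
$64 \times 64 \times 10$ scale for single-subject recovery and a
$48 \times 48 \times 8$ grid per subject for the 25-subject end-to-end
cohort — large enough that per-subject ROI means are essentially
noise-free (thousands of voxels per tissue), so cohort-level comparisons
are dominated by between-subject sampling, which is the quantity under
test. Smoke tests of plumbing use smaller grids with proportionally small
lesions. With 15 and 10 subjects drawn from the published priors the
NAWM-vs-control-WM rNOE percent change has a between-subject sampling SD
near 3.8 percentage points; the end-to-end check asserts agreement with
the published −11.4% within 3 points at a fixed seed, and at larger
cohorts the estimate concentrates as $1/\sqrt{n}$.

Other numerical choices: piecewise-cubic (`stats::spline`, "fmm")
interpolation for spectral resampling; WASSR windows clipped at edges with
degenerate fits flagged rather than failed; lesion spheres trimmed by
distance so drawn volumes are matched exactly; all tolerances surfaced as
function arguments. Known limitations: no Rician noise model, no
partial-volume tissue mixing, no registration (masks must share the
stack's grid exactly), and MT/amide recovery tolerances are wider than the
sharp pools' because a 25 ppm line observed on a ±5 ppm window is
intrinsically poorly constrained.
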