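# zspecfit

Five-pool Lorentzian Z-spectrum decomposition and NOE contrast analysis
for ultra-high-field CEST/NOE brain MRI.

## The problem

Saturation-transfer MRI measures a **Z-spectrum** per voxel: the water
signal after off-resonance saturation at offsets Δω (ppm from water),
normalized by a far off-resonance (100 ppm) reference, Z(Δω) = S(Δω)/S₀.
Dips in the spectrum carry overlapping contributions from direct water
saturation (DS), semi-solid magnetization transfer (MT), amide and amine
proton exchange, and the relayed nuclear Overhauser effect (rNOE) of
mobile lipids and proteins. Separating them matters clinically: in
multiple sclerosis, decreases in the rNOE and amine pools of
normal-appearing tissue track diffuse demyelination that conventional T1
maps miss.

`zspecfit` is for researchers who need that separation as a tested,
reproducible pipeline: it decomposes each voxel's spectrum into five
Lorentzian pools,

    Z(Δω) = Z_base − Σᵢ Aᵢ (Γᵢ²/4) / (Γᵢ²/4 + (Δω − δᵢ)²),   Z_base ≡ 1,

by bounded Levenberg–Marquardt least squares (analytic Jacobian, pools at
nominal centers DS 0, MT −2, amide +3.5, amine +2.2, rNOE −3.5 ppm),
together with everything around the fit:

* a **digital brain phantom** (`phantomSpec()`, `simulateCohort()`) that
  generates multi-subject volumetric Z-spectrum datasets with known ground
  truth — published tissue and demographic priors, smooth B0/B1 fields,
  WASSR series, noise — so every stage is recovery-testable;
* **preprocessing** (`normalizeZStack()`, `estimateB0Wassr()`,
  `correctB0()`, `correctB1()`, `denoiseHook()`): reference normalization,
  WASSR parabolic-vertex B0 mapping and spectral re-interpolation,
  first-order B1 amplitude correction, pluggable denoising;
* **fitting** (`fitVoxel()`, `fitVolume()`) with QC maps and the
  NOE magnetization-transfer-ratio contrast
  NOE_MTR = (S₀ − S(−3.5 ppm))/S₀ × 100;
* **ROI statistics** (`segmentFromT1()`, `cohortStats()`): T1-threshold
  tissue segmentation with lesion masks as inputs, Welch t-tests,
  age/sex-adjusted regression, Bonferroni-corrected pairwise comparisons,
  clinical covariate regressions, percent-change reporting.

## Worked example

Fit a healthy-white-matter spectrum generated from the model itself — the
fit recovers the generating parameters to machine precision:

```r
library(zspecfit)
p <- fivePoolParams(amplitude = c(0.655, 0.10, 0.05, 0.039, 0.114),
                    fwhm = c(2, 25, 1, 1.5, 3))
z <- zSpectrumForward(mainAxis(), p)
fit <- fitVoxel(zValues(z), mainAxis())
fit$params
#> FivePoolParams (baseline fixed at 1)
#>              DS   MT amide amine   rNOE
#> amplitude 0.655  0.1  0.05 0.039  0.114
#> fwhm      2.000 25.0  1.00 1.500  3.000
#> center    0.000 -2.0  3.50 2.200 -3.500
fit$residual
#> [1] 3.48e-16
```

The amplitudes are dimensionless fractions of the normalized signal: here
the rNOE pool removes 11.4% of the water signal at −3.5 ppm.

Percent changes between published group means are one call:

```r
percentChange(0.114, 0.101)   # control WM -> NAWM rNOE
#> [1] -11.40351
```

i.e. an 11.4% rNOE decrease in normal-appearing white matter.

End-to-end, on a simulated 15 MS / 10 control cohort built from the
published tissue priors (48 × 48 × 8 voxels per subject, ~4 min on one
CPU):

```r
res <- runPipeline(phantomSpec(dim = c(48L, 48L, 8L), seed = 1L))
subset(res$stats, analysis == "pairwise Bonferroni" & contrast == "rNOE" &
                  comparison == "controlWM vs NAWM")
#>  contrast        comparison estimate      t       p pAdjusted r2 slope  meanA
#>      rNOE controlWM vs NAWM -0.01138 -2.966 0.01109   0.03327 NA    NA 0.1127
#>      sdA  meanB      sdB percentChange            analysis
#>  0.01103 0.1013 0.006179         -10.1 pairwise Bonferroni
```

The simulated cohort reproduces the published NAWM rNOE decrease
(−10.1% here against the reported −11.4%; the difference is
between-subject sampling at n = 25) and the pairwise Bonferroni-corrected
test detects it (adjusted p = 0.033 < 0.05).

## What the tests do and do not show

The phantom generates spectra directly from the Lorentzian forward model
with Gaussian noise on normalized Z; passing recovery tests validates the
estimation machinery against its own generative assumptions, not
pulse-level saturation physics, partial-volume anatomy or scanner noise
statistics. See the methods vignette (`vignettes/zspecfit-methods.Rmd`)
for the model, parameter defaults, design decisions and limitations.
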