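# Shared fixtures: parameter sets and small phantom specs built in code.

wmParams <- function() {
  fivePoolParams(amplitude = c(DS = 0.655, MT = 0.10, amide = 0.05,
                               amine = 0.039, rNOE = 0.114),
                 fwhm = c(DS = 2, MT = 25, amide = 1, amine = 1.5, rNOE = 3))
}

lesionParams <- function() {
  fivePoolParams(amplitude = c(DS = 0.703, MT = 0.08, amide = 0.05,
                               amine = 0.032, rNOE = 0.076),
                 fwhm = c(DS = 2, MT = 25, amide = 1, amine = 1.5, rNOE = 3))
}

# Independent closed-form sum of the five Lorentzian lines, written out
# term by term (the hand-summation oracle; deliberately not poolDeficit).
handDeficit <- function(w, p) {
  a <- amplitudes(p); g <- fwhms(p); d <- centers(p)
  tot <- 0
  for (i in 1:5) {
    u <- g[[i]]^2 / 4
    tot <- tot + a[[i]] * u / (u + (w - d[[i]])^2)
  }
  tot
}

# Small phantom spec for plumbing tests: tiny grid, small lesions so they
# fit, otherwise default physics.
tinySpec <- function(..., seed = 7L) {
  dem <- defaultDemographics()
  dem$lesionVolume <- c(mean = 0.06, sd = 0.02)
  phantomSpec(dim = c(16L, 16L, 4L), nMS = 2L, nControl = 2L,
              demographics = dem, seed = seed, ...)
}

# One mid-brain voxel index for single-voxel checks.
centerVoxel <- function(vol) {
  d <- dim(tissueLabels(vol))
  c((d[1] + 1) %/% 2, (d[2] + 1) %/% 2, (d[3] + 1) %/% 2)
}
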