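test_that("normalization divides by the reference and masks bad voxels", {
  d <- c(3L, 3L, 2L)
  ref <- array(2, d)
  ref[1, 1, 1] <- 0        # dead voxel
  stack <- array(1, c(d, 4L))
  out <- normalizeZStack(stack, ref)
  expect_false(out$mask[1, 1, 1])
  expect_true(all(out$z[, , , 1][out$mask] == 0.5))
  expect_true(all(is.na(out$z[1, 1, 1, ])))

  # S identically S0 gives Z identically 1
  stack2 <- array(rep(ref, 4L), c(d, 4L))
  out2 <- normalizeZStack(stack2, ref)
  expect_true(all(out2$z[, , , 2][out2$mask] == 1))

  expect_error(normalizeZStack(array(1, c(4, 4, 2, 3)), array(1, c(3, 3, 2))),
               "grid mismatch")
})

test_that("normalizing a noiseless phantom stack recovers the generated Z exactly", {
  spec <- tinySpec(noiseSD = 0, b0Max = 0, b1Range = c(1, 1))
  set.seed(2)
  vol <- buildVolume(spec, drawSubject(spec, "control", "hc"))
  out <- normalizeZStack(vol@zStack, vol@reference)
  lab <- tissueLabels(vol)
  co <- arrayInd(which(lab == 1L)[5], dim(lab))
  truth <- fivePoolParams(vol@truthAmplitude[co[1], co[2], co[3], ],
                          vol@fwhm, vol@center)
  expect_equal(out$z[co[1], co[2], co[3], ],
               zValues(zSpectrumForward(vol@axis, truth)),
               tolerance = 1e-12)
})

test_that("WASSR vertex estimation recovers synthetic shifts", {
  wa <- wassrAxis()
  ww <- offsets(wa)
  # symmetric line centered at zero: vertex exactly zero
  z0 <- 1 - lorentzian(ww, 0.9, 0.5, 0)
  expect_equal(as.numeric(estimateB0Wassr(z0, wa)), 0, tolerance = 1e-12)
  expect_equal(attr(estimateB0Wassr(z0, wa), "flag"), 0L)

  # off-grid shift recovered within 0.01 ppm (noiseless)
  z13 <- 1 - lorentzian(ww, 0.9, 0.5, 0.13)
  expect_lt(abs(as.numeric(estimateB0Wassr(z13, wa)) - 0.13), 0.01)

  # vertex recovery within 0.02 ppm across |B0| <= 0.5
  for (b0 in seq(-0.5, 0.5, by = 0.05)) {
    z <- 1 - lorentzian(ww, 0.9, 0.5, b0)
    expect_lt(abs(as.numeric(estimateB0Wassr(z, wa)) - b0), 0.02)
  }
})

test_that("degenerate WASSR spectra are flagged and fall back to the argmin", {
  wa <- wassrAxis()
  ww <- offsets(wa)
  # minimum at the grid edge
  zEdge <- 1 - lorentzian(ww, 0.9, 0.5, -1.4)
  est <- estimateB0Wassr(zEdge, wa)
  expect_equal(as.numeric(est), ww[which.min(zEdge)])
  expect_equal(attr(est, "flag"), 1L)

  # interior discrete minimum whose local quadratic fit is concave
  zBad <- rep(1, length(ww))
  zBad[9:13] <- c(0.09, 0.30, 0.08, 0.30, 0.09)
  est2 <- estimateB0Wassr(zBad, wa)
  expect_equal(attr(est2, "flag"), 2L)
  expect_equal(as.numeric(est2), ww[11])
})

test_that("volume-level B0 estimation matches the phantom field", {
  spec <- tinySpec(noiseSD = 0, b0Max = 0.3)
  set.seed(19)
  vol <- buildVolume(spec, drawSubject(spec, "control", "hc"))
  mask <- tissueLabels(vol) > 0L
  est <- estimateB0Wassr(vol@wassrStack, vol@wassrAxis, mask = mask)
  err <- abs(est$b0 - vol@b0)[mask & est$flags == 0L]
  expect_lt(max(err), 0.02)
})

test_that("B0 shift-then-correct restores spectra at interior offsets", {
  ax <- mainAxis()
  w <- offsets(ax)
  p <- wmParams()
  zTrue <- zValues(zSpectrumForward(ax, p))
  for (shift in c(-0.27, -0.2, 0.1, 0.2)) {
    zObs <- 1 - handDeficit(w - shift, p)
    zCorr <- correctB0(zObs, shift, ax)
    interior <- !attr(zCorr, "edge")
    expect_lt(max(abs(as.numeric(zCorr) - zTrue)[interior]), 1e-3)
  }
  # zero shift is the identity
  expect_equal(as.numeric(correctB0(zTrue, 0, ax)), zTrue, tolerance = 1e-12)
})

test_that("B0 correction is invertible at interior offsets", {
  ax <- mainAxis()
  z <- zSpectrumForward(ax, lesionParams())
  s <- 0.17
  fwd <- correctB0(z, s)
  back <- correctB0(fwd, -s)
  interior <- !(attr(fwd, "edge") | attr(back, "edge"))
  expect_lt(max(abs(zValues(back) - zValues(z))[interior]), 1e-3)
})

test_that("stack-level correction marks extrapolated ends missing by default", {
  spec <- tinySpec(noiseSD = 0, b0Max = 0.3)
  set.seed(23)
  vol <- buildVolume(spec, drawSubject(spec, "control", "hc"))
  norm <- normalizeZStack(vol@zStack, vol@reference)
  zc <- correctB0(norm$z, vol@b0, vol@axis)
  lab <- tissueLabels(vol)
  i <- which(lab > 0L & abs(vol@b0) > 0.1)[1]
  co <- arrayInd(i, dim(lab))
  spec1 <- zc[co[1], co[2], co[3], ]
  expect_true(any(is.na(spec1)))           # shifted-out end dropped
  expect_true(sum(is.finite(spec1)) >= 49) # at most two end points lost
  # interior values match the voxel's unshifted truth
  truth <- fivePoolParams(vol@truthAmplitude[co[1], co[2], co[3], ] *
                            vol@b1[co[1], co[2], co[3]],
                          vol@fwhm, vol@center)
  zModel <- zValues(zSpectrumForward(vol@axis, truth))
  keep <- is.finite(spec1)
  expect_lt(max(abs(spec1 - zModel)[keep][3:45]), 2e-3)
})

test_that("B1 correction divides amplitudes and masks low-B1 voxels", {
  d <- c(4L, 4L, 2L)
  b1 <- array(1, d)
  amp <- array(0.05, c(d, 5L))
  expect_equal(correctB1(amp, b1), amp, ignore_attr = TRUE)

  b1[2, 2, 1] <- 0.5
  out <- correctB1(amp, b1)
  expect_equal(out[2, 2, 1, 1], 0.10)

  b1[3, 3, 1] <- 0.2   # below the floor
  out2 <- correctB1(amp, b1)
  expect_true(all(is.na(out2[3, 3, 1, ])))
  expect_equal(attr(out2, "nMasked"), 1L)
})

test_that("denoising hook is identity for 'none' and smooths for 'gaussian'", {
  spec <- tinySpec()
  set.seed(29)
  vol <- buildVolume(spec, drawSubject(spec, "control", "hc"))
  expect_identical(denoiseHook(vol@zStack, "none"), vol@zStack)

  const <- array(3, c(8, 8, 4, 2))
  expect_equal(denoiseHook(const, "gaussian", sigma = 1), const,
               tolerance = 1e-12)

  expect_error(denoiseHook(const, "bm4d"), "unknown denoising method")
  plugin <- function(stack) stack * 2
  expect_equal(denoiseHook(const, plugin), const * 2)

  # gaussian smoothing shrinks the noise around the generative truth
  specN <- phantomSpec(dim = c(24L, 24L, 4L), noiseSD = 0.01, b0Max = 0,
                       b1Range = c(1, 1), jitterSD = 0,
                       demographics = local({
                         d <- defaultDemographics()
                         d$lesionVolume <- c(mean = 0.05, sd = 0.01)
                         d
                       }))
  set.seed(31)
  volN <- buildVolume(specN, drawSubject(specN, "control", "hc"))
  sm <- denoiseHook(volN@zStack, "gaussian", sigma = c(1, 1, 0))
  lab <- tissueLabels(volN)
  r <- zspecfit:::phantomRadius(specN@dim)
  deep <- which(lab == 1L & r > 0.35 & r < 0.5)
  truthZ <- vapply(deep, function(i) {
    co <- arrayInd(i, dim(lab))
    1 - handDeficit(0, fivePoolParams(
      volN@truthAmplitude[co[1], co[2], co[3], ], volN@fwhm, volN@center))
  }, numeric(1))
  j0 <- which(offsets(volN@axis) == 0)
  rawZ <- volN@zStack[, , , j0][deep] / specN@referenceSignal
  smZ <- sm[, , , j0][deep] / specN@referenceSignal
  expect_lt(sd(smZ - truthZ), sd(rawZ - truthZ))
})
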