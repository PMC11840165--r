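#' @import methods
NULL

#' Canonical pool order
#'
#' The five saturation-transfer pools resolved by the model, in canonical
#' order: direct saturation (DS), semi-solid magnetization transfer (MT),
#' amide, amine, and relayed nuclear Overhauser effect (rNOE).
#' @export
POOL_NAMES <- c("DS", "MT", "amide", "amine", "rNOE")

#' Nominal pool chemical shifts (ppm from water)
#' @export
POOL_CENTERS <- c(DS = 0, MT = -2, amide = 3.5, amine = 2.2, rNOE = -3.5)

#' FrequencyAxis: saturation offset grid
#'
#' The saturation frequency offsets (ppm relative to the water resonance) at
#' which a Z-spectrum is sampled, plus the far off-resonance offset used for
#' the normalization acquisition.
#'
#' @slot offsets numeric, strictly increasing offsets in ppm.
#' @slot referenceOffset numeric(1), the normalization offset in ppm
#'   (default 100), which must not be a member of \code{offsets}.
#' @export
setClass("FrequencyAxis",
  representation(offsets = "numeric", referenceOffset = "numeric"),
  prototype(offsets = numeric(), referenceOffset = 100)
)

setValidity("FrequencyAxis", function(object) {
  o <- object@offsets
  if (length(o) < 1L || any(!is.finite(o)))
    return("offsets must be a non-empty finite numeric vector")
  if (any(diff(o) <= 0))
    return("offsets must be strictly increasing")
  if (length(object@referenceOffset) != 1L || !is.finite(object@referenceOffset))
    return("referenceOffset must be a single finite number")
  if (any(abs(o - object@referenceOffset) < 1e-9))
    return("referenceOffset must not be a member of offsets")
  TRUE
})

#' FivePoolParams: one parameter set of the five-pool Lorentzian model
#'
#' Amplitudes, full widths at half maximum and centers for the five pools.
#' The spectral baseline is fixed at 1 and is not a free parameter.
#'
#' @slot amplitude named numeric(5), dimensionless fractions of Z in [0, 1].
#' @slot fwhm named numeric(5), line widths in ppm, strictly positive.
#' @slot center named numeric(5), chemical shifts in ppm from water.
#' @slot zBase numeric(1), fixed at 1.
#' @export
setClass("FivePoolParams",
  representation(amplitude = "numeric", fwhm = "numeric",
                 center = "numeric", zBase = "numeric"),
  prototype(zBase = 1)
)

setValidity("FivePoolParams", function(object) {
  for (sl in c("amplitude", "fwhm", "center")) {
    v <- slot(object, sl)
    if (length(v) != 5L || !identical(names(v), POOL_NAMES))
      return(sprintf("%s must be numeric(5) named %s",
                     sl, paste(POOL_NAMES, collapse = ", ")))
    if (any(!is.finite(v))) return(sprintf("%s must be finite", sl))
  }
  if (any(object@amplitude < 0 | object@amplitude > 1))
    return("amplitudes must lie in [0, 1]")
  if (any(object@fwhm <= 0))
    return("fwhm values must be strictly positive")
  if (!identical(object@zBase, 1))
    return("zBase is fixed at 1 and cannot be changed")
  TRUE
})

#' ZSpectrum: a normalized saturation-transfer spectrum
#'
#' @slot axis a \code{FrequencyAxis}.
#' @slot values numeric, normalized signal Z = M_z / M_z0 per offset.
#' @slot referenceSignal numeric(1), raw signal at the reference offset
#'   (arbitrary units).
#' @export
setClass("ZSpectrum",
  representation(axis = "FrequencyAxis", values = "numeric",
                 referenceSignal = "numeric"),
  prototype(referenceSignal = 1)
)

setValidity("ZSpectrum", function(object) {
  if (length(object@values) != length(object@axis@offsets))
    return("values must have one entry per axis offset")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' PhantomSpec: configuration of the digital brain phantom
#'
#' Describes the cohort (subject counts, demographic priors), the voxel grid,
#' the tissue parameter priors, the field inhomogeneity models and the noise
#' model from which synthetic Z-spectrum volumes are generated.
#'
#' @slot dim integer(3), grid shape (nx, ny, nslices).
#' @slot voxelSize numeric(3), voxel size in mm.
#' @slot nMS,nControl integer(1), subjects per group.
#' @slot demographics named list of demographic priors (see
#'   \code{\link{phantomSpec}}).
#' @slot priors data.frame of tissue/group pool-amplitude and T1 priors.
#' @slot fwhm,center named numeric(5), generative line widths and centers.
#' @slot b0Max numeric(1), maximum absolute B0 offset in ppm of the smooth
#'   polynomial field.
#' @slot b1Range numeric(2), range of the smooth relative-B1 field.
#' @slot noiseSD numeric(1), additive Gaussian noise SD on normalized Z.
#' @slot jitterSD numeric(1), voxel-level amplitude jitter SD.
#' @slot t1JitterSD numeric(1), voxel-level T1 jitter SD in ms.
#' @slot wassrAmplitude,wassrFwhm numeric(1), direct-saturation line of the
#'   low-power WASSR acquisition.
#' @slot durationCoupling logical(1), couple lesion T1 to disease duration.
#' @slot durationSlope numeric(1), lesion-T1 slope in ms per year when
#'   coupling is enabled.
#' @slot referenceSignal numeric(1), raw S0 level inside the brain.
#' @slot seed integer(1), seed that fully determines the generated cohort.
#' @export
setClass("PhantomSpec",
  representation(
    dim = "integer", voxelSize = "numeric",
    nMS = "integer", nControl = "integer",
    demographics = "list", priors = "data.frame",
    fwhm = "numeric", center = "numeric",
    b0Max = "numeric", b1Range = "numeric",
    noiseSD = "numeric", jitterSD = "numeric", t1JitterSD = "numeric",
    wassrAmplitude = "numeric", wassrFwhm = "numeric",
    durationCoupling = "logical", durationSlope = "numeric",
    referenceSignal = "numeric", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("dim must be three integers, each at least 4")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive numbers (mm)")
  if (object@nMS < 0L || object@nControl < 0L)
    return("subject counts must be nonnegative")
  pr <- object@priors
  need <- c("tissue", "group", paste0(rep(POOL_NAMES, each = 2L),
                                      c("_mean", "_sd")),
            "t1_mean", "t1_sd")
  if (!all(need %in% names(pr)))
    return("priors is missing required columns")
  num <- pr[, setdiff(need, c("tissue", "group"))]
  if (any(as.matrix(num) < 0))
    return("prior means and SDs must be nonnegative")
  if (length(object@b1Range) != 2L || any(object@b1Range <= 0) ||
      diff(object@b1Range) < 0)
    return("b1Range must be an increasing pair of positive numbers")
  if (object@b0Max < 0 || object@noiseSD < 0 || object@jitterSD < 0)
    return("b0Max, noiseSD and jitterSD must be nonnegative")
  TRUE
})

#' PhantomVolume: one simulated subject volume with its ground truth
#'
#' The simulated raw Z-stack, reference image and WASSR stack for one subject,
#' stored losslessly alongside the generative ground truth (tissue labels,
#' per-voxel pool amplitudes, B0/B1/T1 fields and the subject-level tissue
#' means) so that parameter recovery can be checked exactly.
#'
#' Tissue labels: 0 background, 1 WM, 2 GM, 3 CSF, 4 lesion.
#'
#' @slot labels integer 3D array of tissue labels.
#' @slot truthAmplitude numeric 4D array (x, y, z, pool) of true amplitudes
#'   (before B1 scaling).
#' @slot fwhm,center named numeric(5), generative widths and centers.
#' @slot tissueMeans data.frame of the subject-level drawn tissue means.
#' @slot b0,b1,t1 numeric 3D arrays: true B0 (ppm), relative B1, T1 (ms).
#' @slot zStack numeric 4D array of raw signals (x, y, z, offset).
#' @slot reference numeric 3D array, raw signal at the reference offset.
#' @slot wassrStack numeric 4D array of normalized WASSR spectra.
#' @slot axis,wassrAxis \code{FrequencyAxis} of the main and WASSR grids.
#' @slot subject one-row data.frame: id, group, age, sex, diseaseDuration,
#'   lesionVolume.
#' @export
setClass("PhantomVolume",
  representation(
    labels = "array", truthAmplitude = "array",
    fwhm = "numeric", center = "numeric",
    tissueMeans = "data.frame",
    b0 = "array", b1 = "array", t1 = "array",
    zStack = "array", reference = "array", wassrStack = "array",
    axis = "FrequencyAxis", wassrAxis = "FrequencyAxis",
    subject = "data.frame"
  )
)

setValidity("PhantomVolume", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3L) return("labels must be a 3D array")
  if (!identical(dim(object@zStack)[1:3], d))
    return("zStack grid does not match labels grid")
  if (dim(object@zStack)[4] != length(object@axis@offsets))
    return("zStack must have one volume per axis offset")
  if (!identical(dim(object@reference), d))
    return("reference grid does not match labels grid")
  if (dim(object@wassrStack)[4] != length(object@wassrAxis@offsets))
    return("wassrStack must have one volume per WASSR offset")
  if (nrow(object@subject) != 1L)
    return("subject must be a one-row data.frame")
  TRUE
})

#' FitConfig: bounds, initial values and tolerances for the voxel fitter
#'
#' Rows of \code{init}, \code{lower} and \code{upper} are the parameters
#' (amplitude, fwhm, center); columns are the pools. Entries of \code{free}
#' mark which parameters float; fixed parameters are held at \code{init}.
#' The DS amplitude initial value is data-driven (0.8 * spectral depth)
#' regardless of its entry in \code{init}.
#'
#' @slot init,lower,upper numeric 3x5 matrices.
#' @slot free logical 3x5 matrix.
#' @slot maxIter integer(1), maximum Levenberg-Marquardt iterations.
#' @slot ftol,ptol numeric(1), convergence tolerances.
#' @slot failFactor numeric(1), a voxel is QC-failed when its residual norm
#'   exceeds failFactor times the in-mask median residual norm.
#' @export
setClass("FitConfig",
  representation(init = "matrix", lower = "matrix", upper = "matrix",
                 free = "matrix", maxIter = "integer",
                 ftol = "numeric", ptol = "numeric", failFactor = "numeric")
)

setValidity("FitConfig", function(object) {
  dims <- c(3L, 5L)
  for (sl in c("init", "lower", "upper", "free")) {
    m <- slot(object, sl)
    if (!identical(dim(m), dims))
      return(sprintf("%s must be a 3x5 matrix", sl))
  }
  if (any(object@init < object@lower | object@init > object@upper))
    return("bounds must contain the initial values")
  ctr <- object@init["center", ]
  if (any(ctr < object@lower["center", ] | ctr > object@upper["center", ]))
    return("nominal centers must lie within the center bounds")
  TRUE
})

#' PoolMaps: voxel-wise fitted parameters and derived contrast maps
#'
#' @slot amplitude,fwhm,center numeric 4D arrays (x, y, z, pool) of fitted
#'   parameters; NA outside the fitted mask.
#' @slot residual numeric 3D array of residual norms.
#' @slot converged logical 3D array.
#' @slot qcFail logical 3D array; TRUE where the fit failed QC.
#' @slot noeMtr numeric 3D array, NOE magnetization transfer ratio in percent.
#' @slot mask logical 3D array of fitted voxels.
#' @slot config the \code{FitConfig} used (provenance).
#' @export
setClass("PoolMaps",
  representation(amplitude = "array", fwhm = "array", center = "array",
                 residual = "array", converged = "array", qcFail = "array",
                 noeMtr = "array", mask = "array", config = "FitConfig")
)

setValidity("PoolMaps", function(object) {
  d <- dim(object@mask)
  if (length(d) != 3L) return("mask must be a 3D array")
  if (!identical(dim(object@amplitude), c(d, 5L)))
    return("amplitude must be a 4D (x, y, z, pool) array")
  TRUE
})
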