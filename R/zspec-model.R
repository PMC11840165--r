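#' Construct a frequency axis
#'
#' @param offsets numeric vector of saturation offsets in ppm, strictly
#'   increasing.
#' @param referenceOffset the far off-resonance normalization offset in ppm.
#' @return a \code{FrequencyAxis}.
#' @examples
#' ax <- frequencyAxis(seq(-5, 5, by = 0.2))
#' length(offsets(ax))  # 51
#' @export
frequencyAxis <- function(offsets, referenceOffset = 100) {
  new("FrequencyAxis", offsets = as.numeric(offsets),
      referenceOffset = as.numeric(referenceOffset))
}

#' Default acquisition grids
#'
#' \code{mainAxis} is the full Z-spectrum grid: -5 to +5 ppm in 0.2 ppm
#' steps (51 points) plus a 100 ppm reference acquisition. \code{wassrAxis}
#' is the water saturation shift referencing (WASSR) grid: -1 to +1 ppm in
#' 0.1 ppm steps (21 points).
#' @return a \code{FrequencyAxis}.
#' @export
mainAxis <- function() frequencyAxis(round(seq(-25, 25) * 0.2, 10), 100)

#' @rdname mainAxis
#' @export
wassrAxis <- function() frequencyAxis(round(seq(-10, 10) * 0.1, 10), 100)

#' @rdname offsets
#' @export
setMethod("offsets", "FrequencyAxis", function(x) x@offsets)

#' Axis accessors
#'
#' @param x a \code{FrequencyAxis} (or an object carrying one).
#' @return \code{offsets}: the numeric offset grid in ppm;
#'   \code{referenceOffset}: the normalization offset in ppm.
#' @name offsets
NULL

#' @rdname offsets
#' @export
setMethod("referenceOffset", "FrequencyAxis", function(x) x@referenceOffset)

setMethod("show", "FrequencyAxis", function(object) {
  o <- object@offsets
  cat(sprintf("FrequencyAxis: %d offsets, %.3g to %.3g ppm (reference %g ppm)\n",
              length(o), min(o), max(o), object@referenceOffset))
})

#' Construct a five-pool Lorentzian parameter set
#'
#' @param amplitude,fwhm,center numeric(5) in canonical pool order
#'   (\code{POOL_NAMES}), or named vectors in any order.
#' @return a \code{FivePoolParams}; the baseline is fixed at 1.
#' @examples
#' p <- fivePoolParams(amplitude = c(0.655, 0.10, 0.05, 0.039, 0.114),
#'                     fwhm = c(2, 25, 1, 1.5, 3),
#'                     center = c(0, -2, 3.5, 2.2, -3.5))
#' amplitudes(p)["rNOE"]
#' @export
fivePoolParams <- function(amplitude, fwhm, center = POOL_CENTERS) {
  canon <- function(v) {
    v <- unlist(v)
    if (!is.null(names(v)) && all(POOL_NAMES %in% names(v))) v <- v[POOL_NAMES]
    stats::setNames(as.numeric(v), POOL_NAMES)
  }
  new("FivePoolParams", amplitude = canon(amplitude), fwhm = canon(fwhm),
      center = canon(center), zBase = 1)
}

#' Pool parameter accessors
#'
#' @param x a \code{FivePoolParams} or \code{PoolMaps}.
#' @param ... unused.
#' @return named numeric(5) for \code{FivePoolParams}; a 4D array
#'   (x, y, z, pool) for \code{PoolMaps}.
#' @name poolAccessors
NULL

#' @rdname poolAccessors
#' @export
setMethod("amplitudes", "FivePoolParams", function(x, ...) x@amplitude)

#' @rdname poolAccessors
#' @export
setMethod("fwhms", "FivePoolParams", function(x, ...) x@fwhm)

#' @rdname poolAccessors
#' @export
setMethod("centers", "FivePoolParams", function(x, ...) x@center)

setMethod("show", "FivePoolParams", function(object) {
  cat("FivePoolParams (baseline fixed at 1)\n")
  print(round(rbind(amplitude = object@amplitude, fwhm = object@fwhm,
                    center = object@center), 4))
})

#' Construct a Z-spectrum
#'
#' @param values normalized signal per offset.
#' @param axis a \code{FrequencyAxis}.
#' @param referenceSignal raw signal at the reference offset.
#' @return a \code{ZSpectrum}.
#' @export
zSpectrum <- function(values, axis = mainAxis(), referenceSignal = 1) {
  new("ZSpectrum", axis = axis, values = as.numeric(values),
      referenceSignal = as.numeric(referenceSignal))
}

#' Z-spectrum values
#' @param x a \code{ZSpectrum}.
#' @return numeric vector of normalized signals, one per offset.
#' @name zvalues
NULL

#' @rdname zvalues
#' @export
setMethod("zValues", "ZSpectrum", function(x) x@values)

setMethod("show", "ZSpectrum", function(object) {
  cat(sprintf("ZSpectrum: %d offsets, min Z = %.4f at %+.2f ppm\n",
              length(object@values), min(object@values),
              object@axis@offsets[which.min(object@values)]))
})

#' Single Lorentzian line
#'
#' Evaluates one Lorentzian absorption line
#' \deqn{L(\Delta\omega) = A \frac{\Gamma^2/4}{\Gamma^2/4 +
#'   (\Delta\omega - \delta)^2}}
#' with amplitude \eqn{A}, full width at half maximum \eqn{\Gamma} (ppm) and
#' center \eqn{\delta} (ppm). The line peaks at \eqn{A} for
#' \eqn{\Delta\omega = \delta} and falls to \eqn{A/2} at
#' \eqn{\delta \pm \Gamma/2}.
#'
#' @param deltaOmega saturation offset(s) in ppm.
#' @param amplitude peak amplitude, in [0, 1].
#' @param fwhm full width at half maximum in ppm, positive.
#' @param center chemical shift of the line in ppm.
#' @return numeric, same length as \code{deltaOmega}.
#' @examples
#' lorentzian(0, 0.5, 2, 0)   # 0.5: peak equals amplitude
#' lorentzian(1, 0.5, 2, 0)   # 0.25: half maximum at half the FWHM
#' @export
lorentzian <- function(deltaOmega, amplitude, fwhm, center) {
  stopifnot(all(is.finite(deltaOmega)), is.finite(amplitude),
            is.finite(fwhm), is.finite(center),
            amplitude >= 0, amplitude <= 1, fwhm > 0)
  u <- fwhm^2 / 4
  amplitude * u / (u + (deltaOmega - center)^2)
}

#' Five-pool Lorentzian forward model
#'
#' Evaluates the Z-spectrum model
#' \deqn{Z(\Delta\omega) = Z_{base} - \sum_i L_i(\Delta\omega)}
#' on an offset grid, with the baseline fixed at 1. The reference acquisition
#' is treated as fully unsaturated (model value 1), so the returned spectrum
#' carries \code{referenceSignal = 1}.
#'
#' @param axis a \code{FrequencyAxis}.
#' @param params a \code{FivePoolParams}.
#' @return a \code{ZSpectrum} of the model evaluated at the axis offsets.
#'   A warning is raised if the summed pool deficit exceeds 1 anywhere
#'   (nonphysical parameter set driving Z below 0).
#' @export
zSpectrumForward <- function(axis, params) {
  stopifnot(is(axis, "FrequencyAxis"), is(params, "FivePoolParams"))
  validObject(params)
  deficit <- poolDeficit(axis@offsets, params@amplitude, params@fwhm,
                         params@center)
  if (any(deficit > 1 + 1e-12))
    warning("summed pool amplitudes exceed 1 at some offsets; Z < 0 ",
            "(nonphysical parameter set)")
  zSpectrum(params@zBase - deficit, axis, referenceSignal = 1)
}

# Sum of the five Lorentzian lines at the given offsets (vectorized over
# offsets; scalar pool parameters).
poolDeficit <- function(w, amplitude, fwhm, center) {
  out <- numeric(length(w))
  for (i in seq_along(amplitude)) {
    u <- fwhm[i]^2 / 4
    out <- out + amplitude[i] * u / (u + (w - center[i])^2)
  }
  out
}
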