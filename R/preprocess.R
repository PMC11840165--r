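#' Normalize a raw Z-stack by the reference acquisition
#'
#' Divides each offset image by the far off-resonance (100 ppm) reference
#' image voxel-wise: Z = S(offset) / S0. Voxels whose reference signal is
#' non-positive or below a signal floor are masked out.
#'
#' @param stack numeric 4D array (x, y, z, offset) of raw signals.
#' @param reference numeric 3D array of raw reference signals.
#' @param floor minimum admissible reference signal (same units); voxels at
#'   or below it are excluded from the mask.
#' @return list with \code{z} (4D normalized stack, NA outside the mask) and
#'   \code{mask} (logical 3D array of retained voxels).
#' @export
normalizeZStack <- function(stack, reference, floor = 0) {
  stopifnot(length(dim(stack)) == 4L, length(dim(reference)) == 3L)
  if (!identical(dim(stack)[1:3], dim(reference)))
    stop(sprintf("grid mismatch: stack is %s, reference is %s",
                 paste(dim(stack)[1:3], collapse = "x"),
                 paste(dim(reference), collapse = "x")))
  mask <- is.finite(reference) & reference > max(0, floor)
  nExcluded <- sum(!mask)
  z <- array(NA_real_, dim(stack))
  for (j in seq_len(dim(stack)[4])) {
    vol <- stack[, , , j]
    out <- array(NA_real_, dim(reference))
    out[mask] <- vol[mask] / reference[mask]
    z[, , , j] <- out
  }
  attr(z, "nExcluded") <- nExcluded
  list(z = z, mask = mask)
}

# Parabolic vertex of the WASSR minimum for one spectrum. Returns
# c(shift, flag): flag 0 ok, 1 edge minimum, 2 non-convex local fit.
wassrVertex <- function(values, w, window = 5L) {
  i0 <- which.min(values)
  n <- length(values)
  if (i0 == 1L || i0 == n) return(c(w[i0], 1))
  half <- (window - 1L) %/% 2L
  idx <- max(1L, i0 - half):min(n, i0 + half)
  x <- w[idx] - w[i0]
  fit <- stats::lm.fit(cbind(1, x, x^2), values[idx])
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || a <= 0) return(c(w[i0], 2))
  c(w[i0] - b / (2 * a), 0)
}

#' Estimate the per-voxel B0 offset from a WASSR acquisition
#'
#' Locates the water resonance in each voxel's low-power WASSR spectrum by
#' local interpolation to a second-order polynomial: a parabola is fit to a
#' 5-point window centered on the discrete minimum (clipped at grid edges)
#' and the vertex abscissa is the B0 shift. Voxels whose discrete minimum
#' sits at a grid edge, or whose local fit is non-convex, fall back to the
#' discrete argmin and are flagged.
#'
#' @param wassrStack 4D array (x, y, z, offset) of normalized WASSR spectra,
#'   or a numeric vector for a single voxel.
#' @param axis the WASSR \code{FrequencyAxis}.
#' @param mask optional logical 3D array restricting the estimate.
#' @param window odd window width for the local parabola (default 5).
#' @return for a vector input, a single shift (ppm) with attribute
#'   \code{flag}; for a stack, a list with \code{b0} (3D array, ppm) and
#'   \code{flags} (integer 3D array: 0 ok, 1 edge, 2 non-convex).
#' @export
estimateB0Wassr <- function(wassrStack, axis = wassrAxis(), mask = NULL,
                            window = 5L) {
  w <- offsets(axis)
  if (is.null(dim(wassrStack))) {
    stopifnot(length(wassrStack) == length(w), sum(is.finite(wassrStack)) >= 3)
    v <- wassrVertex(wassrStack, w, window)
    return(structure(v[1], flag = as.integer(v[2])))
  }
  stopifnot(length(dim(wassrStack)) == 4L, dim(wassrStack)[4] == length(w))
  d <- dim(wassrStack)[1:3]
  if (is.null(mask)) mask <- apply(is.finite(wassrStack), 1:3, all)
  b0 <- array(NA_real_, d)
  flags <- array(0L, d)
  idx <- which(mask)
  flat <- matrix(wassrStack, nrow = prod(d))
  for (i in idx) {
    v <- wassrVertex(flat[i, ], w, window)
    b0[i] <- v[1]
    flags[i] <- as.integer(v[2])
  }
  list(b0 = b0, flags = flags)
}

# Piecewise-cubic resampling of one spectrum at (offsets + shift), mapped
# back onto the nominal grid; out-of-range ends take the nearest edge value.
shiftResample <- function(values, w, shift) {
  target <- w + shift
  clamped <- pmin(pmax(target, min(w)), max(w))
  out <- stats::spline(w, values, xout = clamped, method = "fmm")$y
  edge <- target < min(w) | target > max(w)
  out[target < min(w)] <- values[1]
  out[target > max(w)] <- values[length(values)]
  attr(out, "edge") <- edge
  out
}

#' B0 correction of a Z-spectrum
#'
#' Undoes a per-voxel off-resonance shift by resampling the measured
#' spectrum at (nominal offsets + shift) with piecewise-cubic interpolation
#' and mapping the result back onto the nominal grid. Offsets that fall
#' outside the measured range are filled with the nearest edge value and
#' flagged.
#'
#' @param x a \code{ZSpectrum}, a numeric vector of values on the grid, or a
#'   4D stack (x, y, z, offset).
#' @param shift the B0 shift in ppm (scalar, or a 3D array for stacks).
#' @param axis the \code{FrequencyAxis} (vector/stack methods).
#' @param ... unused.
#' @return an object of the same form as \code{x}, corrected; vector results
#'   carry an \code{edge} attribute marking filled offsets.
#' @name correctB0
NULL

#' @rdname correctB0
#' @export
setMethod("correctB0", "ZSpectrum", function(x, shift, ...) {
  v <- shiftResample(x@values, offsets(x@axis), shift)
  out <- zSpectrum(as.numeric(v), x@axis, x@referenceSignal)
  attr(out, "edge") <- attr(v, "edge")
  out
})

#' @rdname correctB0
#' @export
setMethod("correctB0", "numeric", function(x, shift, axis = mainAxis(), ...) {
  shiftResample(x, offsets(axis), shift)
})

#' @rdname correctB0
#' @param fill stack method only: treatment of offsets that fall outside the
#'   measured range after shifting. \code{"na"} (default) marks them missing
#'   so that downstream fitting ignores them; \code{"nearest"} fills with the
#'   nearest edge value.
#' @export
setMethod("correctB0", "array", function(x, shift, axis = mainAxis(),
                                         fill = c("na", "nearest"), ...) {
  fill <- match.arg(fill)
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)[1:3]
  stopifnot(identical(dim(shift), d))
  w <- offsets(axis)
  flat <- matrix(x, nrow = prod(d))
  res <- matrix(NA_real_, nrow = prod(d), ncol = length(w))
  ok <- which(apply(is.finite(flat), 1, all) & is.finite(as.vector(shift)))
  sh <- as.vector(shift)
  for (i in ok) {
    v <- shiftResample(flat[i, ], w, sh[i])
    if (fill == "na") v[attr(v, "edge")] <- NA_real_
    res[i, ] <- v
  }
  array(res, dim(x))
})

#' B1 correction of fitted pool amplitudes
#'
#' First-order correction of transmit-field inhomogeneity: fitted pool
#' amplitudes are divided by the voxel's relative B1 (1 = nominal) and
#' clipped to [0, 1]. Applied after fitting, consistent with a saturation
#' efficiency that scales linearly with B1. Voxels with relative B1 below
#' the floor are masked (set NA).
#'
#' @param amplitude numeric array of fitted amplitudes: 3D (one pool) or 4D
#'   (x, y, z, pool).
#' @param b1 numeric 3D array of relative B1.
#' @param floor minimum admissible relative B1 (default 0.3).
#' @return corrected array of the same shape, with attribute
#'   \code{nMasked}: the number of voxels masked by the floor.
#' @export
correctB1 <- function(amplitude, b1, floor = 0.3) {
  stopifnot(all(b1[is.finite(b1)] > 0))
  d <- dim(amplitude)
  bad <- is.finite(b1) & b1 < floor
  fix <- function(a) {
    out <- pmin(pmax(a / b1, 0), 1)
    out[bad] <- NA_real_
    out
  }
  if (length(d) == 3L) {
    out <- fix(amplitude)
  } else if (length(d) == 4L) {
    out <- array(NA_real_, d)
    for (k in seq_len(d[4])) out[, , , k] <- fix(amplitude[, , , k])
  } else stop("amplitude must be a 3D or 4D array")
  attr(out, "nMasked") <- sum(bad)
  out
}

# 1D Gaussian kernel convolution along one margin of a 3D array, with
# kernel renormalization at the edges.
convolve1d <- function(vol, kernel, margin) {
  d <- dim(vol)
  n <- d[margin]
  half <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  wsum <- array(0, d)
  for (k in -half:half) {
    src <- seq_len(n) + k
    okDst <- which(src >= 1L & src <= n)
    okSrc <- src[okDst]
    idxD <- lapply(d, seq_len); idxD[[margin]] <- okDst
    idxS <- lapply(d, seq_len); idxS[[margin]] <- okSrc
    wt <- kernel[k + half + 1L]
    out[idxD[[1]], idxD[[2]], idxD[[3]]] <-
      out[idxD[[1]], idxD[[2]], idxD[[3]]] +
      wt * vol[idxS[[1]], idxS[[2]], idxS[[3]]]
    wsum[idxD[[1]], idxD[[2]], idxD[[3]]] <-
      wsum[idxD[[1]], idxD[[2]], idxD[[3]]] + wt
  }
  out / wsum
}

#' Pluggable denoising hook
#'
#' Spatial denoising applied per offset image before normalization and
#' fitting. Built-in methods: \code{"none"} (identity) and \code{"gaussian"}
#' (separable 3D Gaussian of the given width). A function of signature
#' \code{function(stack) stack} may be supplied as an external plugin.
#'
#' @param stack numeric 4D array (x, y, z, offset).
#' @param method \code{"none"}, \code{"gaussian"}, or a function.
#' @param sigma Gaussian width in voxels (scalar or length 3).
#' @return a 4D array of the same shape.
#' @export
denoiseHook <- function(stack, method = "none", sigma = 1) {
  if (is.function(method)) return(method(stack))
  if (identical(method, "none")) return(stack)
  if (!identical(method, "gaussian"))
    stop(sprintf("unknown denoising method '%s'", as.character(method)[1]))
  stopifnot(length(dim(stack)) == 4L)
  sigma <- rep(sigma, length.out = 3L)
  out <- stack
  for (m in 1:3) {
    if (sigma[m] <= 0) next
    half <- max(1L, ceiling(3 * sigma[m]))
    kern <- stats::dnorm(-half:half, sd = sigma[m])
    kern <- kern / sum(kern)
    for (j in seq_len(dim(stack)[4]))
      out[, , , j] <- convolve1d(out[, , , j], kern, m)
  }
  out
}
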