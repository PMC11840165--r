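#' Construct a fitter configuration
#'
#' Default bounds and initial values for the five-pool decomposition.
#' Amplitudes, widths (ppm) and centers (ppm) per pool:
#' \itemize{
#'   \item DS: A in [0, 1] (initial value data-driven, 0.8 x spectral depth),
#'     FWHM in [0.3, 10] init 2, center in [-0.2, 0.2] init 0;
#'   \item MT: A in [0, 0.5] init 0.1, FWHM in [10, 60] init 25, center fixed
#'     at -2;
#'   \item amide: A in [0, 0.3] init 0.05, FWHM in [0.4, 3] init 1, center in
#'     [3.4, 3.6];
#'   \item amine: A in [0, 0.3] init 0.03, FWHM in [0.4, 4] init 1.5, center
#'     in [2.1, 2.3];
#'   \item rNOE: A in [0, 0.5] init 0.1, FWHM in [1, 5] init 3, center in
#'     [-3.7, -3.3].
#' }
#' Narrow floats on the CEST/NOE line centers absorb residual off-resonance;
#' the broad MT center is held at its nominal -2 ppm.
#'
#' @param init,lower,upper optional 3x5 matrices (rows amplitude, fwhm,
#'   center; columns \code{POOL_NAMES}) overriding the defaults.
#' @param free optional logical 3x5 matrix marking floating parameters.
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol convergence tolerances.
#' @param failFactor QC threshold: residual norms above failFactor times the
#'   in-mask median are flagged as fit failures.
#' @return a \code{FitConfig}.
#' @export
fitConfig <- function(init = NULL, lower = NULL, upper = NULL, free = NULL,
                      maxIter = 100L, ftol = 1e-10, ptol = 1e-10,
                      failFactor = 5) {
  mk <- function(a, g, d) {
    m <- rbind(amplitude = a, fwhm = g, center = d)
    colnames(m) <- POOL_NAMES
    m
  }
  defInit <- mk(c(0.50, 0.10, 0.05, 0.03, 0.10),
                c(2, 25, 1, 1.5, 3),
                c(0, -2, 3.5, 2.2, -3.5))
  defLower <- mk(c(0, 0, 0, 0, 0),
                 c(0.3, 10, 0.4, 0.4, 1),
                 c(-0.2, -2, 3.4, 2.1, -3.7))
  defUpper <- mk(c(1, 0.5, 0.3, 0.3, 0.5),
                 c(10, 60, 3, 4, 5),
                 c(0.2, -2, 3.6, 2.3, -3.3))
  defFree <- matrix(TRUE, 3, 5, dimnames = dimnames(defInit))
  defFree["center", "MT"] <- FALSE
  new("FitConfig",
      init = if (is.null(init)) defInit else init,
      lower = if (is.null(lower)) defLower else lower,
      upper = if (is.null(upper)) defUpper else upper,
      free = if (is.null(free)) defFree else free,
      maxIter = as.integer(maxIter), ftol = ftol, ptol = ptol,
      failFactor = failFactor)
}

# Residual and analytic Jacobian closures for one spectrum. th is the 3x5
# parameter matrix flattened column-wise (A1, G1, C1, A2, ...).
makeObjective <- function(w, zObs, template, freeIdx) {
  nw <- length(w)
  fn <- function(par) {
    th <- template
    th[freeIdx] <- par
    r <- zObs - 1
    for (i in 0:4) {
      A <- th[3 * i + 1]; G <- th[3 * i + 2]; C <- th[3 * i + 3]
      u <- G * G / 4
      r <- r + A * u / (u + (w - C)^2)
    }
    r
  }
  jac <- function(par) {
    th <- template
    th[freeIdx] <- par
    J <- matrix(0, nw, 15L)
    for (i in 0:4) {
      A <- th[3 * i + 1]; G <- th[3 * i + 2]; C <- th[3 * i + 3]
      u <- G * G / 4
      d <- w - C
      den <- u + d * d
      J[, 3 * i + 1] <- u / den
      J[, 3 * i + 2] <- A * d * d * (G / 2) / (den * den)
      J[, 3 * i + 3] <- 2 * A * u * d / (den * den)
    }
    J[, freeIdx, drop = FALSE]
  }
  list(fn = fn, jac = jac)
}

#' Fit the five-pool model to one Z-spectrum
#'
#' Minimizes the sum of squared differences between the observed normalized
#' spectrum and the model \eqn{1 - \sum_i L_i} over the main offset grid, by
#' Levenberg-Marquardt least squares with box bounds
#' (\code{minpack.lm::nls.lm}, analytic Jacobian). The baseline is held at
#' 1; the reference acquisition takes no part in the residual. The DS
#' amplitude starts at 0.8 times the spectral depth (1 - min Z) unless an
#' explicit initialization is supplied.
#'
#' @param z a \code{ZSpectrum} or a numeric vector of normalized values on
#'   the grid (assumed B0-corrected).
#' @param axis the \code{FrequencyAxis} (used when \code{z} is numeric).
#' @param cfg a \code{FitConfig}.
#' @param init optional \code{FivePoolParams} to initialize at (e.g. a known
#'   truth); clipped into the bounds.
#' @return list with \code{params} (\code{FivePoolParams}), \code{residual}
#'   (residual norm, sqrt of the summed squared residuals), \code{converged}
#'   (logical) and \code{info} (optimizer status code). Offsets marked
#'   missing (e.g. ends invalidated by the B0 shift) are dropped from the
#'   residual; a spectrum with fewer than 20 valid points returns NULL
#'   (masked voxel).
#' @export
fitVoxel <- function(z, axis = mainAxis(), cfg = fitConfig(), init = NULL) {
  if (is(z, "ZSpectrum")) {
    axis <- z@axis
    z <- z@values
  }
  w <- offsets(axis)
  stopifnot(length(z) == length(w))
  keep <- is.finite(z)
  if (sum(keep) < 20L) return(NULL)
  w <- w[keep]
  z <- z[keep]

  start <- cfg@init
  start["amplitude", "DS"] <- min(max(0.8 * (1 - min(z)),
                                      cfg@lower["amplitude", "DS"]),
                                  cfg@upper["amplitude", "DS"])
  if (!is.null(init)) {
    start <- rbind(amplitude = init@amplitude, fwhm = init@fwhm,
                   center = init@center)
    start <- pmin(pmax(start, cfg@lower), cfg@upper)
  }
  freeIdx <- which(cfg@free)
  obj <- makeObjective(w, z, as.vector(start), freeIdx)
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = as.vector(start)[freeIdx], fn = obj$fn, jac = obj$jac,
    lower = as.vector(cfg@lower)[freeIdx],
    upper = as.vector(cfg@upper)[freeIdx],
    control = minpack.lm::nls.lm.control(maxiter = cfg@maxIter,
                                         ftol = cfg@ftol, ptol = cfg@ptol)))
  th <- as.vector(start)
  th[freeIdx] <- fit$par
  th <- matrix(th, 3, 5, dimnames = dimnames(cfg@init))
  params <- fivePoolParams(th["amplitude", ], th["fwhm", ], th["center", ])
  list(params = params,
       residual = sqrt(fit$deviance),
       converged = fit$info %in% 1:4,
       info = fit$info)
}

#' Fit the five-pool model voxel-wise over a volume
#'
#' Applies \code{\link{fitVoxel}} to every masked voxel of a normalized,
#' B0-corrected 4D stack. Voxels are visited in a fixed order and the fit is
#' fully deterministic given the inputs and configuration, so the result is
#' independent of any scheduling. After fitting, voxels whose residual norm
#' exceeds \code{failFactor} times the in-mask median residual norm, or that
#' failed to converge, are QC-flagged; the NOE magnetization transfer ratio
#' map (percent) is derived from the normalized signal at -3.5 ppm.
#'
#' @param stack numeric 4D array (x, y, z, offset) of normalized spectra.
#' @param axis the \code{FrequencyAxis}.
#' @param cfg a \code{FitConfig}.
#' @param mask logical 3D array of voxels to fit; defaults to voxels with
#'   all-finite spectra.
#' @return a \code{PoolMaps}.
#' @export
fitVolume <- function(stack, axis = mainAxis(), cfg = fitConfig(),
                      mask = NULL) {
  stopifnot(length(dim(stack)) == 4L)
  d <- dim(stack)[1:3]
  w <- offsets(axis)
  stopifnot(dim(stack)[4] == length(w))
  if (is.null(mask)) mask <- apply(is.finite(stack), 1:3, sum) >= 20L

  dn <- list(NULL, NULL, NULL, POOL_NAMES)
  amp <- array(NA_real_, c(d, 5L), dimnames = dn)
  gam <- array(NA_real_, c(d, 5L), dimnames = dn)
  ctr <- array(NA_real_, c(d, 5L), dimnames = dn)
  res <- array(NA_real_, d)
  conv <- array(NA, d)

  nvox <- prod(d)
  flat <- matrix(stack, nrow = nvox)
  idx <- which(mask)
  freeIdx <- which(cfg@free)
  lower <- as.vector(cfg@lower)[freeIdx]
  upper <- as.vector(cfg@upper)[freeIdx]
  ctl <- minpack.lm::nls.lm.control(maxiter = cfg@maxIter, ftol = cfg@ftol,
                                    ptol = cfg@ptol)
  aDSlo <- cfg@lower["amplitude", "DS"]
  aDShi <- cfg@upper["amplitude", "DS"]
  startV <- as.vector(cfg@init)

  for (i in idx) {
    z <- flat[i, ]
    keep <- is.finite(z)
    if (sum(keep) < 20L) next
    zi <- z[keep]
    sv <- startV
    sv[1] <- min(max(0.8 * (1 - min(zi)), aDSlo), aDShi)
    obj <- makeObjective(w[keep], zi, sv, freeIdx)
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par = sv[freeIdx], fn = obj$fn, jac = obj$jac,
                         lower = lower, upper = upper, control = ctl))
    th <- sv
    th[freeIdx] <- fit$par
    k <- i + (0:4) * nvox
    amp[k] <- th[c(1, 4, 7, 10, 13)]
    gam[k] <- th[c(2, 5, 8, 11, 14)]
    ctr[k] <- th[c(3, 6, 9, 12, 15)]
    res[i] <- sqrt(fit$deviance)
    conv[i] <- fit$info %in% 1:4
  }

  medRes <- stats::median(res[mask], na.rm = TRUE)
  qcFail <- array(FALSE, d)
  qcFail[mask] <- !isTRUE0(conv[mask]) | res[mask] > cfg@failFactor * medRes
  qcFail[!mask] <- FALSE

  s35 <- signalAtOffset(stack, w, -3.5)
  noe <- array(NA_real_, d)
  noe[mask] <- 100 * (1 - s35[mask])

  new("PoolMaps", amplitude = amp, fwhm = gam, center = ctr, residual = res,
      converged = conv, qcFail = qcFail, noeMtr = noe, mask = mask,
      config = cfg)
}

# elementwise "is TRUE" for logical vectors with NA
isTRUE0 <- function(x) !is.na(x) & x

#' Signal at a given offset from a sampled stack
#'
#' Extracts the per-voxel signal at a target offset. When the target sits on
#' the sampled grid that image is returned directly; otherwise the four
#' nearest offsets are combined with cubic Lagrange weights (the standard
#' -5..5 ppm grid in 0.2 ppm steps does not sample -3.5 ppm itself, so the
#' NOE_MTR readout is interpolated between -3.6 and -3.4 ppm).
#'
#' @param stack numeric 4D array (x, y, z, offset).
#' @param w numeric vector of sampled offsets (ppm).
#' @param x0 target offset (ppm), inside the sampled range.
#' @return numeric 3D array of the per-voxel signal at \code{x0}.
#' @export
signalAtOffset <- function(stack, w, x0) {
  stopifnot(length(dim(stack)) == 4L, dim(stack)[4] == length(w),
            x0 >= min(w), x0 <= max(w))
  d3 <- dim(stack)[1:3]
  grab <- function(j) array(stack[, , , j, drop = FALSE], d3)
  hit <- which(abs(w - x0) < 1e-9)
  if (length(hit) == 1L) return(grab(hit))
  near <- sort(order(abs(w - x0))[1:4])
  wt <- vapply(seq_along(near), function(i) {
    others <- near[-i]
    prod((x0 - w[others]) / (w[near[i]] - w[others]))
  }, numeric(1))
  out <- array(0, d3)
  for (i in seq_along(near)) out <- out + wt[i] * grab(near[i])
  out
}

#' NOE magnetization transfer ratio
#'
#' \deqn{NOE_{MTR} = \frac{S_0 - S(-3.5\,ppm)}{S_0} \times 100}
#' where \eqn{S_0} is the reference (100 ppm) signal. Voxels with
#' non-positive \eqn{S_0} are masked (NA).
#'
#' @param s0 reference signal (scalar or array).
#' @param sM35 signal at -3.5 ppm (same shape).
#' @return NOE_MTR in percent.
#' @examples
#' noeMtr(1, 0.75)  # 25
#' @export
noeMtr <- function(s0, sM35) {
  out <- (s0 - sM35) / s0 * 100
  out[!is.finite(s0) | s0 <= 0] <- NA_real_
  out
}

#' @rdname poolAccessors
#' @export
setMethod("amplitudes", "PoolMaps", function(x, ...) x@amplitude)

#' @rdname poolAccessors
#' @export
setMethod("fwhms", "PoolMaps", function(x, ...) x@fwhm)

#' @rdname poolAccessors
#' @export
setMethod("centers", "PoolMaps", function(x, ...) x@center)

#' @rdname noeMtrMap
#' @export
setMethod("noeMtrMap", "PoolMaps", function(x) x@noeMtr)

#' NOE_MTR map accessor
#' @param x a \code{PoolMaps}.
#' @return numeric 3D array, NOE_MTR in percent.
#' @name noeMtrMap
NULL

setMethod("show", "PoolMaps", function(object) {
  d <- dim(object@mask)
  cat(sprintf("PoolMaps: %d x %d x %d, %d fitted voxels (%d QC failures)\n",
              d[1], d[2], d[3], sum(object@mask), sum(object@qcFail)))
  med <- apply(matrix(object@amplitude, ncol = 5L), 2, stats::median,
               na.rm = TRUE)
  names(med) <- POOL_NAMES
  cat("  median amplitudes: ",
      paste(sprintf("%s %.3f", POOL_NAMES, med), collapse = ", "), "\n")
})
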