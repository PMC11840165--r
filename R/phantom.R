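#' Default tissue parameter priors
#'
#' Per-tissue, per-group priors (mean and SD across subjects) for the five
#' pool amplitudes and for T1. White-matter, lesion and grey-matter rNOE/amine/
#' DS/T1 values encode the group means and standard deviations reported for
#' the MS and control cohorts; MT and amide amplitudes and the CSF and
#' grey-matter DS/T1 rows are not reported at that granularity and carry
#' package defaults chosen to be physiologically plausible at 7T (documented
#' in the methods vignette, tunable here).
#'
#' Tissue "WM" under group "MS" is normal-appearing white matter (NAWM);
#' "GM" under "MS" is normal-appearing grey matter (NAGM). Lesions exist only
#' in the MS group.
#'
#' @return data.frame with one row per (tissue, group) and columns
#'   \code{<pool>_mean}, \code{<pool>_sd} for each of \code{POOL_NAMES},
#'   plus \code{t1_mean}, \code{t1_sd} (ms).
#' @export
defaultTissuePriors <- function() {
  row <- function(tissue, group, DS, MT, amide, amine, rNOE, t1) {
    data.frame(tissue = tissue, group = group,
               DS_mean = DS[1], DS_sd = DS[2],
               MT_mean = MT[1], MT_sd = MT[2],
               amide_mean = amide[1], amide_sd = amide[2],
               amine_mean = amine[1], amine_sd = amine[2],
               rNOE_mean = rNOE[1], rNOE_sd = rNOE[2],
               t1_mean = t1[1], t1_sd = t1[2],
               stringsAsFactors = FALSE)
  }
  rbind(
    row("WM", "control", DS = c(0.655, 0.021), MT = c(0.10, 0.02),
        amide = c(0.050, 0.010), amine = c(0.039, 0.007),
        rNOE = c(0.114, 0.014), t1 = c(1154.6, 31.7)),
    row("WM", "MS", DS = c(0.660, 0.009), MT = c(0.10, 0.02),
        amide = c(0.050, 0.010), amine = c(0.033, 0.006),
        rNOE = c(0.101, 0.007), t1 = c(1197.3, 31.8)),
    row("GM", "control", DS = c(0.620, 0.020), MT = c(0.08, 0.02),
        amide = c(0.045, 0.010), amine = c(0.036, 0.006),
        rNOE = c(0.094, 0.012), t1 = c(1900, 120)),
    row("GM", "MS", DS = c(0.620, 0.020), MT = c(0.08, 0.02),
        amide = c(0.045, 0.010), amine = c(0.034, 0.006),
        rNOE = c(0.085, 0.012), t1 = c(1900, 120)),
    row("lesion", "MS", DS = c(0.703, 0.040), MT = c(0.08, 0.02),
        amide = c(0.050, 0.010), amine = c(0.032, 0.007),
        rNOE = c(0.076, 0.019), t1 = c(1600.7, 269.7)),
    row("CSF", "control", DS = c(0.800, 0.030), MT = c(0.010, 0.005),
        amide = c(0.005, 0.003), amine = c(0.005, 0.003),
        rNOE = c(0.010, 0.005), t1 = c(4000, 200)),
    row("CSF", "MS", DS = c(0.800, 0.030), MT = c(0.010, 0.005),
        amide = c(0.005, 0.003), amine = c(0.005, 0.003),
        rNOE = c(0.010, 0.005), t1 = c(4000, 200))
  )
}

#' Default demographic priors
#'
#' Cohort demographics: 15 MS subjects (age 43.7 +/- 14.7 y, range 21-70,
#' 10 F / 5 M), 10 controls (age 40.9 +/- 16.9 y, range 23-71, 5 F / 5 M),
#' disease duration 6.5 +/- 6.6 y and in-slab lesion volume 1.2 +/- 1.4 cm^3
#' (both truncated at zero, zero for controls).
#' @return named list of demographic priors.
#' @export
defaultDemographics <- function() {
  list(
    age = list(MS = c(mean = 43.7, sd = 14.7, min = 21, max = 70),
               control = c(mean = 40.9, sd = 16.9, min = 23, max = 71)),
    sexFemaleProb = c(MS = 10 / 15, control = 5 / 10),
    diseaseDuration = c(mean = 6.5, sd = 6.6),
    lesionVolume = c(mean = 1.2, sd = 1.4)
  )
}

#' Construct a phantom specification
#'
#' Configures the synthetic cohort generator. Defaults encode the study
#' conditions: 15 MS and 10 control subjects with the published demographic
#' and tissue priors, a 64 x 64 x 10 grid at 1 x 1 x 2 mm emulating the
#' acquired slab at desk scale, smooth polynomial B0 (max 0.3 ppm) and
#' relative-B1 (0.7-1.15) fields, and additive Gaussian noise of SD 0.002
#' on normalized Z.
#'
#' @param dim integer(3) grid shape.
#' @param voxelSize numeric(3) voxel size in mm.
#' @param nMS,nControl subjects per group.
#' @param demographics demographic priors, see \code{\link{defaultDemographics}}.
#' @param priors tissue priors, see \code{\link{defaultTissuePriors}}.
#' @param fwhm,center generative line widths and centers (named, canonical
#'   pool order).
#' @param b0Max maximum absolute B0 offset (ppm).
#' @param b1Range range of the relative B1 field.
#' @param noiseSD additive Gaussian noise SD on normalized Z.
#' @param jitterSD voxel-level pool-amplitude jitter SD.
#' @param t1JitterSD voxel-level T1 jitter SD (ms).
#' @param wassrAmplitude,wassrFwhm direct-saturation line of the low-power
#'   WASSR acquisition (amplitude, FWHM in ppm).
#' @param durationCoupling couple lesion T1 to disease duration?
#' @param durationSlope lesion-T1 slope (ms per year) when coupling is on.
#' @param referenceSignal raw S0 level inside the brain (arbitrary units).
#' @param seed integer seed; fully determines a simulated cohort.
#' @return a \code{PhantomSpec}.
#' @export
phantomSpec <- function(dim = c(64L, 64L, 10L), voxelSize = c(1, 1, 2),
                        nMS = 15L, nControl = 10L,
                        demographics = defaultDemographics(),
                        priors = defaultTissuePriors(),
                        fwhm = c(DS = 2, MT = 25, amide = 1, amine = 1.5,
                                 rNOE = 3),
                        center = POOL_CENTERS,
                        b0Max = 0.3, b1Range = c(0.7, 1.15),
                        noiseSD = 0.002, jitterSD = 0.002, t1JitterSD = 20,
                        wassrAmplitude = 0.9, wassrFwhm = 0.5,
                        durationCoupling = FALSE, durationSlope = 24.34,
                        referenceSignal = 1000, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
      nMS = as.integer(nMS), nControl = as.integer(nControl),
      demographics = demographics, priors = priors,
      fwhm = fwhm[POOL_NAMES], center = center[POOL_NAMES],
      b0Max = b0Max, b1Range = as.numeric(b1Range),
      noiseSD = noiseSD, jitterSD = jitterSD, t1JitterSD = t1JitterSD,
      wassrAmplitude = wassrAmplitude, wassrFwhm = wassrFwhm,
      durationCoupling = durationCoupling, durationSlope = durationSlope,
      referenceSignal = referenceSignal, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d grid (%g x %g x %g mm), %d MS / %d control subjects\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@nMS, object@nControl))
  cat(sprintf("  B0 max %g ppm; B1 %g-%g; noise SD %g; seed %d\n",
              object@b0Max, object@b1Range[1], object@b1Range[2],
              object@noiseSD, object@seed))
})

# Truncated-normal draws by resampling (not clipping), preserving the mean
# of the untruncated distribution inside the bounds.
rnormTrunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:1000) {
    out[need] <- stats::rnorm(length(need), mean, sd)
    need <- which(out < lower | out > upper)
    if (length(need) == 0L) return(out)
  }
  stop("truncated-normal resampling failed to converge; check bounds")
}

#' Draw a synthetic subject record
#'
#' Draws demographics from the group's priors using the current RNG state.
#' Ages are drawn from a normal prior truncated (by resampling) to the
#' group's published range; disease duration and lesion volume are truncated
#' at zero and are identically zero for controls.
#'
#' @param spec a \code{PhantomSpec}.
#' @param group \code{"MS"} or \code{"control"}.
#' @param id subject identifier.
#' @return one-row data.frame: id, group, age, sex, diseaseDuration (years),
#'   lesionVolume (cm^3).
#' @export
drawSubject <- function(spec, group = c("MS", "control"), id = "sub-01") {
  group <- match.arg(group)
  dem <- spec@demographics
  a <- dem$age[[group]]
  age <- rnormTrunc(1, a["mean"], a["sd"], a["min"], a["max"])
  sex <- if (stats::runif(1) < dem$sexFemaleProb[[group]]) "F" else "M"
  if (group == "MS") {
    dd <- rnormTrunc(1, dem$diseaseDuration["mean"],
                     dem$diseaseDuration["sd"], lower = 0)
    lv <- rnormTrunc(1, dem$lesionVolume["mean"],
                     dem$lesionVolume["sd"], lower = 0)
  } else {
    dd <- 0
    lv <- 0
  }
  data.frame(id = id, group = group, age = age, sex = sex,
             diseaseDuration = dd, lesionVolume = lv,
             stringsAsFactors = FALSE)
}

#' Disease-duration coupling of lesion T1
#'
#' When coupling is enabled in the spec, the lesion T1 prior mean is shifted
#' by \code{durationSlope} (ms per year, default 24.34) times the subject's
#' disease duration. Off by default; with coupling off, or for a subject with
#' zero duration, the priors are returned unchanged.
#'
#' @param spec a \code{PhantomSpec}.
#' @param subject a subject record from \code{\link{drawSubject}}.
#' @return the spec's priors data.frame, with the lesion \code{t1_mean}
#'   adjusted when applicable.
#' @export
durationAdjustedPriors <- function(spec, subject) {
  pr <- spec@priors
  if (isTRUE(spec@durationCoupling)) {
    i <- pr$tissue == "lesion" & pr$group == subject$group
    pr$t1_mean[i] <- pr$t1_mean[i] + spec@durationSlope * subject$diseaseDuration
  }
  pr
}

# Normalized ellipsoidal radius for every voxel of the grid: 0 at the brain
# center, 1 at the brain surface.
phantomRadius <- function(dim) {
  cx <- (dim + 1) / 2
  ax <- c(0.45 * dim[1], 0.45 * dim[2], 0.48 * dim[3])
  x <- (seq_len(dim[1]) - cx[1]) / ax[1]
  y <- (seq_len(dim[2]) - cx[2]) / ax[2]
  z <- (seq_len(dim[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  sqrt(r2)
}

# Tissue label geometry: ellipsoidal brain with an outer GM shell, WM
# interior and a central CSF (ventricle) compartment.
phantomLabels <- function(dim) {
  r <- phantomRadius(dim)
  lab <- array(0L, dim)
  lab[r <= 1] <- 2L            # GM shell
  lab[r <= 0.8] <- 1L          # WM interior
  lab[r <= 0.25] <- 3L         # central CSF
  lab
}

# Smooth random low-order polynomial field over the grid, zero-mean-ish,
# scaled so that max |field| over the brain equals `scale`.
smoothField <- function(dim, brain, scale) {
  X <- (seq_len(dim[1]) - (dim[1] + 1) / 2) / (dim[1] / 2)
  Y <- (seq_len(dim[2]) - (dim[2] + 1) / 2) / (dim[2] / 2)
  Z <- (seq_len(dim[3]) - (dim[3] + 1) / 2) / (dim[3] / 2)
  co <- stats::rnorm(7)
  xg <- array(rep(X, times = dim[2] * dim[3]), dim)
  yg <- array(rep(rep(Y, each = dim[1]), times = dim[3]), dim)
  zg <- array(rep(Z, each = dim[1] * dim[2]), dim)
  f <- co[1] * 0.3 + co[2] * xg + co[3] * yg + co[4] * 0.5 * zg +
    co[5] * xg * yg + co[6] * (xg^2 - 1 / 3) + co[7] * (yg^2 - 1 / 3)
  m <- max(abs(f[brain]))
  if (m == 0) f else f * (scale / m)
}

# Place lesions as spheres at uniformly drawn deep-WM centers until the
# lesion voxel count matches the target exactly (the last sphere is trimmed
# by distance). Returns linear voxel indices.
placeLesions <- function(dim, voxelSize, labels, radius, targetVoxels) {
  if (targetVoxels <= 0L) return(integer())
  wm <- which(labels == 1L)
  deep <- which(labels == 1L & radius > 0.3 & radius < 0.72)
  if (length(wm) < targetVoxels) {
    scale <- (targetVoxels / length(wm))^(1 / 3)
    stop(sprintf(paste0("grid too small: lesion of %d voxels exceeds the ",
                        "%d available WM voxels; increase the grid to at ",
                        "least %d x %d x %d"),
                 targetVoxels, length(wm),
                 ceiling(dim[1] * scale), ceiling(dim[2] * scale),
                 ceiling(dim[3] * scale)))
  }
  coords <- arrayInd(wm, dim)
  mm <- sweep(coords, 2, voxelSize, `*`)
  lesion <- integer()
  inLesion <- logical(length(wm))
  while (sum(inLesion) < targetVoxels) {
    ctr <- if (length(deep) > 0) deep[sample.int(length(deep), 1)]
           else wm[sample.int(length(wm), 1)]
    cmm <- arrayInd(ctr, dim)[1, ] * voxelSize
    rad <- stats::runif(1, 2.5, 5)   # mm
    d2 <- (mm[, 1] - cmm[1])^2 + (mm[, 2] - cmm[2])^2 + (mm[, 3] - cmm[3])^2
    hit <- which(!inLesion & d2 <= rad^2)
    need <- targetVoxels - sum(inLesion)
    if (length(hit) > need) hit <- hit[order(d2[hit])][seq_len(need)]
    inLesion[hit] <- TRUE
  }
  wm[inLesion]
}

#' Build one simulated subject volume
#'
#' Generates the full synthetic acquisition for one subject from the current
#' RNG state: tissue labels on an ellipsoidal brain (outer GM shell, WM
#' interior, central CSF, spherical WM lesions matching the subject's drawn
#' lesion volume), subject-level tissue parameter draws plus voxel jitter,
#' smooth B0 and relative-B1 fields, the raw Z-stack (forward model evaluated
#' at offsets shifted by the voxel's B0, amplitudes scaled by its B1, noise
#' added on normalized Z, multiplied by the reference signal), the reference
#' image, and a normalized WASSR stack (narrow direct-saturation line with
#' the same B0 shift).
#'
#' @param spec a \code{PhantomSpec}.
#' @param subject a subject record from \code{\link{drawSubject}}.
#' @param axis,wassr frequency axes of the main and WASSR acquisitions.
#' @return a \code{PhantomVolume} carrying the data and its ground truth.
#' @export
buildVolume <- function(spec, subject, axis = mainAxis(), wassr = wassrAxis()) {
  dim <- spec@dim
  vox <- prod(spec@voxelSize)
  labels <- phantomLabels(dim)
  radius <- phantomRadius(dim)

  targetVoxels <- as.integer(round(subject$lesionVolume * 1000 / vox))
  lesionIdx <- placeLesions(dim, spec@voxelSize, labels, radius, targetVoxels)
  labels[lesionIdx] <- 4L

  pr <- durationAdjustedPriors(spec, subject)
  tissues <- c("1" = "WM", "2" = "GM", "3" = "CSF", "4" = "lesion")
  present <- tissues[as.character(sort(unique(labels[labels > 0L])))]
  # lesion priors exist only for the MS group
  grp <- function(tis) if (tis == "lesion") "MS" else subject$group

  means <- do.call(rbind, lapply(present, function(tis) {
    p <- pr[pr$tissue == tis & pr$group == grp(tis), ]
    amp <- vapply(POOL_NAMES, function(pool) {
      rnormTrunc(1, p[[paste0(pool, "_mean")]], p[[paste0(pool, "_sd")]],
                 lower = 0, upper = 1)
    }, numeric(1))
    t1 <- rnormTrunc(1, p$t1_mean, p$t1_sd, lower = 1)
    data.frame(tissue = tis, t(amp), t1 = t1, stringsAsFactors = FALSE)
  }))
  rownames(means) <- means$tissue

  brain <- labels > 0L
  nb <- sum(brain)
  labBrain <- tissues[as.character(labels[brain])]

  ampMeanMat <- as.matrix(means[, POOL_NAMES])
  t1Mean <- stats::setNames(means$t1, means$tissue)
  truthAmp <- array(NA_real_, c(dim, 5L),
                    dimnames = list(NULL, NULL, NULL, POOL_NAMES))
  t1map <- array(NA_real_, dim)
  for (k in seq_along(POOL_NAMES)) {
    v <- array(NA_real_, dim)
    mu <- ampMeanMat[labBrain, k]
    v[brain] <- pmin(pmax(mu + stats::rnorm(nb, 0, spec@jitterSD), 0), 1)
    truthAmp[, , , k] <- v
  }
  t1map[brain] <- pmax(t1Mean[labBrain] +
                         stats::rnorm(nb, 0, spec@t1JitterSD), 1)

  b0 <- smoothField(dim, brain, spec@b0Max * stats::runif(1, 0.6, 1))
  b1raw <- smoothField(dim, brain, 1)
  rng <- range(b1raw[brain])
  b1 <- spec@b1Range[1] + (b1raw - rng[1]) / (rng[2] - rng[1]) *
    diff(spec@b1Range)
  b1[!brain] <- 1

  # forward synthesis, vectorized over voxels offset-by-offset
  w <- offsets(axis)
  nOff <- length(w)
  zStack <- array(0, c(dim, nOff))
  ampEff <- lapply(seq_len(5L), function(k) {
    a <- truthAmp[, , , k][brain] * b1[brain]
    pmin(pmax(a, 0), 1)
  })
  u <- spec@fwhm^2 / 4
  b0b <- b0[brain]
  for (j in seq_len(nOff)) {
    z <- rep(1, nb)
    for (k in seq_len(5L)) {
      z <- z - ampEff[[k]] * u[k] /
        (u[k] + (w[j] - b0b - spec@center[k])^2)
    }
    if (spec@noiseSD > 0) z <- z + stats::rnorm(nb, 0, spec@noiseSD)
    vol <- array(0, dim)
    vol[brain] <- z * spec@referenceSignal
    zStack[, , , j] <- vol
  }
  reference <- array(0, dim)
  reference[brain] <- spec@referenceSignal

  ww <- offsets(wassr)
  uw <- spec@wassrFwhm^2 / 4
  wassrStack <- array(0, c(dim, length(ww)))
  for (j in seq_along(ww)) {
    z <- 1 - spec@wassrAmplitude * uw / (uw + (ww[j] - b0b)^2)
    if (spec@noiseSD > 0) z <- z + stats::rnorm(nb, 0, spec@noiseSD)
    vol <- array(NA_real_, dim)
    vol[brain] <- z
    wassrStack[, , , j] <- vol
  }

  new("PhantomVolume", labels = labels, truthAmplitude = truthAmp,
      fwhm = spec@fwhm, center = spec@center, tissueMeans = means,
      b0 = b0, b1 = b1, t1 = t1map, zStack = zStack, reference = reference,
      wassrStack = wassrStack, axis = axis, wassrAxis = wassr,
      subject = subject)
}

#' @rdname tissueLabels
#' @export
setMethod("tissueLabels", "PhantomVolume", function(x) x@labels)

#' Ground-truth tissue labels
#' @param x a \code{PhantomVolume}.
#' @return integer 3D array (0 background, 1 WM, 2 GM, 3 CSF, 4 lesion).
#' @name tissueLabels
NULL

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = 0:4,
                      labels = c("background", "WM", "GM", "CSF", "lesion")))
  cat(sprintf("PhantomVolume: %d x %d x %d, subject %s (%s)\n",
              d[1], d[2], d[3], object@subject$id, object@subject$group))
  print(tab)
})

#' Simulate a full cohort
#'
#' Draws \code{nMS + nControl} subjects and builds one \code{PhantomVolume}
#' per subject. The spec's seed fully determines the output.
#'
#' @param spec a \code{PhantomSpec}.
#' @param axis,wassr frequency axes passed to \code{\link{buildVolume}}.
#' @return named list with \code{volumes} (list of \code{PhantomVolume}) and
#'   \code{subjects} (data.frame of all subject records).
#' @export
simulateCohort <- function(spec, axis = mainAxis(), wassr = wassrAxis()) {
  set.seed(spec@seed)
  groups <- c(rep("MS", spec@nMS), rep("control", spec@nControl))
  ids <- sprintf("sub-%02d", seq_along(groups))
  volumes <- vector("list", length(groups))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    s <- drawSubject(spec, groups[i], ids[i])
    volumes[[i]] <- buildVolume(spec, s, axis, wassr)
    subjects[[i]] <- s
  }
  list(volumes = stats::setNames(volumes, ids),
       subjects = do.call(rbind, subjects))
}
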