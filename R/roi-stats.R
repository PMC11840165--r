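TISSUE_LEVELS <- c(background = 0L, WM = 1L, GM = 2L, CSF = 3L, lesion = 4L)

#' Segment tissue classes from a T1 map
#'
#' Labels brain voxels by T1 range: WM below \code{wmMax}, GM between
#' \code{wmMax} and \code{gmMax}, CSF above \code{gmMax}. A lesion mask, when
#' provided, overrides the T1-derived labels (lesion segmentation is a
#' pipeline input, not computed here). The default thresholds bracket the
#' phantom tissue priors at 7T.
#'
#' @param t1 numeric 3D array, T1 in ms (NA/non-positive outside the brain).
#' @param wmMax,gmMax T1 thresholds in ms.
#' @param brainMask optional logical 3D array; defaults to finite, positive
#'   T1.
#' @param lesionMask optional logical 3D array of lesion voxels.
#' @return integer 3D array of labels (0 background, 1 WM, 2 GM, 3 CSF,
#'   4 lesion). Warns when a tissue class comes out empty.
#' @export
segmentFromT1 <- function(t1, wmMax = 1450, gmMax = 2600, brainMask = NULL,
                          lesionMask = NULL) {
  stopifnot(length(dim(t1)) == 3L)
  if (is.null(brainMask)) brainMask <- is.finite(t1) & t1 > 0
  if (any(!is.finite(t1[brainMask])))
    stop("T1 map contains non-finite values inside the brain mask")
  lab <- array(0L, dim(t1))
  lab[brainMask & t1 <= wmMax] <- 1L
  lab[brainMask & t1 > wmMax & t1 <= gmMax] <- 2L
  lab[brainMask & t1 > gmMax] <- 3L
  if (!is.null(lesionMask)) {
    stopifnot(identical(dim(lesionMask), dim(t1)))
    lab[lesionMask & brainMask] <- 4L
  }
  for (tis in c("WM", "GM", "CSF"))
    if (!any(lab == TISSUE_LEVELS[tis]))
      warning(sprintf("tissue class %s is empty after segmentation", tis))
  lab
}

#' ROI mean and SD of a parameter map
#'
#' Arithmetic mean and standard deviation of a voxel map over one labelled
#' region, restricted to QC-passing voxels.
#'
#' @param map numeric 3D array.
#' @param labels integer 3D array of tissue labels.
#' @param label tissue name (\code{"WM"}, \code{"GM"}, \code{"CSF"},
#'   \code{"lesion"}) or integer label.
#' @param qcPass optional logical 3D array; voxels with FALSE are excluded.
#' @return named list \code{mean}, \code{sd}, \code{n}; mean is NA (with a
#'   message) for an empty ROI.
#' @export
roiMean <- function(map, labels, label, qcPass = NULL) {
  lev <- if (is.character(label)) TISSUE_LEVELS[[label]] else as.integer(label)
  sel <- labels == lev & is.finite(map)
  if (!is.null(qcPass)) sel <- sel & qcPass
  v <- map[sel]
  if (length(v) == 0L) {
    message(sprintf("empty ROI for label %s", as.character(label)))
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

# Assemble one tidy StatResult row.
statResult <- function(contrast, comparison, estimate = NA, t = NA, p = NA,
                       pAdjusted = NA, r2 = NA, slope = NA,
                       meanA = NA, sdA = NA, meanB = NA, sdB = NA,
                       percentChange = NA) {
  data.frame(contrast = contrast, comparison = comparison,
             estimate = estimate, t = t, p = p, pAdjusted = pAdjusted,
             r2 = r2, slope = slope, meanA = meanA, sdA = sdA,
             meanB = meanB, sdB = sdB, percentChange = percentChange,
             stringsAsFactors = FALSE)
}

#' Two-sample t-test between groups
#'
#' Welch's unequal-variance two-sample t-test (the default), or the pooled
#' variant. Degenerate input with zero variance in both groups and equal
#' means returns t = 0, p = 1.
#'
#' @param a,b numeric vectors of per-subject values (reference group first).
#' @param contrast,comparison labels carried into the result row.
#' @param varEqual use the pooled-variance test instead of Welch.
#' @return a one-row data.frame: estimate (mean difference b - a), t, p,
#'   group means and SDs, and the percent change of b relative to a.
#' @export
twoSampleTTest <- function(a, b, contrast = "", comparison = "",
                           varEqual = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(b, a, var.equal = varEqual)
  }
  statResult(contrast, comparison,
             estimate = mean(b) - mean(a),
             t = unname(tt$statistic), p = tt$p.value,
             meanA = mean(a), sdA = stats::sd(a),
             meanB = mean(b), sdB = stats::sd(b),
             percentChange = percentChange(mean(a), mean(b)))
}

#' Age/sex-adjusted group regression
#'
#' Ordinary least squares of a per-subject contrast value on the group
#' indicator, age and sex: \code{value ~ group + age + sex}. The group
#' coefficient (MS minus control), its t-value and two-sided p-value are
#' reported.
#'
#' @param value numeric per-subject contrast values.
#' @param group factor/character, \code{"control"} or \code{"MS"}.
#' @param age numeric, years.
#' @param sex factor/character, \code{"F"} or \code{"M"}.
#' @param contrast,comparison labels carried into the result row.
#' @return a one-row data.frame with the group coefficient, t, p and R^2.
#'   A rank-deficient design is an error naming the collinear columns.
#' @export
adjustedGroupRegression <- function(value, group, age, sex,
                                    contrast = "", comparison = "group") {
  stopifnot(length(value) > 4L)
  group <- factor(group, levels = c("control", "MS"))
  sex <- factor(sex, levels = c("F", "M"))
  X <- stats::model.matrix(~ group + age + sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(value ~ group + age + sex)
  s <- summary(fit)
  co <- s$coefficients["groupMS", ]
  statResult(contrast, comparison, estimate = unname(co["Estimate"]),
             t = unname(co["t value"]), p = unname(co["Pr(>|t|)"]),
             r2 = s$r.squared)
}

#' Pairwise Bonferroni-corrected t-tests across WM tissue states
#'
#' The three pairwise comparisons among control WM, normal-appearing WM and
#' lesion tissue, each a two-sample t-test with Bonferroni correction for
#' the family of three: adjusted p = min(1, 3p).
#'
#' @param controlWM,nawm,lesion numeric per-subject ROI values.
#' @param contrast label carried into the result rows.
#' @param varEqual use pooled-variance t-tests.
#' @return data.frame with three rows, one per pairing, with raw and
#'   adjusted p-values.
#' @export
pairwiseBonferroni <- function(controlWM, nawm, lesion, contrast = "",
                               varEqual = FALSE) {
  rows <- rbind(
    twoSampleTTest(controlWM, nawm, contrast, "controlWM vs NAWM", varEqual),
    twoSampleTTest(controlWM, lesion, contrast, "controlWM vs lesion",
                   varEqual),
    twoSampleTTest(nawm, lesion, contrast, "NAWM vs lesion", varEqual)
  )
  rows$pAdjusted <- pmin(1, 3 * rows$p)
  rows
}

#' Clinical covariate regression
#'
#' Simple linear regression of an imaging contrast on a clinical covariate
#' (disease duration in years, or lesion volume in cm^3), within the MS
#' group.
#'
#' @param value numeric per-subject contrast values.
#' @param covariate numeric per-subject covariate values (non-degenerate).
#' @param contrast,comparison labels carried into the result row.
#' @return a one-row data.frame with slope (beta1), t, p and R^2.
#' @export
covariateRegression <- function(value, covariate, contrast = "",
                                comparison = "covariate") {
  stopifnot(length(value) >= 3L, length(covariate) == length(value))
  if (stats::sd(covariate) == 0)
    stop("covariate has zero variance; regression is undefined")
  if (stats::sd(value) == 0)
    return(statResult(contrast, comparison, estimate = 0, t = 0, p = 1,
                      r2 = 0, slope = 0))
  fit <- stats::lm(value ~ covariate)
  s <- summary(fit)
  co <- s$coefficients["covariate", ]
  statResult(contrast, comparison, estimate = unname(co["Estimate"]),
             t = unname(co["t value"]), p = unname(co["Pr(>|t|)"]),
             r2 = s$r.squared, slope = unname(co["Estimate"]))
}

#' Percent change between two group means
#'
#' \code{100 * (comparison - reference) / reference}; negative values are
#' decreases relative to the reference.
#'
#' @param reference reference group mean (nonzero).
#' @param comparison comparison group mean.
#' @return signed percent change.
#' @examples
#' percentChange(0.114, 0.101)  # -11.4: the published NAWM rNOE decrease
#' @export
percentChange <- function(reference, comparison) {
  if (any(reference == 0)) stop("reference mean is zero; percent change undefined")
  100 * (comparison - reference) / reference
}
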