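PIPELINE_CONTRASTS <- c(POOL_NAMES, "t1", "noeMtr")

#' Preprocess and fit one subject volume
#'
#' Runs the per-subject analysis chain in fixed order: optional denoising of
#' the raw stack, normalization by the reference image, WASSR B0 estimation
#' and spectral correction, voxel-wise five-pool fitting, and first-order B1
#' correction of the fitted amplitudes (using the acquired relative-B1 map).
#'
#' @param vol a \code{PhantomVolume} (or any object with the same slots).
#' @param cfg a \code{FitConfig}.
#' @param denoise denoising method passed to \code{\link{denoiseHook}}.
#' @param b0Correct,b1Correct logical switches for the two corrections.
#' @return list with \code{poolMaps} (\code{PoolMaps}, B1-corrected
#'   amplitudes), \code{b0} (estimated B0 map), \code{b0Flags} and
#'   \code{mask}.
#' @export
fitSubject <- function(vol, cfg = fitConfig(), denoise = "none",
                       b0Correct = TRUE, b1Correct = TRUE) {
  stack <- denoiseHook(vol@zStack, denoise)
  norm <- normalizeZStack(stack, vol@reference)
  b0 <- NULL
  flags <- NULL
  z <- norm$z
  if (b0Correct) {
    est <- estimateB0Wassr(vol@wassrStack, vol@wassrAxis, mask = norm$mask)
    b0 <- est$b0
    flags <- est$flags
    z <- correctB0(z, b0, vol@axis)
  }
  pm <- fitVolume(z, vol@axis, cfg, mask = norm$mask)
  if (b1Correct) pm@amplitude <- correctB1(pm@amplitude, vol@b1)
  list(poolMaps = pm, b0 = b0, b0Flags = flags, mask = norm$mask)
}

#' Per-subject ROI summary table
#'
#' Segments the subject's tissue from its T1 map (the provided lesion mask
#' overriding), then summarizes each contrast (the five pool amplitudes, T1
#' and NOE_MTR) over WM, GM, lesion and the whole-brain slab. The
#' whole-brain ROI is GM plus WM, including lesions for MS subjects and
#' excluding CSF. Only QC-passing voxels contribute.
#'
#' @param vol a \code{PhantomVolume}.
#' @param fit result of \code{\link{fitSubject}}.
#' @param labels optional precomputed label array; by default segmented from
#'   the subject's T1 map with the lesion mask applied.
#' @return data.frame: id, group, tissue, contrast, mean, sd, n.
#' @export
subjectRoiTable <- function(vol, fit, labels = NULL) {
  if (is.null(labels)) {
    labels <- suppressWarnings(
      segmentFromT1(vol@t1, lesionMask = vol@labels == 4L))
  }
  checkSameGrid(labels, fit$poolMaps@mask, "labels", "fit mask")
  pm <- fit$poolMaps
  qc <- !pm@qcFail & pm@mask
  maps <- c(lapply(seq_len(5L), function(k) pm@amplitude[, , , k]),
            list(vol@t1, pm@noeMtr))
  names(maps) <- PIPELINE_CONTRASTS

  isMS <- vol@subject$group == "MS"
  rows <- list()
  for (cn in PIPELINE_CONTRASTS) {
    map <- maps[[cn]]
    for (tis in c("WM", "GM", "lesion")) {
      r <- suppressMessages(roiMean(map, labels, tis, qc))
      rows[[length(rows) + 1L]] <-
        data.frame(id = vol@subject$id, group = vol@subject$group,
                   tissue = tis, contrast = cn, mean = r$mean, sd = r$sd,
                   n = r$n, stringsAsFactors = FALSE)
    }
    wbLabels <- c(1L, 2L, if (isMS) 4L)
    sel <- labels %in% wbLabels & is.finite(map) & qc
    v <- map[array(sel, dim(labels))]
    rows[[length(rows) + 1L]] <-
      data.frame(id = vol@subject$id, group = vol@subject$group,
                 tissue = "wholeBrain", contrast = cn,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v)) stats::sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cohort-level statistical battery
#'
#' Reproduces the study's analysis plan on a cohort ROI table: Welch
#' two-sample t-tests and age/sex-adjusted multiple linear regressions for
#' the whole-brain slab and GM contrasts (control versus MS), Bonferroni-
#' corrected pairwise t-tests among control WM, NAWM and lesion tissue, and
#' simple linear regressions of each contrast on disease duration and on
#' lesion volume within the MS group (NAWM, NAGM, lesion).
#'
#' @param roi per-subject ROI table (rows from \code{\link{subjectRoiTable}}).
#' @param subjects data.frame of subject records.
#' @return data.frame of tidy \code{StatResult} rows; the \code{analysis}
#'   column names the battery stage.
#' @export
cohortStats <- function(roi, subjects) {
  roi <- merge(roi, subjects[, c("id", "age", "sex", "diseaseDuration",
                                 "lesionVolume")], by = "id")
  out <- list()
  add <- function(df, analysis) {
    df$analysis <- analysis
    out[[length(out) + 1L]] <<- df
  }

  pull <- function(tissue, contrast, group = NULL) {
    s <- roi[roi$tissue == tissue & roi$contrast == contrast, ]
    if (!is.null(group)) s <- s[s$group == group, ]
    s[!is.na(s$mean), ]
  }

  for (cn in PIPELINE_CONTRASTS) {
    for (tis in c("wholeBrain", "GM")) {
      ctl <- pull(tis, cn, "control")
      ms <- pull(tis, cn, "MS")
      if (nrow(ctl) >= 2L && nrow(ms) >= 2L) {
        add(twoSampleTTest(ctl$mean, ms$mean, cn,
                           paste0(tis, ": control vs MS")),
            "two-sample t-test")
        both <- rbind(ctl, ms)
        # the adjusted model needs enough subjects for its four coefficients
        if (nrow(both) > 4L && length(unique(both$sex)) > 1L)
          add(adjustedGroupRegression(both$mean, both$group, both$age,
                                      both$sex, cn,
                                      paste0(tis, ": control vs MS")),
              "age/sex-adjusted regression")
      }
    }
    ctlWM <- pull("WM", cn, "control")
    nawm <- pull("WM", cn, "MS")
    les <- pull("lesion", cn, "MS")
    if (nrow(ctlWM) >= 2L && nrow(nawm) >= 2L && nrow(les) >= 2L)
      add(pairwiseBonferroni(ctlWM$mean, nawm$mean, les$mean, cn),
          "pairwise Bonferroni")
    for (tis in c("WM", "GM", "lesion")) {
      ms <- pull(tis, cn, "MS")
      for (cov in c("diseaseDuration", "lesionVolume")) {
        if (nrow(ms) >= 3L && stats::sd(ms[[cov]]) > 0)
          add(covariateRegression(ms$mean, ms[[cov]], cn,
                                  paste0(tis, " ~ ", cov)),
              "covariate regression")
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates the cohort from a \code{PhantomSpec}, preprocesses and fits
#' every subject, builds the per-subject ROI table and runs the cohort
#' statistics. Optionally writes the subject table, ROI table and results
#' table as CSV (and the effective configuration as JSON) to a directory.
#'
#' @param spec a \code{PhantomSpec}.
#' @param cfg a \code{FitConfig}.
#' @param outDir optional output directory.
#' @param denoise denoising method for \code{\link{fitSubject}}.
#' @param verbose print per-subject progress.
#' @return list with \code{subjects}, \code{roi}, \code{stats}.
#' @export
runPipeline <- function(spec, cfg = fitConfig(), outDir = NULL,
                        denoise = "none", verbose = FALSE) {
  cohort <- simulateCohort(spec)
  roi <- list()
  for (i in seq_along(cohort$volumes)) {
    vol <- cohort$volumes[[i]]
    if (verbose)
      message(sprintf("fitting subject %s (%s)", vol@subject$id,
                      vol@subject$group))
    fit <- fitSubject(vol, cfg, denoise = denoise)
    roi[[i]] <- subjectRoiTable(vol, fit)
  }
  roi <- do.call(rbind, roi)
  stats <- cohortStats(roi, cohort$subjects)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$subjects, file.path(outDir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(roi, file.path(outDir, "roi_means.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(outDir, "statistics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = spec@seed, dim = spec@dim,
                              noiseSD = spec@noiseSD),
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(subjects = cohort$subjects, roi = roi, stats = stats)
}
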