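#' Write a volumetric image with an offset sidecar
#'
#' Writes a 3D volume or 4D stack as NIfTI-1. When a \code{FrequencyAxis} is
#' supplied, the offset list is written to a JSON sidecar next to the image
#' (offsets are never inferred from volume order alone).
#'
#' @param x numeric 3D or 4D array.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize numeric(3), voxel size in mm.
#' @param axis optional \code{FrequencyAxis} recorded in the sidecar.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, voxelSize = c(1, 1, 2), axis = NULL) {
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L))
  img <- RNifti::asNifti(x)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- voxelSize
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  if (!is.null(axis)) {
    jsonlite::write_json(
      list(offsets = offsets(axis), referenceOffset = referenceOffset(axis)),
      sidecarPath(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a volumetric image and its sidecar
#'
#' @param path path to a NIfTI-1 image written by \code{\link{writeVolume}}
#'   (or any NIfTI-1 volume).
#' @return list with \code{data} (array), \code{voxelSize} (mm) and
#'   \code{axis} (a \code{FrequencyAxis}, or NULL when no sidecar exists).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ax <- NULL
  sp <- sidecarPath(path)
  if (file.exists(sp)) {
    sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
    ax <- frequencyAxis(sc$offsets, sc$referenceOffset)
  }
  list(data = array(as.numeric(img), dim(img)),
       voxelSize = RNifti::pixdim(img)[1:3], axis = ax)
}

#' Check that two volumes share a voxel grid
#'
#' Errors when the spatial grids differ, naming both shapes; masks and
#' stacks must share the grid exactly (no silent resampling).
#'
#' @param a,b arrays (3D, or 4D whose first three dimensions are spatial).
#' @param nameA,nameB names used in the error message.
#' @return TRUE, invisibly.
#' @export
checkSameGrid <- function(a, b, nameA = "first volume",
                          nameB = "second volume") {
  da <- dim(a)[1:3]
  db <- dim(b)[1:3]
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s is %s but %s is %s", nameA,
                 paste(da, collapse = "x"), nameB,
                 paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Write a phantom volume to a directory
#'
#' Emits the subject's raw Z-stack, reference image, WASSR stack, true
#' B0/B1/T1 fields and tissue labels as NIfTI volumes with JSON sidecars,
#' plus a ground-truth sidecar (subject record and drawn tissue means) as
#' JSON.
#'
#' @param vol a \code{PhantomVolume}.
#' @param dir output directory (created if needed).
#' @param voxelSize voxel size in mm.
#' @return the directory, invisibly.
#' @export
writePhantomVolume <- function(vol, dir, voxelSize = c(1, 1, 2)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(vol@zStack, file.path(dir, "zstack.nii.gz"), voxelSize,
              vol@axis)
  writeVolume(vol@reference, file.path(dir, "reference.nii.gz"), voxelSize)
  writeVolume(vol@wassrStack, file.path(dir, "wassr.nii.gz"), voxelSize,
              vol@wassrAxis)
  writeVolume(vol@b0, file.path(dir, "b0_true.nii.gz"), voxelSize)
  writeVolume(vol@b1, file.path(dir, "b1.nii.gz"), voxelSize)
  writeVolume(vol@t1, file.path(dir, "t1.nii.gz"), voxelSize)
  writeVolume(vol@labels + 0, file.path(dir, "labels.nii.gz"), voxelSize)
  jsonlite::write_json(
    list(subject = vol@subject, tissueMeans = vol@tissueMeans,
         fwhm = as.list(vol@fwhm), center = as.list(vol@center)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
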