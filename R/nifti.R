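#' Read a volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file into a [as_volume()] object. Voxel spacing is
#' taken from the header's pixdim. A 3D file yields a single-channel volume;
#' a 4D file maps its last axis to channels. Any NaN voxel triggers an error
#' reporting the number of affected voxels, so corrupt inputs fail loudly at
#' the door rather than deep inside a model.
#'
#' @param path Path to a readable NIfTI file.
#' @return An `afno_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (!(nd %in% c(3L, 4L))) stop("expected a 3D or 4D NIfTI, got rank ", nd)
  pix <- attr(img, "pixdim")
  spacing <- abs(as.numeric(pix[1:3]))
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  arr <- unclass(arr)
  attributes(arr) <- list(dim = dim(arr))
  as_volume(arr, spacing = spacing, origin_note = paste0("nifti:", path))
}

#' Write a volume to a NIfTI file
#'
#' Stores intensities as 32-bit float with the voxel spacing encoded in the
#' header; round trips are lossless for float32 data.
#'
#' @param vol An `afno_volume`.
#' @param path Destination `.nii` or `.nii.gz` path; parent must exist.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "afno_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  arr <- vol$data
  if (dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  hdr <- list(pixdim = c(1, vol$spacing, 1, 1, 1, 1))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "float")
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write NIfTI to ", path)
  invisible(NULL)
}

#' Read a label map from a NIfTI file
#'
#' @param path Path to a NIfTI file holding integer class labels.
#' @param num_classes Optional `K`; inferred as `max(label) + 1` when `NULL`.
#' @return An `afno_labelmap`.
#' @export
read_labels <- function(path, num_classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("label NIfTI must be 3D, got rank ",
                                   length(dim(arr)))
  if (any(is.na(arr))) stop("label file contains NaN values")
  if (any(arr != round(arr))) {
    stop("label file contains ", sum(arr != round(arr)),
         " fractional value(s); labels must be integers")
  }
  if (any(arr < 0)) stop("label file contains negative values")
  pix <- attr(img, "pixdim")
  spacing <- abs(as.numeric(pix[1:3]))
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  arr <- unclass(arr)
  attributes(arr) <- list(dim = dim(arr))
  as_labelmap(arr, num_classes = num_classes, spacing = spacing)
}

#' Write a label map to a NIfTI file
#'
#' Labels are stored as unsigned 8-bit integers when `K <= 256`, otherwise
#' unsigned 16-bit.
#'
#' @param lm An `afno_labelmap`.
#' @param path Destination path; parent must exist.
#' @export
write_labels <- function(lm, path) {
  stopifnot(inherits(lm, "afno_labelmap"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  dtype <- if (lm$num_classes <= 256L) "uint8" else "uint16"
  hdr <- list(pixdim = c(1, lm$spacing, 1, 1, 1, 1))
  img <- RNifti::asNifti(lm$labels, reference = hdr, datatype = dtype)
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write NIfTI to ", path)
  invisible(NULL)
}
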