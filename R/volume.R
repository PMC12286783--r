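#' Construct a multi-channel 3D volume
#'
#' A `Volume` is the package's container for volumetric image data: a rank-4
#' numeric array indexed `(H, W, D, C)` (channel axis last) together with the
#' physical voxel spacing in millimetres along the three spatial axes. Voxel
#' indices are 0-based in physical terms: the centre of voxel `i` along an
#' axis sits at `i * spacing` mm.
#'
#' @param data Numeric array. Rank 3 arrays are promoted to rank 4 with a
#'   single channel; rank 4 arrays are taken as `(H, W, D, C)`.
#' @param spacing Numeric length-3 vector of positive voxel sizes in mm.
#' @param origin_note Free-text provenance string carried along unmodified.
#' @return An object of class `afno_volume`.
#' @examples
#' v <- as_volume(array(rnorm(8^3), c(8, 8, 8)))
#' dim(v$data)   # 8 8 8 1
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin_note = "") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a rank-3 or rank-4 array, got rank ",
         length(dim(data)))
  }
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)")
  }
  n_nan <- sum(is.na(data))
  if (n_nan > 0L) {
    stop("volume contains ", n_nan, " NaN/NA voxel value(s)")
  }
  structure(
    list(data = data, spacing = spacing, origin_note = as.character(origin_note)[1]),
    class = "afno_volume"
  )
}

#' @export
print.afno_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<afno_volume> %d x %d x %d voxels, %d channel(s), spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  invisible(x)
}

#' Construct a label map
#'
#' A `LabelMap` pairs a rank-3 integer class grid with the number of classes
#' `K` (labels take values `0 .. K-1`, class 0 is background) and the voxel
#' spacing of the grid it annotates.
#'
#' @param labels Integer-valued rank-3 array.
#' @param num_classes Number of classes `K >= 2`; defaults to `max(labels)+1`.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `afno_labelmap`.
#' @export
as_labelmap <- function(labels, num_classes = NULL, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a rank-3 array")
  }
  if (any(is.na(labels))) stop("label map contains NA values")
  if (any(labels != round(labels))) {
    stop("label map contains ", sum(labels != round(labels)),
         " non-integer value(s)")
  }
  if (any(labels < 0)) stop("label map contains negative values")
  storage.mode(labels) <- "integer"
  if (is.null(num_classes)) num_classes <- max(labels) + 1L
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("`num_classes` must be >= 2")
  if (max(labels) >= num_classes) {
    stop("max label ", max(labels), " exceeds num_classes - 1 = ",
         num_classes - 1L)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)")
  }
  structure(
    list(labels = labels, num_classes = num_classes, spacing = spacing),
    class = "afno_labelmap"
  )
}

#' @export
print.afno_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<afno_labelmap> %d x %d x %d voxels, K = %d classes\n",
              d[1], d[2], d[3], x$num_classes))
  invisible(x)
}

#' Per-channel z-score intensity normalization
#'
#' Standardizes each channel to zero mean and unit standard deviation, with
#' statistics computed over the entire channel (no foreground mask). Channels
#' whose standard deviation falls below `1e-8` are set to all zeros rather
#' than dividing by a vanishing denominator, so the output never contains
#' NaN. The operation is idempotent on non-degenerate channels.
#'
#' @param vol A [as_volume()] object.
#' @return A normalized `afno_volume` with the same shape and spacing.
#' @export
normalize_zscore <- function(vol) {
  stopifnot(inherits(vol, "afno_volume"))
  d <- dim(vol$data)
  out <- vol$data
  for (c in seq_len(d[4])) {
    ch <- vol$data[, , , c]
    m <- mean(ch)
    s <- sqrt(mean((ch - m)^2))    # population SD: a constant-plus-step
                                   # channel maps exactly to +-1
    if (!is.finite(s) || s < 1e-8) {
      out[, , , c] <- 0
    } else {
      out[, , , c] <- (ch - m) / s
    }
  }
  vol$data <- out
  vol
}

# spatial grid shape helpers used across modules
vol_shape <- function(vol) dim(vol$data)[1:3]
vol_channels <- function(vol) dim(vol$data)[4]
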