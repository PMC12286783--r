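#' Dice overlap coefficient
#'
#' `2 |T intersect S| / (|T| + |S|)` between two binary masks on a shared
#' grid; 1 means perfect overlap, 0 means none. When both masks are empty
#' the value is 1 by convention (perfect agreement on absence) and the
#' `"both_empty"` attribute flags it; when exactly one mask is empty the
#' value is 0.
#'
#' @param T,S Logical (or 0/1) arrays of identical shape.
#' @return Dice value in `[0, 1]`, with attribute `both_empty`.
#' @export
dice <- function(T, S) {
  if (!identical(dim(T), dim(S))) {
    stop("masks must share a grid: ", paste(dim(T), collapse = "x"),
         " vs ", paste(dim(S), collapse = "x"))
  }
  T <- as.logical(T); S <- as.logical(S)
  nT <- sum(T); nS <- sum(S)
  if (nT + nS == 0L) {
    return(structure(1, both_empty = TRUE))
  }
  structure(2 * sum(T & S) / (nT + nS), both_empty = FALSE)
}

#' Extract surface points of a binary mask
#'
#' A voxel belongs to the surface when it is foreground and at least one of
#' its six face neighbours is background; voxels on the grid border count
#' out-of-bounds neighbours as background. Coordinates are physical: the
#' 0-based voxel index scaled by the spacing (voxel-centre convention), in
#' mm.
#'
#' @param mask Logical rank-3 array.
#' @param spacing Voxel spacing in mm.
#' @return An `afno_surface`: list with `points` (`n x 3` matrix of mm
#'   coordinates) and `empty` flag.
#' @export
surface_points <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) {
    return(structure(list(points = matrix(numeric(0), 0, 3), empty = TRUE),
                     class = "afno_surface"))
  }
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- function(oh, ow, od) {
    pad[(2:(d[1] + 1)) + oh, (2:(d[2] + 1)) + ow, (2:(d[3] + 1)) + od]
  }
  n_bg <- (!core(1, 0, 0)) + (!core(-1, 0, 0)) + (!core(0, 1, 0)) +
    (!core(0, -1, 0)) + (!core(0, 0, 1)) + (!core(0, 0, -1))
  surf <- mask & (n_bg > 0)
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, as.numeric(spacing), `*`)
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, empty = FALSE), class = "afno_surface")
}

# directed nearest-neighbour distances from each row of A to the set B,
# chunked so peak memory stays bounded
nn_distances <- function(A, B, chunk = 512L) {
  nA <- nrow(A)
  out <- numeric(nA)
  bb <- rowSums(B * B)
  for (s in seq(1, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    Ai <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ai * Ai), bb, `+`) - 2 * Ai %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# percentile by linear interpolation between closest ranks
percentile_linear <- function(x, q) {
  as.numeric(stats::quantile(x, q / 100, type = 7, names = FALSE))
}

#' 95th-percentile Hausdorff distance
#'
#' For each direction, the nearest-neighbour distance from every surface
#' point of one mask to the other surface is computed; the qth percentile
#' (linear interpolation between closest ranks) of those distances is taken,
#' and the maximum of the two directed values is returned, in mm. With
#' `percentile = 100` this is the classical (maximum) Hausdorff distance.
#' If either surface is empty the distance is undefined and `NA` is
#' returned with an `undefined` attribute.
#'
#' @param T,S Logical arrays on a shared grid.
#' @param spacing Voxel spacing in mm.
#' @param percentile Percentile of the directed distance distributions.
#' @return Distance in mm (`NA` when undefined).
#' @export
hd95 <- function(T, S, spacing = c(1, 1, 1), percentile = 95) {
  if (!identical(dim(T), dim(S))) {
    stop("masks must share a grid")
  }
  sT <- surface_points(T, spacing)
  sS <- surface_points(S, spacing)
  if (sT$empty || sS$empty) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d_ts <- nn_distances(sT$points, sS$points)
  d_st <- nn_distances(sS$points, sT$points)
  structure(max(percentile_linear(d_ts, percentile),
                percentile_linear(d_st, percentile)),
            undefined = FALSE)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Per-class one-vs-rest binarization for classes `1 .. K-1` (background is
#' excluded, matching organ-wise reporting), Dice and HD95 per class, and
#' means over the classes where each metric is defined. Classes absent from
#' both maps get flagged Dice 1 and undefined HD95; undefined HD95 values
#' are excluded from `mean_hd95` and listed in `notes` rather than silently
#' dropped.
#'
#' @param pred,gt `afno_labelmap`s on the same grid.
#' @param spacing Voxel spacing in mm (defaults to the ground truth's).
#' @param percentile HD percentile (default 95).
#' @return An `afno_metric_report`: per-class table plus `mean_dice`,
#'   `mean_hd95`, `notes`.
#' @export
evaluate <- function(pred, gt, spacing = NULL, percentile = 95) {
  stopifnot(inherits(pred, "afno_labelmap"), inherits(gt, "afno_labelmap"))
  if (!identical(dim(pred$labels), dim(gt$labels))) {
    stop("prediction and ground truth grids differ")
  }
  if (is.null(spacing)) spacing <- gt$spacing
  K <- max(pred$num_classes, gt$num_classes)
  classes <- seq_len(K - 1L)
  rows <- lapply(classes, function(c) {
    Tm <- gt$labels == c
    Sm <- pred$labels == c
    dc <- dice(Tm, Sm)
    hd <- hd95(Tm, Sm, spacing, percentile)
    data.frame(class = c,
               dice = as.numeric(dc),
               dice_both_empty = isTRUE(attr(dc, "both_empty")),
               hd95_mm = as.numeric(hd),
               hd95_undefined = isTRUE(attr(hd, "undefined")),
               n_voxels_gt = sum(Tm), n_voxels_pred = sum(Sm))
  })
  per_class <- do.call(rbind, rows)
  defined_hd <- !per_class$hd95_undefined
  notes <- character(0)
  if (any(!defined_hd)) {
    notes <- c(notes, paste0("hd95 undefined for class(es) ",
                             paste(per_class$class[!defined_hd],
                                   collapse = ", "),
                             " (empty surface); excluded from mean_hd95"))
  }
  if (any(per_class$dice_both_empty)) {
    notes <- c(notes, paste0("dice = 1 by both-empty convention for ",
                             "class(es) ",
                             paste(per_class$class[per_class$dice_both_empty],
                                   collapse = ", ")))
  }
  structure(
    list(per_class = per_class,
         mean_dice = mean(per_class$dice),
         mean_hd95 = if (any(defined_hd))
           mean(per_class$hd95_mm[defined_hd]) else NA_real_,
         notes = notes, percentile = percentile),
    class = "afno_metric_report"
  )
}

#' @export
print.afno_metric_report <- function(x, ...) {
  cat("<afno_metric_report>\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("mean Dice %.4f | mean HD95 %s mm\n", x$mean_dice,
              ifelse(is.na(x$mean_hd95), "NA",
                     sprintf("%.3f", x$mean_hd95))))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Serialize a metric report
#'
#' @param report An `afno_metric_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "afno_metric_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(per_class = report$per_class, mean_dice = report$mean_dice,
           mean_hd95 = report$mean_hd95, notes = report$notes),
      path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(report$per_class, path, row.names = FALSE)
  }
  invisible(path)
}
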