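#' Segment a volume with a single forward pass
#'
#' Convenience wrapper: optional z-score normalization, forward pass,
#' per-voxel softmax. Use [sliding_window_predict()] for volumes larger
#' than the model's training window.
#'
#' @param model An `afno_model`.
#' @param vol An `afno_volume`.
#' @param normalize Apply [normalize_zscore()] first?
#' @param keep_logits Retain raw logits in the result?
#' @return An `afno_segmentation`.
#' @export
model_predict <- function(model, vol, normalize = TRUE,
                          keep_logits = FALSE) {
  stopifnot(inherits(model, "afno_model"), inherits(vol, "afno_volume"))
  v <- if (normalize) normalize_zscore(vol) else vol
  fw <- model_forward(model, v$data, keep_cache = FALSE)
  segmentation_result(fw$logits, keep_logits = keep_logits,
                      spacing = vol$spacing)
}

# Gaussian importance map for blending overlapping windows: highest weight
# at the window centre, sigma = window/8 per axis, floored away from zero
gaussian_importance <- function(window, sigma_scale = 0.125) {
  w <- lapply(window, function(n) {
    c0 <- (n + 1) / 2
    v <- exp(-0.5 * ((seq_len(n) - c0) / (sigma_scale * n))^2)
    pmax(v, 1e-3)
  })
  outer(outer(w[[1]], w[[2]]), w[[3]])
}

# window start positions covering [1, size] with the requested stride; the
# last window is shifted flush with the end so every voxel is covered
window_starts <- function(size, window, stride) {
  if (size <= window) return(1L)
  s <- seq(1L, size - window + 1L, by = max(1L, stride))
  if (s[length(s)] != size - window + 1L) s <- c(s, size - window + 1L)
  as.integer(s)
}

#' Sliding-window inference
#'
#' Tiles the volume with fixed-size windows at stride
#' `window * (1 - overlap)`, runs the model on each tile, and blends the
#' per-tile class probabilities with a Gaussian importance map so that the
#' blending weights form a partition of unity at every voxel. Volumes
#' smaller than the window are zero-padded and the output cropped back.
#' When a single window covers the whole volume the direct forward pass is
#' returned as-is, bit for bit.
#'
#' @param model An `afno_model`.
#' @param vol An `afno_volume`.
#' @param window Length-3 window size in voxels (default the model's
#'   reference input shape).
#' @param overlap Fractional overlap between adjacent windows, in `[0, 1)`.
#' @param normalize Apply [normalize_zscore()] to the whole volume first?
#' @return An `afno_segmentation` at the volume's resolution.
#' @export
sliding_window_predict <- function(model, vol, window = model$input_shape,
                                   overlap = 0.5, normalize = TRUE) {
  stopifnot(inherits(model, "afno_model"), inherits(vol, "afno_volume"))
  window <- as.integer(window)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  P <- if (model$config$constant_resolution) model$config$const_patch_size
       else 16L * model$config$patch_size
  if (any(window < P)) {
    stop("window ", paste(window, collapse = "x"),
         " is below the model minimum of ", P, " per axis")
  }
  v <- if (normalize) normalize_zscore(vol) else vol
  d <- vol_shape(v)
  pad <- pmax(window - d, 0L)
  x <- v$data
  if (any(pad > 0L)) {
    xp <- array(0, c(d + pad, dim(x)[4]))
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- xp
  }
  dp <- dim(x)[1:3]
  stride <- pmax(1L, as.integer(round(window * (1 - overlap))))
  s1 <- window_starts(dp[1], window[1], stride[1])
  s2 <- window_starts(dp[2], window[2], stride[2])
  s3 <- window_starts(dp[3], window[3], stride[3])
  single <- length(s1) == 1L && length(s2) == 1L && length(s3) == 1L &&
    all(dp == window)
  if (single) {
    fw <- model_forward(model, x, keep_cache = FALSE)
    probs <- softmax4(fw$logits)
    probs <- probs[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
                   drop = FALSE]
    return(structure(
      list(probabilities = probs,
           labels = predict_labels_from_probs(probs, vol$spacing),
           logits = NULL, spacing = vol$spacing),
      class = "afno_segmentation"))
  }
  K <- model$num_classes
  num <- array(0, c(dp, K))
  den <- array(0, dp)
  imp <- gaussian_importance(window)
  for (a in s1) for (b in s2) for (cc in s3) {
    ih <- a:(a + window[1] - 1L)
    iw <- b:(b + window[2] - 1L)
    id <- cc:(cc + window[3] - 1L)
    tile <- x[ih, iw, id, , drop = FALSE]
    fw <- model_forward(model, tile, keep_cache = FALSE)
    pr <- softmax4(fw$logits)
    for (k in seq_len(K)) {
      num[ih, iw, id, k] <- num[ih, iw, id, k] + pr[, , , k] * imp
    }
    den[ih, iw, id] <- den[ih, iw, id] + imp
  }
  probs <- num / as.vector(den)
  probs <- probs[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
                 drop = FALSE]
  structure(
    list(probabilities = probs,
         labels = predict_labels_from_probs(probs, vol$spacing),
         logits = NULL, spacing = vol$spacing),
    class = "afno_segmentation"
  )
}
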