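# Convolutional decoder: mirror-wired U-Net over the encoder pyramid.
# Decoder stage i upsamples the deeper path by 2 (learned transposed
# convolution), concatenates the encoder stage-i skip along channels, and
# refines with two 3x3x3 convolutions, each followed by per-voxel layer
# normalization and a Gaussian-error nonlinearity.

init_decoder_params <- function(config, num_classes, in_channels, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    ch <- config$stage_channels
    dec_ch <- c(ch[3], ch[2], ch[1])          # widths of decoder stages 3,2,1
    stem <- max(8L, ch[1] %/% 2L)
    prev <- ch[4]
    stages <- vector("list", 3)
    for (j in 1:3) {
      i <- 4L - j                              # encoder stage used as skip
      skip_c <- ch[i]
      stages[[j]] <- list(
        up = init_tconv2(prev, skip_c),
        conv1 = init_conv3(2L * skip_c, dec_ch[j]),
        ln1 = init_layernorm(dec_ch[j]),
        conv2 = init_conv3(dec_ch[j], dec_ch[j]),
        ln2 = init_layernorm(dec_ch[j])
      )
      prev <- dec_ch[j]
    }
    adapters <- NULL
    if (config$constant_resolution) {
      adapters <- lapply(1:4, function(s)
        init_linear(config$embed_dim, ch[s]))
    }
    list(stages = stages,
         final_up = init_tconv2(dec_ch[3], stem),
         head = init_linear(stem, num_classes),
         adapters = adapters, stem = stem)
  })
}

# per-voxel layer norm on an (h,w,d,C) array
vln_fwd <- function(x, p) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  o <- layernorm_fwd(xm, p)
  y <- o$y; dim(y) <- d
  list(y = y, cache = o$cache)
}

vln_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  dym <- dy; dim(dym) <- c(prod(d[1:3]), d[4])
  o <- layernorm_bwd(dym, cache, p)
  dx <- o$dx; dim(dx) <- d
  list(dx = dx, g = o$g)
}

vgelu_fwd <- function(x) list(y = x * stats::pnorm(x), cache = x)
vgelu_bwd <- function(dy, cache)
  dy * (stats::pnorm(cache) + cache * stats::dnorm(cache))

# one decoder stage; prev and skip are (h,w,d,C) arrays
ds_fwd <- function(prev, skip, p, use_norm_act = TRUE) {
  up <- tconv2_fwd(prev, p$up)
  u <- up$y
  du <- dim(u)[1:3]; dsk <- dim(skip)[1:3]
  if (any(du < dsk) || any(du - dsk > 1L)) {
    stop("upsampled shape (", paste(du, collapse = "x"),
         ") does not match skip shape (", paste(dsk, collapse = "x"), ")")
  }
  cropped <- any(du > dsk)
  if (cropped) {
    u <- u[seq_len(dsk[1]), seq_len(dsk[2]), seq_len(dsk[3]), , drop = FALSE]
  }
  cat_in <- array(0, c(dsk, dim(u)[4] + dim(skip)[4]))
  cat_in[, , , seq_len(dim(u)[4])] <- u
  cat_in[, , , dim(u)[4] + seq_len(dim(skip)[4])] <- skip
  c1 <- conv3_fwd(cat_in, p$conv1)
  if (use_norm_act) {
    n1 <- vln_fwd(c1$y, p$ln1)
    a1 <- vgelu_fwd(n1$y)
    c2 <- conv3_fwd(a1$y, p$conv2)
    n2 <- vln_fwd(c2$y, p$ln2)
    a2 <- vgelu_fwd(n2$y)
    y <- a2$y
    cache <- list(up = up, c1 = c1, n1 = n1, a1 = a1, c2 = c2, n2 = n2,
                  a2 = a2, up_c = dim(u)[4], skip_c = dim(skip)[4],
                  up_dim = du, cropped = cropped, norm_act = TRUE)
  } else {
    c2 <- conv3_fwd(c1$y, p$conv2)
    y <- c2$y
    cache <- list(up = up, c1 = c1, c2 = c2, up_c = dim(u)[4],
                  skip_c = dim(skip)[4], up_dim = du, cropped = cropped,
                  norm_act = FALSE)
  }
  list(y = y, cache = cache)
}

ds_bwd <- function(dy, cache, p) {
  if (cache$norm_act) {
    d2 <- vgelu_bwd(dy, cache$a2$cache)
    l2 <- vln_bwd(d2, cache$n2$cache, p$ln2)
    cb2 <- conv3_bwd(l2$dx, cache$c2$cache, p$conv2)
    d1 <- vgelu_bwd(cb2$dx, cache$a1$cache)
    l1 <- vln_bwd(d1, cache$n1$cache, p$ln1)
    cb1 <- conv3_bwd(l1$dx, cache$c1$cache, p$conv1)
    gln1 <- l1$g; gln2 <- l2$g
  } else {
    cb2 <- conv3_bwd(dy, cache$c2$cache, p$conv2)
    cb1 <- conv3_bwd(cb2$dx, cache$c1$cache, p$conv1)
    gln1 <- tree_zeros(p$ln1); gln2 <- tree_zeros(p$ln2)
  }
  dcat <- cb1$dx
  dsk <- dim(dcat)[1:3]
  dup <- dcat[, , , seq_len(cache$up_c), drop = FALSE]
  dskip <- dcat[, , , cache$up_c + seq_len(cache$skip_c), drop = FALSE]
  if (cache$cropped) {
    full <- array(0, c(cache$up_dim, cache$up_c))
    full[seq_len(dsk[1]), seq_len(dsk[2]), seq_len(dsk[3]), ] <- dup
    dup <- full
  }
  ub <- tconv2_bwd(dup, cache$up$cache, p$up)
  list(dprev = ub$dx, dskip = dskip,
       g = list(up = ub$g, conv1 = cb1$g, ln1 = gln1, conv2 = cb2$g,
                ln2 = gln2))
}

#' Run one decoder fusion stage
#'
#' Upsamples the deeper feature map by 2 with a learned transposed
#' convolution, concatenates the encoder skip along channels, and applies a
#' two-convolution refinement block (each 3x3x3 convolution followed by
#' per-voxel layer normalization and a Gaussian-error nonlinearity).
#'
#' @param prev Deeper-path feature array `(h, w, d, C_prev)`.
#' @param skip Encoder skip feature array at twice `prev`'s resolution.
#' @param params Stage parameters (`up`, `conv1`, `ln1`, `conv2`, `ln2`).
#' @param use_norm_act Apply normalization/nonlinearity? Disable to obtain
#'   the purely linear stage used in algebraic identity checks.
#' @return Refined feature array at the skip's resolution.
#' @export
decode_stage <- function(prev, skip, params, use_norm_act = TRUE) {
  ds_fwd(prev, skip, params, use_norm_act)$y
}

# full decoder forward; returns logits at the cropped input resolution
decode_fwd <- function(pyr, params, keep_cache = TRUE) {
  skips <- pyr$stages
  if (isTRUE(pyr$constant_resolution)) {
    ad <- adapt_skips_fwd(pyr, params)
    skips <- ad$skips
    ad_cache <- ad$cache
  } else ad_cache <- NULL
  x <- skips[[4]]
  st_caches <- vector("list", 3)
  for (j in 1:3) {
    i <- 4L - j
    o <- ds_fwd(x, skips[[i]], params$stages[[j]])
    x <- o$y
    if (keep_cache) st_caches[[j]] <- o$cache
  }
  fu <- tconv2_fwd(x, params$final_up)
  y <- fu$y
  padded <- dim(y)[1:3]
  keep <- pyr$input_shape
  y <- y[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), ,
         drop = FALSE]
  ga <- vgelu_fwd(y)
  hd <- conv1_fwd(ga$y, params$head)
  list(logits = hd$y,
       cache = if (keep_cache) list(stages = st_caches, fu = fu, ga = ga,
                                    hd = hd, padded = padded, keep = keep,
                                    ad = ad_cache) else NULL)
}

decode_bwd <- function(dlogits, cache, params) {
  hb <- conv1_bwd(dlogits, cache$hd$cache, params$head)
  dga <- vgelu_bwd(hb$dx, cache$ga$cache)
  keep <- cache$keep; padded <- cache$padded
  if (any(padded > keep)) {
    full <- array(0, c(padded, dim(dga)[4]))
    full[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), ] <- dga
    dga <- full
  }
  fb <- tconv2_bwd(dga, cache$fu$cache, params$final_up)
  dx <- fb$dx
  dskips <- vector("list", 4)
  gst <- vector("list", 3)
  for (j in 3:1) {
    sb <- ds_bwd(dx, cache$stages[[j]], params$stages[[j]])
    dskips[[4L - j]] <- sb$dskip
    dx <- sb$dprev
    gst[[j]] <- sb$g
  }
  dskips[[4]] <- dx
  g_ad <- NULL
  if (!is.null(cache$ad)) {
    g_ad <- vector("list", 4)
    for (s in 1:4) {
      cs <- cache$ad[[s]]
      d <- dim(dskips[[s]])
      dm <- dskips[[s]]; dim(dm) <- c(prod(d[1:3]), d[4])
      lb <- linear_bwd(dm, cs$lin, params$adapters[[s]])
      g_ad[[s]] <- lb$g
      dr <- lb$dx; dim(dr) <- c(d[1:3], nrow(params$adapters[[s]]$W))
      dskips[[s]] <- if (cs$rs$cache$f == 1L) dr
        else if (cs$rs$kind == "up") nnup_bwd(dr, cs$rs$cache)
        else avgpool_bwd(dr, cs$rs$cache)
    }
  }
  list(dskips = dskips,
       g = list(stages = gst, final_up = fb$g, head = hb$g,
                adapters = g_ad, stem = NULL))
}

# constant-resolution adapter: bring each equal-resolution skip to the
# mirror resolution H/2^s and the hierarchical stage width
adapt_skips_fwd <- function(pyr, params) {
  base <- dim(pyr$stages[[1]])[1:3]            # token grid (H/const_P)
  target1 <- as.integer(ceiling(pyr$input_shape / 2))
  skips <- vector("list", 4)
  caches <- vector("list", 4)
  for (s in 1:4) {
    tgt <- as.integer(ceiling(pyr$input_shape / 2^s))
    x <- pyr$stages[[s]]
    if (all(tgt >= base)) {
      f <- max(1L, round(tgt[1] / base[1]))
      rs <- nnup_fwd(x, f)
      rs$kind <- "up"
    } else {
      f <- max(1L, round(base[1] / tgt[1]))
      rs <- avgpool_fwd(x, f)
      rs$kind <- "pool"
    }
    d <- dim(rs$y)
    xm <- rs$y; dim(xm) <- c(prod(d[1:3]), d[4])
    pr <- linear_fwd(xm, params$adapters[[s]])
    y <- pr$y; dim(y) <- c(d[1:3], ncol(pr$y))
    skips[[s]] <- y
    caches[[s]] <- list(rs = rs, lin = pr$cache, dims = d)
  }
  list(skips = skips, cache = caches)
}

#' Decode a feature pyramid to per-voxel class probabilities
#'
#' Mirror-wired U-Net decoding: decoder stage `j` consumes encoder stage
#' `4 - j` as its skip. After the last fusion stage the features are
#' upsampled to the padded input resolution, the patch-partition padding is
#' cropped away, and a 1x1x1 convolution followed by a per-voxel softmax
#' yields the class distribution.
#'
#' @param pyr An `afno_pyramid` from [encode()].
#' @param params Decoder parameters (see [init_model()]).
#' @param num_classes `K >= 2`; must match the head width.
#' @param keep_logits Retain raw logits in the result?
#' @param spacing Voxel spacing propagated to the result's label map.
#' @return An `afno_segmentation`: list with `probabilities`
#'   (`(H, W, D, K)` array summing to 1 per voxel), `labels` (argmax
#'   `afno_labelmap`), and optionally `logits`.
#' @export
decode <- function(pyr, params, num_classes, keep_logits = FALSE,
                   spacing = c(1, 1, 1)) {
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (ncol(params$head$W) != num_classes) {
    stop("decoder head emits ", ncol(params$head$W), " classes, not ",
         num_classes)
  }
  out <- decode_fwd(pyr, params, keep_cache = FALSE)
  segmentation_result(out$logits, keep_logits = keep_logits,
                      spacing = spacing)
}

segmentation_result <- function(logits, keep_logits = FALSE,
                                spacing = c(1, 1, 1)) {
  probs <- softmax4(logits)
  structure(
    list(probabilities = probs,
         labels = predict_labels_from_probs(probs, spacing),
         logits = if (keep_logits) logits else NULL,
         spacing = spacing),
    class = "afno_segmentation"
  )
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- logits
  dim(m) <- c(prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

predict_labels_from_probs <- function(probs, spacing = c(1, 1, 1)) {
  d <- dim(probs)
  m <- probs
  dim(m) <- c(prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  as_labelmap(lab, num_classes = d[4], spacing = spacing)
}

#' Hard labels from a segmentation result
#'
#' Per-voxel argmax over the class distribution; ties break toward the
#' lowest class index.
#'
#' @param result An `afno_segmentation` from [decode()].
#' @return An `afno_labelmap`.
#' @export
predict_labels <- function(result) {
  stopifnot(inherits(result, "afno_segmentation"))
  predict_labels_from_probs(result$probabilities, result$spacing)
}
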