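#' Initialize a full segmentation model
#'
#' Builds encoder and decoder parameters for a reference input shape. The
#' learned positional table and spectral filters are stored on the token
#' grids implied by that shape; forward passes on other shapes resample the
#' positional table trilinearly and map spectral filters by signed frequency
#' (unseen frequencies receive the identity weight).
#'
#' @param config An [encoder_config()].
#' @param input_shape Length-3 reference spatial shape (e.g. the training
#'   window), each axis at least `16 * patch_size` in hierarchical mode.
#' @param in_channels Number of image channels.
#' @param num_classes Number of output classes `K >= 2`.
#' @param seed Integer seed for all weight initializations.
#' @return An `afno_model`.
#' @export
init_model <- function(config, input_shape, in_channels, num_classes,
                       seed = 0L) {
  stopifnot(inherits(config, "afno_encoder_config"))
  input_shape <- as.integer(input_shape)
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  enc <- init_encoder_params(config, input_shape, in_channels, seed = seed)
  dec <- init_decoder_params(config, num_classes, in_channels,
                             seed = seed + 1L)
  structure(
    list(config = config,
         params = list(encoder = enc, decoder = dec),
         input_shape = input_shape, in_channels = as.integer(in_channels),
         num_classes = num_classes, seed = as.integer(seed)),
    class = "afno_model"
  )
}

#' @export
print.afno_model <- function(x, ...) {
  cat(sprintf(
    "<afno_model> %s mixing, stages %s, K = %d classes, ref input %s\n",
    x$config$mixing_mode,
    paste(x$config$stage_channels, collapse = "/"),
    x$num_classes, paste(x$input_shape, collapse = "x")))
  invisible(x)
}

# full forward; x is an (H,W,D,C) array. Returns logits at input resolution
# plus caches for backprop when requested.
model_forward <- function(model, x, keep_cache = FALSE) {
  enc <- encode_fwd(x, model$config, model$params$encoder,
                    keep_cache = keep_cache)
  dec <- decode_fwd(enc$pyramid, model$params$decoder,
                    keep_cache = keep_cache)
  list(logits = dec$logits, pyramid = enc$pyramid,
       enc_cache = enc$cache, dec_cache = dec$cache)
}

# full backward from dL/dlogits; returns gradients mirroring model$params
model_backward <- function(model, dlogits, fw) {
  db <- decode_bwd(dlogits, fw$dec_cache, model$params$decoder)
  ge <- encode_bwd(db$dskips, fw$enc_cache, model$config,
                   model$params$encoder)
  list(encoder = ge, decoder = db$g)
}

# ---- encoder backward --------------------------------------------------------

encode_bwd <- function(dskips, cache, config, params) {
  if (config$constant_resolution) {
    return(encode_const_bwd(dskips, cache, config, params))
  }
  g_stages <- vector("list", 4)
  dx <- NULL        # token-matrix gradient flowing down from deeper stages
  for (s in 4:1) {
    sc <- cache$stages[[s]]
    sp <- params$stages[[s]]
    if (s < 4) {
      mb <- merge2_bwd(array_from_tokens(dx), sc$merge, sp$merge)
      darr <- mb$dx
      g_merge <- mb$g
    } else {
      darr <- NULL
      g_merge <- NULL
    }
    dstage <- dskips[[s]]
    if (!is.null(darr)) dstage <- dstage + darr
    d <- dim(dstage)
    dtok <- dstage
    dim(dtok) <- c(prod(d[1:3]), d[4])
    g_blocks <- vector("list", length(sc$blocks))
    for (b in rev(seq_along(sc$blocks))) {
      bb <- block_bwd(dtok, sc$blocks[[b]]$cache, sc$blocks[[b]]$p,
                      NULL, config)
      dtok <- bb$dx
      g_blocks[[b]] <- bb$g
    }
    g_stages[[s]] <- list(blocks = g_blocks, merge = g_merge)
    dx <- structure(dtok, grid = d[1:3])
  }
  part <- cache$part
  g_embed <- list(W_proj = crossprod(part$patches, dx),
                  E_pos = unclass_grad(dx),
                  grid = params$embed$grid * 0L)
  list(embed = g_embed, stages = g_stages,
       grids = lapply(params$grids, function(g) g * 0L))
}

encode_const_bwd <- function(dskips, cache, config, params) {
  nl <- config$num_layers
  marks <- cache$marks
  dtok <- NULL
  g_blocks <- vector("list", nl)
  for (b in nl:1) {
    mi <- which(marks == b)
    for (m in rev(mi)) {
      darr <- dskips[[m]]
      d <- dim(darr)
      dm <- darr; dim(dm) <- c(prod(d[1:3]), d[4])
      dtok <- if (is.null(dtok)) dm else dtok + dm
    }
    bb <- block_bwd(dtok, cache$blocks[[b]]$cache, cache$blocks[[b]]$p,
                    NULL, config)
    dtok <- bb$dx
    g_blocks[[b]] <- bb$g
  }
  part <- cache$part
  list(embed = list(W_proj = crossprod(part$patches, dtok),
                    E_pos = unclass_grad(dtok),
                    grid = params$grid * 0L),
       blocks = g_blocks, grid = params$grid * 0L)
}

array_from_tokens <- function(dx) {
  g <- attr(dx, "grid")
  a <- as.numeric(dx)
  dim(a) <- c(g, ncol(dx))
  a
}

unclass_grad <- function(dx) {
  a <- as.matrix(dx)
  attr(a, "grid") <- NULL
  a
}

# ---- AdamW -------------------------------------------------------------------
# Decoupled weight decay applied to weight matrices/arrays only (biases and
# normalization gains are exempt). Complex leaves (spectral filters) keep
# separate moments for real and imaginary parts and are re-projected onto
# the Hermitian-symmetric subspace after each update so the mixing path
# keeps mapping real signals to real signals.

adamw_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  step_leaf <- function(p, g, m, v) {
    if (is.complex(p)) {
      g <- herm_project_filter(g)
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) *
        complex(real = Re(g)^2, imaginary = Im(g)^2)
      mh <- m / bc1
      vr <- Re(v) / bc2; vi <- Im(v) / bc2
      upd <- complex(real = Re(mh) / (sqrt(vr) + eps),
                     imaginary = Im(mh) / (sqrt(vi) + eps))
      dim(upd) <- dim(p)
      p <- p - lr * upd - lr * weight_decay * p
      p <- herm_project_filter(p)
    } else {
      decay <- if (!is.null(dim(p))) weight_decay else 0
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps)) - lr * decay * p
    }
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        if (is.null(g[[i]])) next
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.integer(p) || is.character(p)) return(list(p = p, m = m, v = v))
    step_leaf(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
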