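#' Encoder configuration
#'
#' Describes the transformer encoder. In the default hierarchical form the
#' encoder has four stages: the patch embedding places tokens on an
#' `H/patch_size` grid at `stage_channels[1]` width, each stage applies its
#' transformer blocks, and patch merging halves the grid and re-projects the
#' channels between stages, giving stage outputs at `H/2^s` resolution with
#' channels `stage_channels[s]`. With `patch_size = 2` (the default) the
#' documented schedule `(H/2, 48), (H/4, 96), (H/8, 192), (H/16, 384)`
#' holds exactly.
#'
#' With `constant_resolution = TRUE` the encoder instead keeps one token
#' grid and width throughout (`embed_dim`, `num_layers`, patch size
#' `const_patch_size`), and the four skip sources are taken after each
#' quarter of the layer stack; the decoder resamples them to the mirror
#' resolutions.
#'
#' @param patch_size Patch edge length for the hierarchical stem.
#' @param stage_channels Four strictly increasing stage widths.
#' @param blocks_per_stage Transformer blocks per stage.
#' @param heads Attention heads per stage (used by `msa_only` mixing).
#' @param mixing_mode Token mixing: `"afno_3d"` (separable 3D spectral
#'   mixing, default), `"afno_1d"` (spectral mixing over the flattened token
#'   index), or `"msa_only"` (multi-head self-attention).
#' @param constant_resolution Keep one resolution/width through all layers?
#' @param embed_dim,num_layers,const_patch_size Constant-resolution settings
#'   (defaults 768, 12, 4).
#' @param mlp_ratio Hidden-width multiplier of the MLP blocks.
#' @return An `afno_encoder_config`.
#' @export
encoder_config <- function(patch_size = 2L,
                           stage_channels = c(48L, 96L, 192L, 384L),
                           blocks_per_stage = c(2L, 2L, 2L, 2L),
                           heads = c(4L, 4L, 8L, 8L),
                           mixing_mode = c("afno_3d", "afno_1d", "msa_only"),
                           constant_resolution = FALSE,
                           embed_dim = 768L, num_layers = 12L,
                           const_patch_size = 4L,
                           mlp_ratio = 4) {
  mixing_mode <- match.arg(mixing_mode)
  stage_channels <- as.integer(stage_channels)
  stopifnot(length(stage_channels) == 4L)
  if (!constant_resolution && any(diff(stage_channels) <= 0)) {
    stop("stage_channels must be strictly increasing in hierarchical mode")
  }
  if (mixing_mode == "msa_only" &&
      any(stage_channels %% as.integer(heads) != 0L)) {
    stop("each stage width must be divisible by its head count")
  }
  structure(
    list(patch_size = as.integer(patch_size),
         stage_channels = stage_channels,
         blocks_per_stage = as.integer(blocks_per_stage),
         heads = as.integer(heads),
         mixing_mode = mixing_mode,
         constant_resolution = isTRUE(constant_resolution),
         embed_dim = as.integer(embed_dim),
         num_layers = as.integer(num_layers),
         const_patch_size = as.integer(const_patch_size),
         mlp_ratio = mlp_ratio),
    class = "afno_encoder_config"
  )
}

# token grids per stage for a padded input shape
encoder_stage_grids <- function(config, input_shape) {
  P <- config$patch_size
  g <- ceiling(input_shape / P)
  grids <- vector("list", 4)
  for (s in 1:4) {
    grids[[s]] <- as.integer(g)
    g <- ceiling(g / 2)
  }
  grids
}

#' Trace encoder/decoder shapes without running a forward pass
#'
#' Pure shape arithmetic: returns the spatial grid and channel width of each
#' encoder stage for a given input shape and configuration. Useful for
#' checking the stage schedule of large configurations without allocating
#' features.
#'
#' @param config An [encoder_config()].
#' @param input_shape Length-3 spatial input shape.
#' @return List of four `list(grid, channels)` entries.
#' @export
trace_encoder_shapes <- function(config, input_shape) {
  input_shape <- as.integer(input_shape)
  if (config$constant_resolution) {
    g <- as.integer(ceiling(input_shape / config$const_patch_size))
    return(lapply(1:4, function(s) list(grid = g,
                                        channels = config$embed_dim)))
  }
  grids <- encoder_stage_grids(config, input_shape)
  lapply(1:4, function(s) list(grid = grids[[s]],
                               channels = config$stage_channels[s]))
}

# ---- parameter initialization ----------------------------------------------

init_block_params <- function(C, grid, config, stage) {
  p <- list(ln1 = init_layernorm(C), ln2 = init_layernorm(C),
            fc1 = init_linear(C, round(config$mlp_ratio * C)),
            fc2 = init_linear(round(config$mlp_ratio * C), C))
  if (config$mixing_mode == "msa_only") {
    p$msa <- init_msa(C)
  } else if (config$mixing_mode == "afno_1d") {
    p$filt <- matrix(complex(real = 1), prod(grid), C)
  } else {
    p$filt <- array(complex(real = 1), c(grid, C))
  }
  p
}

init_encoder_params <- function(config, input_shape, in_channels, seed = 0L) {
  withr::with_seed(as.integer(seed), {
    if (config$constant_resolution) {
      P <- config$const_patch_size
      grid <- as.integer(ceiling(input_shape / P))
      K <- config$embed_dim
      blocks <- lapply(seq_len(config$num_layers), function(i)
        init_block_params(K, grid, config, 1L))
      return(list(embed = init_embedding_params(P^3 * in_channels, K, grid,
                                                seed = stats::runif(1, 0, 1e6)),
                  blocks = blocks, grid = grid))
    }
    grids <- encoder_stage_grids(config, input_shape)
    ch <- config$stage_channels
    stages <- vector("list", 4)
    for (s in 1:4) {
      stages[[s]] <- list(
        blocks = lapply(seq_len(config$blocks_per_stage[s]), function(i)
          init_block_params(ch[s], grids[[s]], config, s)),
        merge = if (s < 4) init_merge2(ch[s], ch[s + 1]) else NULL
      )
    }
    list(embed = init_embedding_params(config$patch_size^3 * in_channels,
                                       ch[1], grids[[1]],
                                       seed = stats::runif(1, 0, 1e6)),
         stages = stages, grids = grids)
  })
}

# ---- transformer block forward/backward -------------------------------------

# x: N x C token matrix on `grid`. Returns list(y, cache).
block_fwd <- function(x, p, grid, config, heads = config$heads[1]) {
  c1 <- layernorm_fwd(x, p$ln1)
  if (config$mixing_mode == "msa_only") {
    mix <- msa_fwd(c1$y, p$msa, heads)
  } else if (config$mixing_mode == "afno_1d") {
    mix <- afno1d_fwd(c1$y, p$filt)
  } else {
    mix <- afno_filter_fwd(c1$y, p$filt, grid)
  }
  z <- x + mix$y
  c2 <- layernorm_fwd(z, p$ln2)
  f1 <- linear_fwd(c2$y, p$fc1)
  a1 <- gelu_fwd(f1$y)
  f2 <- linear_fwd(a1$y, p$fc2)
  y <- z + f2$y
  list(y = y, cache = list(c1 = c1, mix = mix, c2 = c2, f1 = f1, a1 = a1,
                           f2 = f2))
}

block_bwd <- function(dy, cache, p, grid, config) {
  b2 <- linear_bwd(dy, cache$f2$cache, p$fc2)
  da1 <- gelu_bwd(b2$dx, cache$a1$cache)
  b1 <- linear_bwd(da1, cache$f1$cache, p$fc1)
  l2 <- layernorm_bwd(b1$dx, cache$c2$cache, p$ln2)
  dz <- dy + l2$dx
  if (config$mixing_mode == "msa_only") {
    mb <- msa_bwd(dz, cache$mix$cache, p$msa)
    gmix <- list(msa = mb$g)
  } else if (config$mixing_mode == "afno_1d") {
    mb <- afno1d_bwd(dz, cache$mix$cache, p$filt)
    gmix <- list(filt = mb$g)
  } else {
    mb <- afno_filter_bwd(dz, cache$mix$cache, p$filt)
    gmix <- list(filt = mb$g)
  }
  l1 <- layernorm_bwd(mb$dx, cache$c1$cache, p$ln1)
  dx <- dz + l1$dx
  g <- c(list(ln1 = l1$g, ln2 = l2$g, fc1 = b1$g, fc2 = b2$g), gmix)
  list(dx = dx, g = g)
}

# 1D spectral mixing over the flattened token index, per channel
afno1d_fwd <- function(x, W) {
  N <- nrow(x)
  y <- x
  Xs <- vector("list", ncol(x))
  for (ch in seq_len(ncol(x))) {
    X <- stats::fft(x[, ch])
    Xs[[ch]] <- X
    y[, ch] <- Re(stats::fft(W[, ch] * X, inverse = TRUE) / N)
  }
  list(y = y, cache = list(Xs = Xs, N = N))
}

afno1d_bwd <- function(dy, cache, W) {
  N <- cache$N
  dx <- dy
  dW <- W * 0
  for (ch in seq_len(ncol(dy))) {
    G <- stats::fft(dy[, ch])
    dx[, ch] <- Re(stats::fft(W[, ch] * Conj(G)) / N)
    dW[, ch] <- Conj(cache$Xs[[ch]] * Conj(G) / N)
  }
  list(dx = dx, g = dW)
}

# ---- spec-surface single-block operations -----------------------------------

#' Pre-norm multi-head self-attention block
#'
#' Computes `z' = MSA(Norm(z)) + z`: layer normalization applied to the
#' residual-branch input, attention on the normalized tokens, and the
#' untouched input added back.
#'
#' @param tok A `TokenSequence`.
#' @param params Attention parameters (`q`, `k`, `v`, `o` affine maps with
#'   `W`, `b`) plus `ln` layer-norm gain/bias.
#' @param heads Number of attention heads; token width must divide evenly.
#' @return A `TokenSequence`.
#' @export
msa_block <- function(tok, params, heads = 1L) {
  K <- ncol(tok$tokens)
  if (K %% heads != 0L) {
    stop("token width ", K, " is not divisible by ", heads, " heads")
  }
  n <- layernorm_fwd(tok$tokens, params$ln)
  a <- msa_fwd(n$y, params, heads)
  tok$tokens <- tok$tokens + a$y
  tok
}

#' Pre-norm MLP block
#'
#' Computes `z = MLP(Norm(z')) + z'` with a two-layer perceptron and smooth
#' Gaussian-error activation between the affine maps.
#'
#' @param tok A `TokenSequence`.
#' @param params List with `ln` (layer norm), `fc1`, `fc2` affine maps.
#' @param activation `"gelu"` (default) or `"linear"` (identity activation,
#'   useful for algebraic checks).
#' @return A `TokenSequence`.
#' @export
mlp_block <- function(tok, params, activation = c("gelu", "linear")) {
  activation <- match.arg(activation)
  n <- layernorm_fwd(tok$tokens, params$ln)
  h <- linear_fwd(n$y, params$fc1)
  a <- if (activation == "gelu") gelu_fwd(h$y)$y else h$y
  o <- linear_fwd(a, params$fc2)
  tok$tokens <- tok$tokens + o$y
  tok
}

#' Patch merging: 2x token-grid downsampling
#'
#' Concatenates each 2x2x2 token neighbourhood (8 * C_in values, h-fastest
#' block order) and applies a learned linear map to `C_out` channels. Odd
#' grid axes are zero-padded by one before merging.
#'
#' @param x Feature array `(h, w, d, C_in)` or `TokenSequence`.
#' @param params List with `W` (`8*C_in x C_out`) and `b`.
#' @return Feature array on the halved grid with `C_out` channels.
#' @export
patch_merge <- function(x, params) {
  if (inherits(x, "afno_tokens")) {
    arr <- x$tokens
    dim(arr) <- c(x$grid, ncol(x$tokens))
    x <- arr
  }
  merge2_fwd(x, params)$y
}

# ---- full encoder ------------------------------------------------------------

#' Run the hierarchical encoder
#'
#' Partitions the volume into patches, embeds them with positional
#' encodings, and runs the four encoder stages (transformer blocks with the
#' configured token mixing, patch merging between stages). Returns the
#' feature pyramid of the four stage outputs, the skip sources for the
#' decoder.
#'
#' @param vol An `afno_volume`.
#' @param config An [encoder_config()].
#' @param params Parameters from [init_model()]/`init_encoder_params`;
#'   positional tables and spectral filters are adapted automatically when
#'   the input grid differs from the reference grid they were built for.
#' @return An `afno_pyramid`: list with `stages` (four `(h,w,d,C)` arrays),
#'   `pad_amounts`, `input_shape`.
#' @export
encode <- function(vol, config, params) {
  stopifnot(inherits(vol, "afno_volume"))
  out <- encode_fwd(vol$data, config, params, keep_cache = FALSE)
  out$pyramid
}

# forward with optional cache for backprop; x is the (H,W,D,C) array
encode_fwd <- function(x, config, params, keep_cache = TRUE) {
  d <- dim(x)
  P <- if (config$constant_resolution) config$const_patch_size else
    config$patch_size
  minsize <- if (config$constant_resolution) P else 16L * P
  if (any(d[1:3] < minsize)) {
    stop("input spatial shape (", paste(d[1:3], collapse = "x"),
         ") is below the minimum ", minsize, " per axis for this config")
  }
  part <- partition_patches(as_volume(x), P)
  if (config$constant_resolution) {
    return(encode_const_fwd(part, config, params, keep_cache, d))
  }
  embed_p <- params$embed
  E <- resample_pos_table(embed_p$E_pos, embed_p$grid, part$grid)
  tokens <- part$patches %*% embed_p$W_proj + E
  grid <- part$grid
  caches <- list(part = part, E_grid = part$grid)
  stage_out <- vector("list", 4)
  stage_caches <- vector("list", 4)
  xk <- tokens
  for (s in 1:4) {
    sp <- params$stages[[s]]
    bl_caches <- vector("list", length(sp$blocks))
    for (b in seq_along(sp$blocks)) {
      bp <- adapt_block_filter(sp$blocks[[b]], params$grids[[s]], grid, config)
      fw <- block_fwd(xk, bp, grid, config, heads = config$heads[s])
      xk <- fw$y
      if (keep_cache) bl_caches[[b]] <- list(cache = fw$cache, p = bp)
    }
    arr <- xk
    dim(arr) <- c(grid, ncol(xk))
    stage_out[[s]] <- arr
    if (s < 4) {
      mg <- merge2_fwd(arr, sp$merge)
      if (keep_cache) stage_caches[[s]] <- list(blocks = bl_caches,
                                                merge = mg$cache)
      grid <- dim(mg$y)[1:3]
      xk <- mg$y
      dim(xk) <- c(prod(grid), dim(mg$y)[4])
    } else if (keep_cache) {
      stage_caches[[s]] <- list(blocks = bl_caches)
    }
  }
  pyramid <- structure(list(stages = stage_out,
                            pad_amounts = part$pad_amounts,
                            input_shape = d[1:3],
                            constant_resolution = FALSE),
                       class = "afno_pyramid")
  list(pyramid = pyramid,
       cache = if (keep_cache) list(part = part, stages = stage_caches,
                                    E = E) else NULL)
}

encode_const_fwd <- function(part, config, params, keep_cache, d) {
  embed_p <- params$embed
  E <- resample_pos_table(embed_p$E_pos, embed_p$grid, part$grid)
  xk <- part$patches %*% embed_p$W_proj + E
  grid <- part$grid
  nl <- config$num_layers
  marks <- unique(pmax(1L, round(nl * (1:4) / 4)))
  while (length(marks) < 4L) marks <- c(marks, nl)
  stage_out <- vector("list", 4)
  bl_caches <- vector("list", nl)
  si <- 1L
  for (b in seq_len(nl)) {
    bp <- adapt_block_filter(params$blocks[[b]], params$grid, grid, config)
    fw <- block_fwd(xk, bp, grid, config)
    xk <- fw$y
    if (keep_cache) bl_caches[[b]] <- list(cache = fw$cache, p = bp)
    if (si <= 4L && b == marks[si]) {
      arr <- xk
      dim(arr) <- c(grid, ncol(xk))
      stage_out[[si]] <- arr
      si <- si + 1L
    }
  }
  pyramid <- structure(list(stages = stage_out,
                            pad_amounts = part$pad_amounts,
                            input_shape = d[1:3],
                            constant_resolution = TRUE),
                       class = "afno_pyramid")
  list(pyramid = pyramid,
       cache = if (keep_cache) list(part = part, blocks = bl_caches,
                                    marks = marks, E = E) else NULL)
}

# Map a spectral filter trained on `from` grid onto `to` grid by matching
# signed frequencies; unseen frequencies get the identity weight 1.
adapt_block_filter <- function(bp, from, to, config) {
  if (config$mixing_mode == "msa_only") return(bp)
  if (config$mixing_mode == "afno_1d") {
    Nf <- nrow(bp$filt); Nt <- prod(to)
    if (Nf == Nt) return(bp)
    W <- matrix(complex(real = 1), Nt, ncol(bp$filt))
    idx <- match_freqs(Nf, Nt)
    ok <- !is.na(idx)
    W[ok, ] <- bp$filt[idx[ok], ]
    bp$filt <- W
    return(bp)
  }
  df <- dim(bp$filt)
  if (all(df[1:3] == to)) return(bp)
  C <- df[4]
  W <- array(complex(real = 1), c(to, C))
  i1 <- match_freqs(df[1], to[1])
  i2 <- match_freqs(df[2], to[2])
  i3 <- match_freqs(df[3], to[3])
  o1 <- which(!is.na(i1)); o2 <- which(!is.na(i2)); o3 <- which(!is.na(i3))
  W[o1, o2, o3, ] <- bp$filt[i1[o1], i2[o2], i3[o3], , drop = FALSE]
  bp$filt <- W
  bp
}

# for each DFT bin of an n_to axis, the bin of the n_from axis carrying the
# same signed frequency (NA when the source axis never saw that frequency)
match_freqs <- function(n_from, n_to) {
  sf_to <- ifelse(seq_len(n_to) - 1 <= n_to %/% 2,
                  seq_len(n_to) - 1, seq_len(n_to) - 1 - n_to)
  max_pos <- (n_from - 1) %/% 2
  max_neg <- n_from %/% 2
  idx <- rep(NA_integer_, n_to)
  ok_pos <- sf_to >= 0 & sf_to <= max_pos
  ok_neg <- sf_to < 0 & -sf_to <= max_neg
  idx[ok_pos] <- sf_to[ok_pos] + 1L
  idx[ok_neg] <- n_from + sf_to[ok_neg] + 1L
  idx
}
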