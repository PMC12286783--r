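#' Partition a volume into non-overlapping cubic patches
#'
#' The volume is zero-padded at the high end of each spatial axis up to the
#' next multiple of `P`, then cut into `P x P x P` blocks. Patches are
#' enumerated with the H patch index varying fastest, then W, then D (the
#' native column-major order of the token grid); within a patch, values are
#' flattened in `(h, w, d, channel)` order with `h` fastest and the channel
#' axis last. Both orders are frozen and pinned by tests: un-partitioning and
#' cropping the recorded padding recovers the input bit-exactly.
#'
#' @param vol An [as_volume()] object.
#' @param P Patch edge length, a positive integer.
#' @return List with `patches` (matrix `N x P^3*C`), `grid` (token-grid shape
#'   `(h, w, d)`), `pad_amounts` (zero-padding added per axis) and
#'   `channels`.
#' @export
partition_patches <- function(vol, P) {
  stopifnot(inherits(vol, "afno_volume"))
  P <- as.integer(P)
  if (P <= 0L) stop("patch size P must be a positive integer")
  d <- dim(vol$data)
  pad <- (P - d[1:3] %% P) %% P
  x <- vol$data
  if (any(pad > 0L)) {
    padded <- array(0, c(d[1:3] + pad, d[4]))
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- padded
  }
  dp <- dim(x)
  grid <- dp[1:3] %/% P
  C <- dp[4]
  # (P,h,P,w,P,d,C) -> (P,P,P,C, h,w,d) -> (P^3*C) x N -> transpose
  dim(x) <- c(P, grid[1], P, grid[2], P, grid[3], C)
  x <- aperm(x, c(1, 3, 5, 7, 2, 4, 6))
  dim(x) <- c(P^3 * C, prod(grid))
  list(patches = t(x), grid = grid, pad_amounts = pad, channels = C)
}

#' Reassemble a volume from a patch matrix
#'
#' Inverse of [partition_patches()]: lays the patch rows back on the padded
#' grid and crops the recorded padding.
#'
#' @param patches Matrix `N x P^3*C` in the frozen flattening order.
#' @param grid Token-grid shape `(h, w, d)`.
#' @param P Patch edge length.
#' @param channels Number of channels `C`.
#' @param pad_amounts Padding recorded by [partition_patches()].
#' @param spacing Voxel spacing for the rebuilt volume.
#' @return An `afno_volume`.
#' @export
unpartition_patches <- function(patches, grid, P, channels,
                                pad_amounts = c(0L, 0L, 0L),
                                spacing = c(1, 1, 1)) {
  x <- t(patches)
  dim(x) <- c(P, P, P, channels, grid[1], grid[2], grid[3])
  x <- aperm(x, c(1, 5, 2, 6, 3, 7, 4))
  dims <- c(grid * P, channels)
  dim(x) <- dims
  keep <- dims[1:3] - pad_amounts
  as_volume(x[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]), ,
              drop = FALSE],
            spacing = spacing)
}

#' Initialize patch-embedding parameters
#'
#' The projection matrix maps flattened patches (`P^3 * C` values) to
#' `embed_dim`-dimensional tokens; the positional table holds one learnable
#' `embed_dim` vector per 3D token-grid position, initialized from a
#' zero-mean Gaussian with standard deviation 0.02 (fixed sinusoids are not
#' used). When a forward pass later encounters a different token grid, the
#' table is trilinearly resampled to the new grid.
#'
#' @param patch_dim `P^3 * C`, the flattened patch width.
#' @param embed_dim Token width `K`.
#' @param grid Reference token-grid shape the positional table is stored on.
#' @param seed Integer seed for the Gaussian initializations.
#' @return List with `W_proj` (`patch_dim x embed_dim`), `E_pos`
#'   (`N x embed_dim`), `grid`.
#' @export
init_embedding_params <- function(patch_dim, embed_dim, grid, seed = 0L) {
  withr::with_seed(as.integer(seed), {
    list(
      W_proj = matrix(stats::rnorm(patch_dim * embed_dim,
                                   sd = 1 / sqrt(patch_dim)),
                      patch_dim, embed_dim),
      E_pos = matrix(stats::rnorm(prod(grid) * embed_dim, sd = 0.02),
                     prod(grid), embed_dim),
      grid = as.integer(grid)
    )
  })
}

#' Project patches to token embeddings
#'
#' Computes `tokens = patches %*% W_proj + E_pos`: a linear projection of
#' each flattened patch plus a learned positional encoding per token-grid
#' position.
#'
#' @param patches Matrix `N x P^3*C` from [partition_patches()].
#' @param params List with `W_proj` and `E_pos` (see
#'   [init_embedding_params()]).
#' @param grid Token-grid shape `(h, w, d)` with `prod(grid) == nrow(patches)`.
#' @param patch_size The patch edge length `P`, carried as metadata.
#' @param pad_amounts Padding metadata carried through to the decoder.
#' @return A `TokenSequence`: list with `tokens` (`N x K`), `grid`,
#'   `patch_size`, `pad_amounts`.
#' @export
embed_patches <- function(patches, params, grid,
                          patch_size = NA_integer_,
                          pad_amounts = c(0L, 0L, 0L)) {
  if (ncol(patches) != nrow(params$W_proj)) {
    stop("patch width ", ncol(patches), " does not match W_proj rows ",
         nrow(params$W_proj))
  }
  E <- params$E_pos
  if (nrow(E) != nrow(patches)) {
    stop("E_pos has ", nrow(E), " rows but there are ", nrow(patches),
         " tokens")
  }
  tok <- patches %*% params$W_proj + E
  token_sequence(tok, grid, patch_size = patch_size,
                 pad_amounts = pad_amounts)
}

#' @keywords internal
token_sequence <- function(tokens, grid, patch_size = NA_integer_,
                           pad_amounts = c(0L, 0L, 0L)) {
  grid <- as.integer(grid)
  if (prod(grid) != nrow(tokens)) {
    stop("token count ", nrow(tokens), " != prod(grid) = ", prod(grid))
  }
  structure(list(tokens = tokens, grid = grid,
                 patch_size = as.integer(patch_size),
                 pad_amounts = as.integer(pad_amounts)),
            class = "afno_tokens")
}

# Trilinear resampling of a positional table stored on `from` grid to a
# `to` grid; used when a model trained at one window size runs on another.
resample_pos_table <- function(E, from, to) {
  if (all(from == to)) return(E)
  K <- ncol(E)
  arrE <- array(E, c(from, K))
  coords <- lapply(1:3, function(a) {
    if (to[a] == 1L) rep((from[a] + 1) / 2, 1)
    else (seq_len(to[a]) - 1) * (from[a] - 1) / (to[a] - 1) + 1
  })
  out <- array(0, c(to, K))
  for (k in seq_len(K)) {
    out[, , , k] <- trilinear_grid_sample(arrE[, , , k],
                                          coords[[1]], coords[[2]], coords[[3]])
  }
  matrix(out, prod(to), K)
}

# sample a rank-3 array at the tensor grid given by 1-based fractional
# coordinates along each axis (separable trilinear interpolation)
trilinear_grid_sample <- function(a, cx, cy, cz) {
  interp_axis <- function(x, coord, axis) {
    n <- dim(x)[axis]
    lo <- pmax(pmin(floor(coord), n - 1), 1)
    hi <- lo + 1
    w <- coord - lo
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    dim(xp) <- c(dp[1], prod(dp[-1]))
    yp <- xp[lo, , drop = FALSE] * (1 - w) + xp[hi, , drop = FALSE] * w
    dim(yp) <- c(length(coord), dp[-1])
    aperm(yp, order(perm))
  }
  a <- interp_axis(a, cx, 1)
  a <- interp_axis(a, cy, 2)
  interp_axis(a, cz, 3)
}
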