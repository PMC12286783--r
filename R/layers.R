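# Low-level differentiable layers.
#
# Every layer is a pair of pure functions: `*_fwd(x, p)` returning
# `list(y, cache)` and `*_bwd(dy, cache, p)` returning `list(dx, g)` with `g`
# mirroring the parameter structure. Gradients are hand-derived and pinned by
# finite-difference tests; feature maps are `(h, w, d, C)` arrays or `N x C`
# matrices in the package's frozen column-major token order, so array/matrix
# conversion is a `dim<-` with no data movement.

LN_EPS <- 1e-5

# ---- parameter-tree utilities ------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  tree_map2(`+`, a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

# ---- affine ------------------------------------------------------------------

linear_fwd <- function(x, p) {
  y <- x %*% p$W
  y <- sweep(y, 2, p$b, `+`)
  list(y = y, cache = x)
}

linear_bwd <- function(dy, cache, p) {
  list(dx = dy %*% t(p$W),
       g = list(W = crossprod(cache, dy), b = colSums(dy)))
}

init_linear <- function(n_in, n_out, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(n_in)
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

# ---- layer normalization (over the channel/feature axis) ---------------------

layernorm_fwd <- function(x, p) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, p$g, `*`), 2, p$b, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, p$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx,
       g = list(g = colSums(dy * xhat), b = colSums(dy)))
}

init_layernorm <- function(n) list(g = rep(1, n), b = numeric(n))

# ---- GELU (exact Gaussian-error form) ---------------------------------------

gelu_fwd <- function(x) {
  list(y = x * stats::pnorm(x), cache = x)
}

gelu_bwd <- function(dy, cache) {
  x <- cache
  dy * (stats::pnorm(x) + x * stats::dnorm(x))
}

# ---- spectral (AFNO) filter layer -------------------------------------------
# y[,c] = Re( IFFT( W[,c] * FFT(x[,c]) ) ), separably 3D over the token grid.
# Parameter gradient convention for the complex filter: Re(dW) = dL/dRe(W),
# Im(dW) = dL/dIm(W).

afno_filter_fwd <- function(x, W, grid) {
  C <- ncol(x)
  N <- prod(grid)
  y <- x
  Xs <- vector("list", C)
  for (ch in seq_len(C)) {
    X <- stats::fft(array(x[, ch], grid))
    Xs[[ch]] <- X
    Wc <- W[, , , ch]
    dim(Wc) <- grid
    y[, ch] <- as.vector(Re(stats::fft(Wc * X, inverse = TRUE) / N))
  }
  list(y = y, cache = list(Xs = Xs, grid = grid))
}

afno_filter_bwd <- function(dy, cache, W) {
  grid <- cache$grid
  N <- prod(grid)
  C <- ncol(dy)
  dx <- dy
  dW <- W * 0
  for (ch in seq_len(C)) {
    G <- stats::fft(array(dy[, ch], grid))   # FFT of upstream gradient
    Wc <- W[, , , ch]
    dim(Wc) <- grid
    # adjoint of the modulation path
    dx[, ch] <- as.vector(Re(stats::fft(Wc * Conj(G)) / N))
    Gk <- (cache$Xs[[ch]] * Conj(G)) / N
    dW[, , , ch] <- Conj(Gk)
  }
  list(dx = dx, g = dW)
}

# ---- multi-head self-attention ----------------------------------------------

msa_fwd <- function(x, p, heads) {
  N <- nrow(x); K <- ncol(x)
  dk <- K %/% heads
  q <- linear_fwd(x, p$q); k <- linear_fwd(x, p$k); v <- linear_fwd(x, p$v)
  ctx <- matrix(0, N, K)
  As <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    S <- q$y[, cols, drop = FALSE] %*% t(k$y[, cols, drop = FALSE]) / sqrt(dk)
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    As[[h]] <- A
    ctx[, cols] <- A %*% v$y[, cols, drop = FALSE]
  }
  o <- linear_fwd(ctx, p$o)
  list(y = o$y,
       cache = list(x = x, q = q, k = k, v = v, As = As, ctx = ctx,
                    heads = heads, dk = dk))
}

msa_bwd <- function(dy, cache, p) {
  heads <- cache$heads; dk <- cache$dk
  ob <- linear_bwd(dy, cache$ctx, p$o)
  dctx <- ob$dx
  dq <- cache$q$y * 0; dkk <- dq; dv <- dq
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    A <- cache$As[[h]]
    Vh <- cache$v$y[, cols, drop = FALSE]
    dA <- dctx[, cols, drop = FALSE] %*% t(Vh)
    dv[, cols] <- t(A) %*% dctx[, cols, drop = FALSE]
    # softmax backward, row-wise
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dk)
    dq[, cols] <- dS %*% cache$k$y[, cols, drop = FALSE]
    dkk[, cols] <- t(dS) %*% cache$q$y[, cols, drop = FALSE]
  }
  qb <- linear_bwd(dq, cache$x, p$q)
  kb <- linear_bwd(dkk, cache$x, p$k)
  vb <- linear_bwd(dv, cache$x, p$v)
  list(dx = qb$dx + kb$dx + vb$dx,
       g = list(q = qb$g, k = kb$g, v = vb$g, o = ob$g))
}

init_msa <- function(K) {
  list(q = init_linear(K, K), k = init_linear(K, K),
       v = init_linear(K, K), o = init_linear(K, K))
}

# ---- 3x3x3 "same" convolution on (h,w,d,C) arrays ---------------------------
# Implemented as a sum over the 27 kernel offsets of shifted-slice matrix
# products, which keeps peak memory at one feature map rather than an
# im2col buffer.

conv3_fwd <- function(x, p) {
  d <- dim(x)
  sp <- d[1:3]; Cin <- d[4]
  Cout <- dim(p$W)[5]
  xp <- array(0, c(sp + 2L, Cin))
  xp[2:(sp[1] + 1), 2:(sp[2] + 1), 2:(sp[3] + 1), ] <- x
  nvox <- prod(sp)
  y <- matrix(rep(p$b, each = nvox), nvox, Cout)
  for (oh in 1:3) for (ow in 1:3) for (od in 1:3) {
    xs <- xp[oh:(oh + sp[1] - 1), ow:(ow + sp[2] - 1),
             od:(od + sp[3] - 1), , drop = FALSE]
    dim(xs) <- c(nvox, Cin)
    y <- y + xs %*% p$W[oh, ow, od, , ]
  }
  dim(y) <- c(sp, Cout)
  list(y = y, cache = xp)
}

conv3_bwd <- function(dy, cache, p) {
  xp <- cache
  dp <- dim(xp)
  sp <- dp[1:3] - 2L; Cin <- dp[4]
  Cout <- dim(dy)[4]
  nvox <- prod(sp)
  dym <- dy; dim(dym) <- c(nvox, Cout)
  dW <- p$W * 0
  dxp <- xp * 0
  for (oh in 1:3) for (ow in 1:3) for (od in 1:3) {
    ih <- oh:(oh + sp[1] - 1); iw <- ow:(ow + sp[2] - 1)
    id <- od:(od + sp[3] - 1)
    xs <- xp[ih, iw, id, , drop = FALSE]
    dim(xs) <- c(nvox, Cin)
    Wo <- matrix(p$W[oh, ow, od, , ], Cin, Cout)
    dW[oh, ow, od, , ] <- crossprod(xs, dym)
    dxs <- dym %*% t(Wo)
    dim(dxs) <- c(sp, Cin)
    dxp[ih, iw, id, ] <- dxp[ih, iw, id, , drop = FALSE] + dxs
  }
  dx <- dxp[2:(sp[1] + 1), 2:(sp[2] + 1), 2:(sp[3] + 1), , drop = FALSE]
  list(dx = dx, g = list(W = dW, b = colSums(dym)))
}

init_conv3 <- function(Cin, Cout) {
  list(W = array(stats::rnorm(27 * Cin * Cout, sd = 1 / sqrt(27 * Cin)),
                 c(3, 3, 3, Cin, Cout)),
       b = numeric(Cout))
}

# identity-configured 3x3x3 kernel: passes the first min(Cin,Cout) channels
# through unchanged (used in tests and worked examples)
conv3_identity <- function(Cin, Cout) {
  W <- array(0, c(3, 3, 3, Cin, Cout))
  for (c in seq_len(min(Cin, Cout))) W[2, 2, 2, c, c] <- 1
  list(W = W, b = numeric(Cout))
}

# ---- 1x1x1 convolution (a per-voxel linear map) -----------------------------

conv1_fwd <- function(x, p) {
  d <- dim(x)
  nvox <- prod(d[1:3])
  xm <- x; dim(xm) <- c(nvox, d[4])
  out <- linear_fwd(xm, p)
  y <- out$y; dim(y) <- c(d[1:3], ncol(p$W))
  list(y = y, cache = out$cache)
}

conv1_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  nvox <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(nvox, d[4])
  out <- linear_bwd(dym, cache, p)
  dx <- out$dx; dim(dx) <- c(d[1:3], nrow(p$W))
  list(dx = dx, g = out$g)
}

# ---- 2x stride-2 transposed convolution (learned upsampling) ----------------
# Each input voxel emits a 2x2x2 output block: a linear map Cin -> 8*Cout
# followed by block reassembly (the exact inverse layout of patch merging).

tconv2_fwd <- function(x, p) {
  d <- dim(x)
  sp <- d[1:3]; Cin <- d[4]
  Cout <- length(p$b)
  nvox <- prod(sp)
  xm <- x; dim(xm) <- c(nvox, Cin)
  y8 <- xm %*% p$W
  y8 <- sweep(y8, 2, rep(p$b, each = 8), `+`)
  # columns are (2,2,2,Cout) h-fastest, channel last
  y <- t(y8)
  dim(y) <- c(2, 2, 2, Cout, sp[1], sp[2], sp[3])
  y <- aperm(y, c(1, 5, 2, 6, 3, 7, 4))
  dim(y) <- c(2L * sp, Cout)
  list(y = y, cache = xm)
}

tconv2_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  sp <- d[1:3] %/% 2L; Cout <- d[4]
  Cin <- nrow(p$W)
  nvox <- prod(sp)
  g <- dy
  dim(g) <- c(2, sp[1], 2, sp[2], 2, sp[3], Cout)
  g <- aperm(g, c(1, 3, 5, 7, 2, 4, 6))
  dim(g) <- c(8L * Cout, nvox)
  g8 <- t(g)
  db8 <- colSums(g8)
  dim(db8) <- c(8, Cout)
  dx <- g8 %*% t(p$W)
  dim(dx) <- c(sp, Cin)
  list(dx = dx,
       g = list(W = crossprod(cache, g8), b = colSums(db8)))
}

init_tconv2 <- function(Cin, Cout) {
  list(W = matrix(stats::rnorm(Cin * 8 * Cout, sd = 1 / sqrt(Cin)),
                  Cin, 8 * Cout),
       b = numeric(Cout))
}

# ---- patch merging (2x downsampling by 2x2x2 concat + linear) ---------------
# Odd grid axes are zero-padded by one (recorded in the returned cache).

merge2_fwd <- function(x, p) {
  d <- dim(x)
  sp <- d[1:3]; C <- d[4]
  pad <- sp %% 2L
  if (any(pad > 0L)) {
    xp <- array(0, c(sp + pad, C))
    xp[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), ] <- x
    x <- xp
  }
  spp <- dim(x)[1:3]
  g2 <- spp %/% 2L
  dim(x) <- c(2, g2[1], 2, g2[2], 2, g2[3], C)
  x <- aperm(x, c(1, 3, 5, 7, 2, 4, 6))
  dim(x) <- c(8L * C, prod(g2))
  x8 <- t(x)
  y <- sweep(x8 %*% p$W, 2, p$b, `+`)
  dim(y) <- c(g2, ncol(p$W))
  list(y = y, cache = list(x8 = x8, sp = sp, pad = pad, C = C))
}

merge2_bwd <- function(dy, cache, p) {
  d <- dim(dy)
  g2 <- d[1:3]; Cout <- d[4]
  nvox <- prod(g2)
  dym <- dy; dim(dym) <- c(nvox, Cout)
  dx8 <- dym %*% t(p$W)
  C <- cache$C
  dx <- t(dx8)
  dim(dx) <- c(2, 2, 2, C, g2[1], g2[2], g2[3])
  dx <- aperm(dx, c(1, 5, 2, 6, 3, 7, 4))
  dim(dx) <- c(2L * g2, C)
  sp <- cache$sp
  dx <- dx[seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), , drop = FALSE]
  list(dx = dx, g = list(W = crossprod(cache$x8, dym), b = colSums(dym)))
}

init_merge2 <- function(Cin, Cout) {
  list(W = matrix(stats::rnorm(8 * Cin * Cout, sd = 1 / sqrt(8 * Cin)),
                  8 * Cin, Cout),
       b = numeric(Cout))
}

# ---- integer-factor resize of feature maps (constant-resolution adapter) ----

avgpool_fwd <- function(x, f) {
  if (f == 1L) return(list(y = x, cache = list(f = 1L)))
  d <- dim(x)
  sp <- d[1:3]; C <- d[4]
  g <- sp %/% f
  xx <- x[seq_len(g[1] * f), seq_len(g[2] * f), seq_len(g[3] * f), ,
          drop = FALSE]
  dim(xx) <- c(f, g[1], f, g[2], f, g[3], C)
  y <- apply(xx, c(2, 4, 6, 7), mean)
  list(y = y, cache = list(f = f, sp = sp, C = C))
}

avgpool_bwd <- function(dy, cache) {
  f <- cache$f
  if (f == 1L) return(dy)
  d <- dim(dy)
  g <- d[1:3]; C <- d[4]
  dx <- array(0, c(cache$sp, C))
  up <- dy[rep(seq_len(g[1]), each = f),
           rep(seq_len(g[2]), each = f),
           rep(seq_len(g[3]), each = f), , drop = FALSE] / f^3
  dx[seq_len(g[1] * f), seq_len(g[2] * f), seq_len(g[3] * f), ] <- up
  dx
}

nnup_fwd <- function(x, f) {
  if (f == 1L) return(list(y = x, cache = list(f = 1L)))
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = f),
         rep(seq_len(d[2]), each = f),
         rep(seq_len(d[3]), each = f), , drop = FALSE]
  list(y = y, cache = list(f = f, sp = d[1:3]))
}

nnup_bwd <- function(dy, cache) {
  f <- cache$f
  if (f == 1L) return(dy)
  sp <- cache$sp
  d <- dim(dy)
  dd <- dy
  dim(dd) <- c(f, sp[1], f, sp[2], f, sp[3], d[4])
  apply(dd, c(2, 4, 6, 7), sum)
}
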