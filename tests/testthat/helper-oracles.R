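# Independent oracles used across the suite. These are deliberately naive
# (direct sums, per-voxel loops) and share no code with the implementation.

# O(N^2) direct-summation DFT / inverse DFT
naive_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * (0:(N - 1)) * k / N)), complex(1))
}

naive_idft <- function(F) {
  N <- length(F)
  vapply(0:(N - 1), function(n)
    sum(F * exp(2i * pi * (0:(N - 1)) * n / N)) / N, complex(1))
}

# hand-rolled single-head attention: softmax(Q K^T / sqrt(d)) V, plus the
# surrounding pre-norm residual wiring
naive_attention_block <- function(x, params) {
  ln <- function(z, g, b) {
    t(apply(z, 1, function(r) {
      m <- mean(r); v <- mean((r - m)^2)
      ((r - m) / sqrt(v + 1e-5)) * g + b
    }))
  }
  n <- ln(x, params$ln$g, params$ln$b)
  aff <- function(z, p) sweep(z %*% p$W, 2, p$b, `+`)
  Q <- aff(n, params$q); K <- aff(n, params$k); V <- aff(n, params$v)
  d <- ncol(Q)
  S <- Q %*% t(K) / sqrt(d)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  if (nrow(S) == 1L) A <- matrix(1, 1, 1)
  x + aff(A %*% V, params$o)
}

# per-voxel counting-loop Dice
brute_dice <- function(T, S) {
  T <- as.vector(T); S <- as.vector(S)
  inter <- 0; nT <- 0; nS <- 0
  for (i in seq_along(T)) {
    if (T[i]) nT <- nT + 1
    if (S[i]) nS <- nS + 1
    if (T[i] && S[i]) inter <- inter + 1
  }
  if (nT + nS == 0) return(1)
  2 * inter / (nT + nS)
}

# all-pairs directed nearest distances + closest-rank linear interpolation
brute_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

brute_hd <- function(A, B, q = 95) {
  dmin <- function(P, Q) {
    apply(P, 1, function(p) {
      min(sqrt(rowSums(sweep(Q, 2, p)^2)))
    })
  }
  max(brute_percentile(dmin(A, B), q), brute_percentile(dmin(B, A), q))
}

# brute-force voxel-centre inside-ellipsoid count
brute_ellipsoid_count <- function(grid, center, radii) {
  cnt <- 0
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2]))
    for (k in seq_len(grid[3])) {
      u <- (c(i, j, k) - 0.5) / grid
      if (sum(((u - center) / radii)^2) <= 1) cnt <- cnt + 1
    }
  cnt
}

# small shared fixtures -------------------------------------------------------

tiny_encoder_config <- function(...) {
  encoder_config(stage_channels = c(4L, 6L, 8L, 10L),
                 blocks_per_stage = c(1L, 1L, 1L, 1L), ...)
}

sphere_phantom_spec <- function(grid = c(32, 32, 32), noise = 5, blur = 0.5) {
  phantom_spec(grid = grid, channels = 1, num_classes = 2,
               organs = list(list(class_id = 1L, shape = "ellipsoid",
                                  center = c(0.5, 0.5, 0.5),
                                  radii = c(0.3, 0.3, 0.3))),
               intensity_table = rbind(0, 100),
               noise_sigma = noise, blur_sigma = blur)
}

random_volume <- function(shape, channels = 1, seed = 1) {
  withr::with_seed(seed, as_volume(array(stats::rnorm(prod(shape) * channels),
                                         c(shape, channels))))
}
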