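make_msa_params <- function(K, seed = 1) {
  withr::with_seed(seed, c(afnoseg:::init_msa(K),
                           list(ln = afnoseg:::init_layernorm(K))))
}

test_that("attention block degenerates correctly and matches the oracle", {
  K <- 4L
  p <- make_msa_params(K, seed = 2)

  # single token: softmax over one key is 1 -> out = z + O(V(Norm(z)))
  z1 <- matrix(stats::rnorm(K), 1, K)
  tok1 <- afnoseg:::token_sequence(z1, c(1L, 1L, 1L))
  out1 <- msa_block(tok1, p, heads = 1L)
  n <- afnoseg:::layernorm_fwd(z1, p$ln)$y
  v <- afnoseg:::linear_fwd(n, p$v)$y
  o <- afnoseg:::linear_fwd(v, p$o)$y
  expect_lt(max(abs(out1$tokens - (z1 + o))), 1e-10)

  # zero projections: pure residual
  p0 <- p
  for (nm in c("q", "k", "v", "o")) {
    p0[[nm]]$W <- p0[[nm]]$W * 0
    p0[[nm]]$b <- p0[[nm]]$b * 0
  }
  z <- matrix(stats::rnorm(3 * K), 3, K)
  tok <- afnoseg:::token_sequence(z, c(3L, 1L, 1L))
  expect_equal(msa_block(tok, p0, heads = 1L)$tokens, z)

  # N = 3, K = 4, one head vs the hand-rolled oracle
  out <- msa_block(tok, p, heads = 1L)
  expect_lt(max(abs(out$tokens - naive_attention_block(z, p))), 1e-8)

  expect_error(msa_block(tok, p, heads = 3L), "divisible")
})

test_that("MLP block follows the pre-norm residual wiring", {
  K <- 5L
  z <- matrix(stats::rnorm(4 * K), 4, K)
  tok <- afnoseg:::token_sequence(z, c(4L, 1L, 1L))
  p <- withr::with_seed(3, list(ln = afnoseg:::init_layernorm(K),
                                fc1 = afnoseg:::init_linear(K, 2 * K),
                                fc2 = afnoseg:::init_linear(2 * K, K)))
  # zero MLP weights: identity
  p0 <- p
  p0$fc1$W <- p0$fc1$W * 0; p0$fc2$W <- p0$fc2$W * 0
  p0$fc2$b <- p0$fc2$b * 0
  expect_equal(mlp_block(tok, p0)$tokens, z)

  # linear activation + identity affine maps: z + Norm(z)
  pid <- list(ln = afnoseg:::init_layernorm(K),
              fc1 = list(W = diag(K), b = numeric(K)),
              fc2 = list(W = diag(K), b = numeric(K)))
  nz <- afnoseg:::layernorm_fwd(z, pid$ln)$y
  expect_lt(max(abs(mlp_block(tok, pid, activation = "linear")$tokens -
                      (z + nz))), 1e-10)

  # random case vs manual composition
  n <- afnoseg:::layernorm_fwd(z, p$ln)$y
  h <- afnoseg:::linear_fwd(n, p$fc1)$y
  a <- h * stats::pnorm(h)
  o <- afnoseg:::linear_fwd(a, p$fc2)$y
  expect_lt(max(abs(mlp_block(tok, p)$tokens - (z + o))), 1e-10)
})

test_that("patch merging halves the grid and can average neighbourhoods", {
  withr::with_seed(4, {
    x <- array(stats::rnorm(4^3 * 3), c(4, 4, 4, 3))
    p <- afnoseg:::init_merge2(3L, 6L)
    y <- patch_merge(x, p)
    expect_equal(dim(y), c(2L, 2L, 2L, 6L))
    y2 <- patch_merge(y, afnoseg:::init_merge2(6L, 12L))
    expect_equal(dim(y2), c(1L, 1L, 1L, 12L))

    # averaging stencil: the 8*C concatenation is position-fastest with the
    # channel axis last, so channel c occupies rows (c-1)*8 + 1:8
    C <- 3L
    W <- matrix(0, 8 * C, C)
    for (c in seq_len(C)) W[(c - 1) * 8 + 1:8, c] <- 1 / 8
    avg <- patch_merge(x, list(W = W, b = numeric(C)))
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (c in seq_len(C)) {
      blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
               (2 * k - 1):(2 * k), c]
      expect_equal(avg[i, j, k, c], mean(blk), tolerance = 1e-12)
    }
  })
})

test_that("encode follows the halving stage schedule", {
  cfg <- tiny_encoder_config()
  m <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 1)
  v <- random_volume(c(32, 32, 32), seed = 9)
  pyr <- encode(v, cfg, m$params$encoder)
  dims <- lapply(pyr$stages, dim)
  expect_equal(dims[[1]], c(16L, 16L, 16L, 4L))
  expect_equal(dims[[2]], c(8L, 8L, 8L, 6L))
  expect_equal(dims[[3]], c(4L, 4L, 4L, 8L))
  expect_equal(dims[[4]], c(2L, 2L, 2L, 10L))

  # repeated forward passes are bit-identical
  pyr2 <- encode(v, cfg, m$params$encoder)
  expect_identical(pyr$stages, pyr2$stages)

  expect_error(encode(random_volume(c(16, 32, 32), seed = 1), cfg,
                      m$params$encoder), "minimum")
})

test_that("full-width stage schedule matches the documented worked example", {
  cfg <- encoder_config()
  tr <- trace_encoder_shapes(cfg, c(128, 128, 128))
  expect_equal(sapply(tr, function(s) s$channels), c(48L, 96L, 192L, 384L))
  expect_equal(tr[[1]]$grid, c(64L, 64L, 64L))
  expect_equal(tr[[4]]$grid, c(8L, 8L, 8L))
  tr32 <- trace_encoder_shapes(cfg, c(32, 32, 32))
  expect_equal(tr32[[1]]$grid, c(16L, 16L, 16L))
  expect_equal(tr32[[4]]$grid, c(2L, 2L, 2L))
})

test_that("with identity filters and zeroed blocks, encode is embed + merge", {
  cfg <- tiny_encoder_config()
  m <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 5)
  pe <- m$params$encoder
  # zero every block's contribution: identity filters already contribute
  # LN(x); zeroing the norm gains and MLP weights silences both branches
  for (s in 1:4) for (b in seq_along(pe$stages[[s]]$blocks)) {
    bp <- pe$stages[[s]]$blocks[[b]]
    bp$ln1$g <- bp$ln1$g * 0; bp$ln1$b <- bp$ln1$b * 0
    bp$fc2$W <- bp$fc2$W * 0; bp$fc2$b <- bp$fc2$b * 0
    pe$stages[[s]]$blocks[[b]] <- bp
  }
  v <- random_volume(c(32, 32, 32), seed = 6)
  pyr <- encode(v, cfg, pe)

  # oracle: patch embedding followed by the three merges, nothing else
  pp <- partition_patches(v, cfg$patch_size)
  tok <- pp$patches %*% pe$embed$W_proj + pe$embed$E_pos
  x <- array(tok, c(pp$grid, ncol(tok)))
  expect_lt(max(abs(pyr$stages[[1]] - x)), 1e-9)
  for (s in 1:3) {
    x <- patch_merge(x, pe$stages[[s]]$merge)
    expect_lt(max(abs(pyr$stages[[s + 1]] - x)), 1e-9)
  }
})

test_that("constant-resolution encoding keeps one grid and width", {
  cfg <- encoder_config(constant_resolution = TRUE, embed_dim = 8L,
                        num_layers = 4L, const_patch_size = 4L,
                        stage_channels = c(4L, 6L, 8L, 10L))
  m <- init_model(cfg, c(16, 16, 16), 1, 2, seed = 2)
  v <- random_volume(c(16, 16, 16), seed = 3)
  pyr <- encode(v, cfg, m$params$encoder)
  for (s in 1:4) expect_equal(dim(pyr$stages[[s]]), c(4L, 4L, 4L, 8L))
})
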