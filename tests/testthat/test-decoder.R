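# naive "same" 3x3x3 convolution oracle, plain loops over output voxels
naive_conv3 <- function(x, W, b) {
  d <- dim(x)
  Cout <- dim(W)[5]
  y <- array(0, c(d[1:3], Cout))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (oi in -1:1) for (oj in -1:1) for (ok in -1:1) {
        ii <- i + oi; jj <- j + oj; kk <- k + ok
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3]) {
          acc <- acc + sum(x[ii, jj, kk, ] * W[oi + 2, oj + 2, ok + 2, , co])
        }
      }
      y[i, j, k, co] <- acc
    }
  y
}

make_stage_params <- function(Cprev, Cskip, Cout, seed = 1) {
  withr::with_seed(seed, list(
    up = afnoseg:::init_tconv2(Cprev, Cskip),
    conv1 = afnoseg:::init_conv3(2L * Cskip, Cout),
    ln1 = afnoseg:::init_layernorm(Cout),
    conv2 = afnoseg:::init_conv3(Cout, Cout),
    ln2 = afnoseg:::init_layernorm(Cout)))
}

test_that("decode_stage upsamples, fuses the skip, and reports mismatches", {
  withr::with_seed(11, {
    prev <- array(stats::rnorm(2^3 * 6), c(2, 2, 2, 6))
    skip <- array(stats::rnorm(4^3 * 4), c(4, 4, 4, 4))
    p <- make_stage_params(6L, 4L, 5L)
    y <- decode_stage(prev, skip, p)
    expect_equal(dim(y), c(4L, 4L, 4L, 5L))

    bad_skip <- array(0, c(8, 8, 8, 4))
    expect_error(decode_stage(prev, bad_skip, p), "does not match")
  })
})

test_that("identity-configured refinement passes Up(prev) through", {
  withr::with_seed(12, {
    prev <- array(stats::rnorm(2^3 * 3), c(2, 2, 2, 3))
    skip <- array(stats::rnorm(4^3 * 3), c(4, 4, 4, 3))
    p <- make_stage_params(3L, 3L, 6L)
    p$conv1 <- afnoseg:::conv3_identity(6L, 6L)
    p$conv2 <- afnoseg:::conv3_identity(6L, 6L)
    y <- decode_stage(prev, skip, p, use_norm_act = FALSE)
    up <- afnoseg:::tconv2_fwd(prev, p$up)$y
    expect_lt(max(abs(y[, , , 1:3] - up)), 1e-12)
    expect_lt(max(abs(y[, , , 4:6] - skip)), 1e-12)
  })
})

test_that("decode_stage equals the manually composed Up -> concat -> conv", {
  withr::with_seed(13, {
    prev <- array(stats::rnorm(2^3 * 4), c(2, 2, 2, 4))
    skip <- array(stats::rnorm(4^3 * 3), c(4, 4, 4, 3))
    p <- make_stage_params(4L, 3L, 4L)
    y <- decode_stage(prev, skip, p, use_norm_act = FALSE)
    up <- afnoseg:::tconv2_fwd(prev, p$up)$y
    cat_in <- array(0, c(4, 4, 4, 6))
    cat_in[, , , 1:3] <- up
    cat_in[, , , 4:6] <- skip
    oracle <- naive_conv3(naive_conv3(cat_in, p$conv1$W, p$conv1$b),
                          p$conv2$W, p$conv2$b)
    expect_lt(max(abs(y - oracle)), 1e-8)
  })
})

test_that("decode restores the pre-padding shape and emits distributions", {
  cfg <- tiny_encoder_config()
  m <- init_model(cfg, c(32, 32, 32), 1, 3, seed = 4)
  v <- random_volume(c(33, 35, 32), seed = 14)
  pyr <- encode(v, cfg, m$params$encoder)
  res <- decode(pyr, m$params$decoder, 3)
  expect_equal(dim(res$probabilities), c(33L, 35L, 32L, 3L))
  sums <- apply(res$probabilities, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_error(decode(pyr, m$params$decoder, 1), ">= 2")
})

test_that("softmax head produces uniform and shift-invariant distributions", {
  const <- array(2.7, c(3, 3, 3, 4))
  p <- afnoseg:::softmax4(const)
  expect_lt(max(abs(p - 0.25)), 1e-12)

  withr::with_seed(15, {
    lg <- array(stats::rnorm(3^3 * 4), c(3, 3, 3, 4))
    expect_lt(max(abs(afnoseg:::softmax4(lg + 10) - afnoseg:::softmax4(lg))),
              1e-9)
  })
})

test_that("predict_labels takes the argmax with lowest-index tie-break", {
  pr <- array(0, c(1, 1, 2, 2))
  pr[1, 1, 1, ] <- c(0.5, 0.5)
  pr[1, 1, 2, ] <- c(0.2, 0.8)
  lab <- afnoseg:::predict_labels_from_probs(pr)
  expect_equal(as.vector(lab$labels), c(0L, 1L))

  withr::with_seed(16, {
    probs <- array(stats::runif(4^3 * 5), c(4, 4, 4, 5))
    got <- afnoseg:::predict_labels_from_probs(probs)$labels
    oracle <- array(0L, c(4, 4, 4))
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      oracle[i, j, k] <- which.max(probs[i, j, k, ]) - 1L
    }
    expect_identical(got, oracle)
  })
})

test_that("gradient reaches every encoder skip through the decoder", {
  cfg <- tiny_encoder_config()
  m <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 6)
  v <- random_volume(c(32, 32, 32), seed = 17)
  fw <- afnoseg:::model_forward(m, v$data, keep_cache = TRUE)
  withr::with_seed(18, {
    dlog <- array(stats::rnorm(length(fw$logits)), dim(fw$logits))
  })
  db <- afnoseg:::decode_bwd(dlog, fw$dec_cache, m$params$decoder)
  for (s in 1:4) {
    expect_gt(max(abs(db$dskips[[s]])), 0)
  }
})
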