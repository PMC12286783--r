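test_that("the seeded splitter is exact, disjoint and reproducible", {
  items <- as.list(seq_len(30))
  sp <- split_dataset(items, 0.8, seed = 3)
  expect_length(sp$train, 24L)
  expect_length(sp$test, 6L)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), 1:30)
  sp2 <- split_dataset(items, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(items, 0.8, seed = 4)))

  expect_warning(sp1 <- split_dataset(list("a"), 0.8, seed = 1), "empty")
  expect_length(sp1$train, 1L)
  expect_length(sp1$test, 0L)
})

test_that("augmentation is identity at zero magnitude and label-safe", {
  ph <- generate_phantom(sphere_phantom_spec(grid = c(20, 20, 20)), 5)
  zero <- list(rotate_deg = 0, scale_range = c(1, 1), elastic_sigma = 0,
               elastic_alpha = 0)
  out <- augment(ph$volume, ph$labels, zero, seed = 1)
  expect_identical(out$volume$data, ph$volume$data)
  expect_identical(out$labels$labels, ph$labels$labels)

  prm <- list(rotate_deg = 15, scale_range = c(0.9, 1.1),
              elastic_sigma = 4, elastic_alpha = 10)
  a1 <- augment(ph$volume, ph$labels, prm, seed = 7)
  a2 <- augment(ph$volume, ph$labels, prm, seed = 7)
  expect_identical(a1$volume$data, a2$volume$data)
  expect_identical(a1$labels$labels, a2$labels$labels)
  expect_false(identical(a1$labels$labels, ph$labels$labels))
  # nearest-neighbour labels never invent classes
  expect_true(all(unique(as.vector(a1$labels$labels)) %in%
                    unique(as.vector(ph$labels$labels))))
})

test_that("augmentation moves volume and labels together", {
  # paint the volume with the label values themselves; after a joint
  # transform the rounded intensities must still agree with the labels away
  # from interpolation boundaries
  lab <- array(0L, c(20, 20, 20))
  lab[6:14, 6:14, 6:14] <- 1L
  vol <- as_volume(array(as.numeric(lab), c(20, 20, 20, 1)))
  lm <- as_labelmap(lab, num_classes = 2L)
  prm <- list(rotate_deg = 20, scale_range = c(0.95, 1.05),
              elastic_sigma = 3, elastic_alpha = 4)
  a <- augment(vol, lm, prm, seed = 11)
  agree <- as.numeric(dice(a$volume$data[, , , 1] > 0.5,
                           a$labels$labels == 1L))
  expect_gte(agree, 0.97)
})

test_that("the loss obeys its analytic limits and gradient", {
  K <- 3L
  lab <- withr::with_seed(41, array(sample(0:(K - 1), 4^3, TRUE), c(4, 4, 4)))
  gt <- as_labelmap(lab, num_classes = K)

  # saturated perfect prediction
  onehot <- array(0, c(4, 4, 4, K))
  for (c in 0:(K - 1)) onehot[, , , c + 1] <- 20 * (lab == c)
  lo <- seg_loss(onehot, gt)
  expect_lt(lo$loss, 1e-3)

  # uniform logits: CE term is exactly ln K
  lo_u <- seg_loss(array(0, c(4, 4, 4, K)), gt)
  expect_equal(lo_u$ce_term, log(K), tolerance = 1e-12)

  # finite-difference gradient on the 4^3 toy
  withr::with_seed(42, {
    lg <- array(stats::rnorm(4^3 * K), c(4, 4, 4, K))
  })
  lo_r <- seg_loss(lg, gt)
  eps <- 1e-5
  idx <- c(1, 17, 100, 150)
  for (i in idx) {
    lp <- lg; lp[i] <- lp[i] + eps
    lm_ <- lg; lm_[i] <- lm_[i] - eps
    fdv <- (seg_loss(lp, gt)$loss - seg_loss(lm_, gt)$loss) / (2 * eps)
    expect_lt(abs(lo_r$dlogits[i] - fdv) / max(abs(fdv), 1e-8), 1e-4)
  }
})

test_that("early stopping fires after the configured patience", {
  ph <- generate_phantom(sphere_phantom_spec(), 1)
  cfg <- tiny_encoder_config()
  model <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 1)
  # vanishing learning rate: the validation metric cannot improve after
  # the first epoch, so patience 3 must stop the run at epoch 4
  tc <- train_config(learning_rate = 1e-30, max_epochs = 50,
                     early_stop_patience = 3, batch_size = 1,
                     augment = FALSE, seed = 1)
  fit <- train(model, list(ph), tc)
  expect_equal(fit$stop_reason, "early_stop")
  expect_equal(nrow(fit$history), 4L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training is deterministic and decreases the loss", {
  ph <- generate_phantom(sphere_phantom_spec(), 2)
  cfg <- tiny_encoder_config()
  model <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 2)
  tc <- train_config(learning_rate = 5e-3, max_epochs = 3, batch_size = 1,
                     augment = FALSE, early_stop_patience = 100, seed = 3)
  f1 <- train(model, list(ph), tc)
  f2 <- train(model, list(ph), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params$decoder$head$W,
                   f2$model$params$decoder$head$W)
  expect_lt(f1$history$train_loss[3], f1$history$train_loss[1])
  # best-epoch parameters never come from after the best epoch
  expect_lte(f1$best_epoch, nrow(f1$history))
})

test_that("run configs round trip through YAML", {
  p <- file.path(tempdir(), "run.yaml")
  writeLines(c(
    "model:",
    "  stage_channels: [8, 16, 32, 64]",
    "  mixing_mode: afno_3d",
    "  num_classes: 3",
    "  in_channels: 1",
    "  window: [48, 48, 48]",
    "train:",
    "  learning_rate: 0.005",
    "  max_epochs: 12",
    "  batch_size: 1",
    "  augment: false"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$model_config$stage_channels, c(8L, 16L, 32L, 64L))
  expect_equal(cfg$train_config$learning_rate, 5e-3)
  expect_equal(cfg$num_classes, 3L)
  expect_equal(cfg$window, c(48L, 48L, 48L))
})

test_that("checkpoints round trip with a JSON sidecar", {
  cfg <- tiny_encoder_config()
  m <- init_model(cfg, c(32, 32, 32), 1, 2, seed = 9)
  p <- file.path(tempdir(), "m.ckpt")
  save_checkpoint(m, p)
  expect_true(file.exists(paste0(p, ".json")))
  m2 <- load_checkpoint(p)
  expect_identical(m2$params$decoder$head$W, m$params$decoder$head$W)
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$num_classes, 2L)
})
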