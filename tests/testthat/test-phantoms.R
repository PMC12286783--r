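test_that("phantom generation is deterministic in (spec, seed)", {
  spec <- sphere_phantom_spec()
  a <- generate_phantom(spec, 42)
  b <- generate_phantom(spec, 42)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- generate_phantom(spec, 43)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("noise-free, blur-free phantoms hit the intensity table exactly", {
  spec <- sphere_phantom_spec(noise = 0, blur = 0)
  ph <- generate_phantom(spec, 1)
  want <- spec$intensity_table[ph$labels$labels + 1L, 1]
  expect_identical(as.vector(ph$volume$data), as.numeric(want))
})

test_that("ellipsoid voxel count matches a brute-force inside test", {
  grid <- c(24L, 24L, 24L)
  ctr <- c(0.5, 0.45, 0.55)
  rad <- c(0.3, 0.22, 0.26)
  spec <- phantom_spec(grid, 1, 2,
                       list(list(class_id = 1L, shape = "ellipsoid",
                                 center = ctr, radii = rad)),
                       rbind(0, 1))
  ph <- generate_phantom(spec, 0)
  expect_equal(sum(ph$labels$labels == 1L),
               brute_ellipsoid_count(grid, ctr, rad))
})

test_that("an organ that rasterizes to nothing names itself in the error", {
  spec <- phantom_spec(c(16, 16, 16), 1, 3,
                       list(list(class_id = 1L, shape = "ellipsoid",
                                 center = c(0.5, 0.5, 0.5),
                                 radii = c(0.3, 0.3, 0.3)),
                            list(class_id = 2L, shape = "ellipsoid",
                                 center = c(0.5, 0.5, 0.5),
                                 radii = c(0.001, 0.001, 0.001))),
                       rbind(0, 1, 2))
  expect_error(generate_phantom(spec, 0), "organ 2")
})

test_that("nested-lesion phantom has 4 channels and strictly nested classes", {
  ph <- nested_tumor_phantom(c(28, 28, 28), seed = 9)
  expect_equal(dim(ph$volume$data)[4], 4L)
  expect_equal(ph$labels$num_classes, 4L)
  lab <- ph$labels$labels
  expect_true(all(table(factor(lab, levels = 0:3)) > 0))
  # classes are disjoint by construction; the enhancing centre must sit
  # inside the bounding region of the whole lesion
  fg <- which(lab > 0, arr.ind = TRUE)
  c3 <- which(lab == 3L, arr.ind = TRUE)
  for (ax in 1:3) {
    expect_gte(min(c3[, ax]), min(fg[, ax]))
    expect_lte(max(c3[, ax]), max(fg[, ax]))
  }
  # determinism and the minimum-grid guard
  expect_identical(nested_tumor_phantom(c(28, 28, 28), 9)$volume$data,
                   ph$volume$data)
  expect_error(nested_tumor_phantom(c(16, 28, 28), 9), ">= 24")
})

test_that("generate_dataset jitters items apart and reproduces checksums", {
  spec <- sphere_phantom_spec(grid = c(20, 20, 20))
  expect_length(generate_dataset(spec, 0, seed = 1), 0)
  ds <- generate_dataset(spec, 5, seed = 1)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(identical(ds[[i]]$volume$data, ds[[j]]$volume$data))
  }
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(spec, 2, seed = 3, dir = d1)
  generate_dataset(spec, 2, seed = 3, dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("phantoms are separable by a per-voxel nearest-mean classifier", {
  # noise well below a quarter of the inter-class intensity gap
  for (name in c("btcv-like-mini", "msd-like")) {
    spec <- phantom_preset(name)
    ph <- generate_phantom(spec, 7)
    d <- dim(ph$volume$data)
    X <- ph$volume$data
    dim(X) <- c(prod(d[1:3]), d[4])
    means <- spec$intensity_table
    d2 <- sapply(seq_len(nrow(means)), function(k)
      rowSums(sweep(X, 2, means[k, ])^2))
    pred <- max.col(-d2) - 1L
    acc <- mean(pred == as.vector(ph$labels$labels))
    expect_gte(acc, 0.99)
  }
})

test_that("phantom specs round trip through YAML", {
  spec <- phantom_preset("btcv-like")
  p <- file.path(tempdir(), "spec.yaml")
  write_phantom_spec(spec, p)
  spec2 <- read_phantom_spec(p)
  expect_equal(spec2$intensity_table, spec$intensity_table)
  expect_equal(spec2$organs, spec$organs)
  expect_identical(generate_phantom(spec2, 5)$volume$data,
                   generate_phantom(spec, 5)$volume$data)
})
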