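test_that("dice handles the canonical overlap cases", {
  m <- function(v) array(v, c(2, 2, 2))
  a <- m(c(1, 1, 0, 0, 1, 0, 0, 0))
  expect_equal(as.numeric(dice(a, a)), 1.0)
  b <- m(c(0, 0, 1, 1, 0, 0, 1, 0))
  expect_equal(as.numeric(dice(a, b)), 0.0)

  # |T| = 8, |S| = 8, overlap 4 -> 0.5
  T <- array(0, c(4, 4, 4)); S <- T
  T[1:2, 1:2, 1:2] <- 1
  S[1:2, 1:2, 2:3] <- 1
  expect_equal(sum(T), 8); expect_equal(sum(S), 8)
  expect_equal(sum(T & S), 4)
  expect_equal(as.numeric(dice(T, S)), 0.5)

  e <- array(FALSE, c(3, 3, 3))
  both <- dice(e, e)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  one <- array(c(1, rep(0, 26)), c(3, 3, 3))
  expect_equal(as.numeric(dice(e, one)), 0)

  expect_error(dice(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))), "grid")
})

test_that("dice equals the counting-loop oracle on random masks", {
  withr::with_seed(31, {
    for (r in 1:40) {
      T <- array(stats::runif(16^3) < stats::runif(1, 0.05, 0.5), c(16, 16, 16))
      S <- array(stats::runif(16^3) < stats::runif(1, 0.05, 0.5), c(16, 16, 16))
      expect_identical(as.numeric(dice(T, S)), brute_dice(T, S))
      expect_identical(as.numeric(dice(T, S)), as.numeric(dice(S, T)))
    }
  })
})

test_that("dice is monotone in overlap at fixed total mass", {
  # growing the intersection while |T|+|S| stays fixed never lowers Dice
  T <- array(FALSE, c(4, 4, 4)); T[1:2, , ] <- TRUE
  prev <- -1
  for (shift in 3:0) {
    S <- array(FALSE, c(4, 4, 4))
    rows <- (1 + shift):(2 + shift)
    S[rows[rows <= 4], , ] <- TRUE
    if (sum(S) != sum(T)) next
    val <- as.numeric(dice(T, S))
    expect_gte(val, prev)
    prev <- val
  }
})

test_that("surface extraction uses 6-connectivity with border background", {
  mask <- array(FALSE, c(5, 5, 5))
  mask[2:4, 2:4, 2:4] <- TRUE          # 3^3 cube inside a larger grid
  sp <- surface_points(mask)
  expect_equal(nrow(sp$points), 26L)   # all but the centre voxel

  single <- array(FALSE, c(4, 4, 4)); single[2, 3, 4] <- TRUE
  sp1 <- surface_points(single)
  expect_equal(unname(sp1$points[1, ]), c(1, 2, 3))  # 0-based * spacing

  sp2 <- surface_points(single, spacing = c(2, 2, 2))
  expect_equal(unname(sp2$points[1, ]), 2 * c(1, 2, 3))

  empty <- surface_points(array(FALSE, c(3, 3, 3)))
  expect_true(empty$empty)
  expect_equal(nrow(empty$points), 0L)
})

test_that("hd95 matches the brute-force oracle and its special cases", {
  T <- array(FALSE, c(8, 8, 8)); T[2, 2, 2] <- TRUE
  S <- array(FALSE, c(8, 8, 8)); S[5, 6, 2] <- TRUE
  d <- sqrt(3^2 + 4^2)
  expect_equal(as.numeric(hd95(T, S)), d)
  expect_equal(as.numeric(hd95(T, T)), 0)

  withr::with_seed(32, {
    for (r in 1:10) {
      T <- array(stats::runif(10^3) < 0.15, c(10, 10, 10))
      S <- array(stats::runif(10^3) < 0.15, c(10, 10, 10))
      spc <- stats::runif(3, 0.5, 2)
      sT <- surface_points(T, spc)$points
      sS <- surface_points(S, spc)$points
      if (nrow(sT) == 0 || nrow(sS) == 0 || nrow(sT) > 300 ||
          nrow(sS) > 300) next
      expect_lt(abs(as.numeric(hd95(T, S, spc)) - brute_hd(sT, sS, 95)),
                1e-9)
      # percentile 100 recovers the classical maximum Hausdorff distance
      expect_lt(abs(as.numeric(hd95(T, S, spc, percentile = 100)) -
                      brute_hd(sT, sS, 100)), 1e-9)
      # symmetry of the symmetrized definition
      expect_equal(as.numeric(hd95(T, S, spc)), as.numeric(hd95(S, T, spc)))
    }
  })

  und <- hd95(array(FALSE, c(3, 3, 3)), array(c(TRUE, rep(FALSE, 26)),
                                              c(3, 3, 3)))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("evaluate reports per-class metrics with honest flags", {
  lab <- array(0L, c(8, 8, 8))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[6:7, 6:7, 6:7] <- 2L
  gt <- as_labelmap(lab, num_classes = 4L)

  rep0 <- evaluate(gt, gt)
  expect_true(all(rep0$per_class$dice[1:2] == 1))
  expect_true(all(rep0$per_class$hd95_mm[1:2] == 0))
  # class 3 absent from both: flagged dice 1, hd95 undefined + noted
  expect_true(rep0$per_class$dice_both_empty[3])
  expect_true(rep0$per_class$hd95_undefined[3])
  expect_true(any(grepl("class\\(es\\) 3", rep0$notes)))
  expect_equal(rep0$mean_hd95, 0)

  # shifted prediction decomposes into per-class direct calls
  pred_lab <- array(0L, c(8, 8, 8))
  pred_lab[3:5, 2:4, 2:4] <- 1L
  pred_lab[6:7, 6:7, 5:6] <- 2L
  pred <- as_labelmap(pred_lab, num_classes = 4L)
  repc <- evaluate(pred, gt, spacing = c(1, 1, 1))
  for (c in 1:2) {
    expect_equal(repc$per_class$dice[c],
                 as.numeric(dice(gt$labels == c, pred$labels == c)))
    expect_equal(repc$per_class$hd95_mm[c],
                 as.numeric(hd95(gt$labels == c, pred$labels == c,
                                 c(1, 1, 1))))
  }
  expect_equal(repc$mean_dice, mean(repc$per_class$dice))

  p <- file.path(tempdir(), "report.json")
  write_metric_report(repc, p)
  j <- jsonlite::read_json(p)
  expect_equal(length(j$per_class), 3L)
  pcsv <- file.path(tempdir(), "report.csv")
  write_metric_report(repc, pcsv)
  expect_equal(nrow(utils::read.csv(pcsv)), 3L)
})
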