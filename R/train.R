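#' Training configuration
#'
#' Defaults follow the training recipe the architecture is meant to be run
#' with: AdamW with learning rate 1e-4 and weight decay 0.01, an 80/20
#' train/test split, up to 150 epochs with early stopping on validation
#' mean Dice, and random rotation / isotropic scaling / elastic deformation
#' augmentation. The validation set is carved out of the training portion
#' (90/10) so the held-out test partition stays untouched.
#'
#' @param learning_rate AdamW learning rate (> 0).
#' @param weight_decay Decoupled weight decay.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without validation-Dice improvement
#'   before stopping.
#' @param batch_size Gradient-accumulation batch size.
#' @param train_fraction Fraction of the data used for training (0, 1).
#' @param seed Seed governing the split, shuffling and augmentation.
#' @param loss_weights Named vector `c(dice = , ce = )` weighting the
#'   soft-Dice and cross-entropy terms.
#' @param augment Apply data augmentation during training?
#' @param rotate_deg Per-axis rotation range in degrees.
#' @param scale_range Isotropic scale range.
#' @param elastic_sigma Smoothing width of the elastic field, voxels.
#' @param elastic_alpha Elastic displacement magnitude, voxels.
#' @param val_fraction Fraction of the training portion held out for
#'   validation.
#' @return An `afno_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 0.01,
                         max_epochs = 150L, early_stop_patience = 20L,
                         batch_size = 2L, train_fraction = 0.8,
                         seed = 0L, loss_weights = c(dice = 1, ce = 1),
                         augment = TRUE, rotate_deg = 15,
                         scale_range = c(0.9, 1.1), elastic_sigma = 4,
                         elastic_alpha = 10, val_fraction = 0.1) {
  stopifnot(learning_rate > 0, train_fraction > 0, train_fraction < 1)
  structure(
    list(learning_rate = learning_rate, weight_decay = weight_decay,
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size),
         train_fraction = train_fraction, seed = as.integer(seed),
         loss_weights = loss_weights, augment = isTRUE(augment),
         rotate_deg = rotate_deg, scale_range = scale_range,
         elastic_sigma = elastic_sigma, elastic_alpha = elastic_alpha,
         val_fraction = val_fraction),
    class = "afno_train_config"
  )
}

#' Seeded train/test split
#'
#' Shuffles the items under the given seed and takes the first
#' `round(fraction * n)` as training data; the split is disjoint and
#' exhaustive, and identical for identical seeds.
#'
#' @param items A list (or vector) of dataset items.
#' @param fraction Training fraction.
#' @param seed Integer seed.
#' @return List with `train` and `test`.
#' @export
split_dataset <- function(items, fraction = 0.8, seed = 0L) {
  n <- length(items)
  stopifnot(fraction > 0, fraction < 1)
  if (n == 0L) return(list(train = items[0], test = items[0]))
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- round(fraction * n)
  if (n_train == n) {
    warning("test partition is empty (n = ", n, ", fraction = ", fraction, ")")
  }
  if (n_train == 0L) n_train <- 1L
  list(train = items[perm[seq_len(n_train)]],
       test = items[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

# ---- augmentation ------------------------------------------------------------

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

# vectorized trilinear sampling of a rank-3 array at fractional 1-based
# coordinates; points outside the grid sample `fill`
trilinear_sample <- function(a, px, py, pz, fill = 0) {
  d <- dim(a)
  inb <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
  out <- rep(fill, length(px))
  if (!any(inb)) return(out)
  px <- px[inb]; py <- py[inb]; pz <- pz[inb]
  x0 <- pmin(pmax(floor(px), 1), d[1] - 1); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(py), 1), d[2] - 1); y1 <- y0 + 1
  z0 <- pmin(pmax(floor(pz), 1), d[3] - 1); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1L, length(px)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1L, length(py)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1L, length(pz)) }
  wx <- px - x0; wy <- py - y0; wz <- pz - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
    at(x1, y0, z0) * wx * (1 - wy) * (1 - wz) +
    at(x0, y1, z0) * (1 - wx) * wy * (1 - wz) +
    at(x1, y1, z0) * wx * wy * (1 - wz) +
    at(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
    at(x1, y0, z1) * wx * (1 - wy) * wz +
    at(x0, y1, z1) * (1 - wx) * wy * wz +
    at(x1, y1, z1) * wx * wy * wz
  out[inb] <- v
  out
}

nearest_sample <- function(a, px, py, pz, fill = 0L) {
  d <- dim(a)
  i <- round(px); j <- round(py); k <- round(pz)
  inb <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, length(px))
  out[inb] <- a[cbind(i[inb], j[inb], k[inb])]
  out
}

#' Seeded spatial augmentation of a volume/label pair
#'
#' Applies one random rigid-plus-scale transform (per-axis rotation angles
#' drawn uniformly from the rotation range, one isotropic scale factor) and
#' a smooth elastic displacement field, identically to the volume (trilinear
#' interpolation) and its labels (nearest-neighbour, so label values stay a
#' subset of the original class set). All-zero magnitudes return the inputs
#' unchanged. Fully determined by the seed.
#'
#' @param vol An `afno_volume`.
#' @param labels The paired `afno_labelmap`.
#' @param params List with `rotate_deg`, `scale_range`, `elastic_sigma`,
#'   `elastic_alpha` (see [train_config()]).
#' @param seed Integer seed.
#' @return List with transformed `volume` and `labels`.
#' @export
augment <- function(vol, labels, params, seed) {
  stopifnot(inherits(vol, "afno_volume"), inherits(labels, "afno_labelmap"))
  d <- vol_shape(vol)
  if (!identical(as.integer(d), as.integer(dim(labels$labels)))) {
    stop("volume and labels are not aligned")
  }
  rot <- params$rotate_deg %||% 0
  scl <- params$scale_range %||% c(1, 1)
  esig <- params$elastic_sigma %||% 0
  ealp <- params$elastic_alpha %||% 0
  if (rot == 0 && all(scl == 1) && (esig == 0 || ealp == 0)) {
    return(list(volume = vol, labels = labels))
  }
  withr::with_seed(as.integer(seed), {
    ang <- stats::runif(3, -rot, rot)
    s <- stats::runif(1, min(scl), max(scl))
    M <- rotation_matrix(ang) * s
    Minv <- solve(M)
    ctr <- (d + 1) / 2
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    q <- t(Minv %*% t(sweep(as.matrix(g), 2, ctr))) # target -> source offsets
    src <- sweep(q, 2, ctr, `+`)
    if (esig > 0 && ealp > 0) {
      for (ax in 1:3) {
        f <- gaussian_blur3(array(stats::runif(prod(d), -1, 1), d), esig)
        f <- f / max(stats::sd(as.vector(f)), 1e-12) * ealp
        src[, ax] <- src[, ax] + as.vector(f)
      }
    }
    nd <- dim(vol$data)
    out <- vol$data
    for (ch in seq_len(nd[4])) {
      out[, , , ch] <- array(
        trilinear_sample(vol$data[, , , ch], src[, 1], src[, 2], src[, 3]), d)
    }
    lab <- array(as.integer(
      nearest_sample(labels$labels, src[, 1], src[, 2], src[, 3])), d)
    list(volume = as_volume(out, spacing = vol$spacing,
                            origin_note = vol$origin_note),
         labels = as_labelmap(lab, num_classes = labels$num_classes,
                              spacing = labels$spacing))
  })
}

# ---- loss --------------------------------------------------------------------

#' Soft-Dice plus cross-entropy segmentation loss
#'
#' `dice_w * (1 - mean soft-Dice over foreground classes) + ce_w * mean
#' voxel cross-entropy`, computed from logits through a numerically stable
#' log-softmax. Returns the scalar loss, its two components, and the exact
#' gradient with respect to the logits.
#'
#' @param logits `(H, W, D, K)` array of unnormalized class scores.
#' @param gt An `afno_labelmap` on the same spatial grid.
#' @param weights Named vector `c(dice = , ce = )`.
#' @return List with `loss`, `dice_term`, `ce_term`, `dlogits`.
#' @export
seg_loss <- function(logits, gt, weights = c(dice = 1, ce = 1)) {
  stopifnot(inherits(gt, "afno_labelmap"))
  d <- dim(logits)
  if (!identical(as.integer(d[1:3]), as.integer(dim(gt$labels)))) {
    stop("logit grid does not match label grid")
  }
  K <- d[4]
  N <- prod(d[1:3])
  m <- logits; dim(m) <- c(N, K)
  mx <- apply(m, 1, max)
  sh <- m - mx
  lse <- log(rowSums(exp(sh)))
  ls <- sh - lse                       # log-softmax
  p <- exp(ls)
  idx <- as.integer(gt$labels) + 1L
  sel <- cbind(seq_len(N), idx)
  ce <- -mean(ls[sel])
  dce <- p
  dce[sel] <- dce[sel] - 1
  dce <- dce / N
  eps <- 1e-6
  fg <- 2:K
  dp <- matrix(0, N, K)
  dice_vals <- numeric(length(fg))
  for (j in seq_along(fg)) {
    c <- fg[j]
    t <- as.numeric(idx == c)
    pc <- p[, c]
    num <- 2 * sum(pc * t) + eps
    den <- sum(pc) + sum(t) + eps
    dice_vals[j] <- num / den
    # d(1 - mean_j s_j)/dp_c = -(1/|fg|) * (2 t den - num) / den^2
    dp[, c] <- -(2 * t * den - num) / (den^2 * length(fg))
  }
  dice_term <- 1 - mean(dice_vals)
  # softmax jacobian: dlogit = p * (dp - sum_k dp_k p_k)
  ddice <- p * (dp - rowSums(dp * p))
  w_d <- unname(weights["dice"]); w_c <- unname(weights["ce"])
  dlog <- w_d * ddice + w_c * dce
  dim(dlog) <- d
  list(loss = w_d * dice_term + w_c * ce,
       dice_term = dice_term, ce_term = ce, dlogits = dlog)
}

# mean foreground Dice of hard predictions vs ground truth
hard_mean_dice <- function(labels_pred, gt) {
  K <- gt$num_classes
  vals <- vapply(seq_len(K - 1L), function(c)
    as.numeric(dice(gt$labels == c, labels_pred == c)), numeric(1))
  mean(vals)
}

# ---- training loop -----------------------------------------------------------

#' Train a segmentation model
#'
#' AdamW optimization of the soft-Dice + cross-entropy loss with gradient
#' accumulation over `batch_size` items, optional augmentation, per-epoch
#' validation, and early stopping on validation mean Dice. The parameters
#' returned are those of the best validation epoch, never a later one. Two
#' runs with identical inputs and configuration produce identical histories
#' and parameters.
#'
#' @param model An [init_model()] object.
#' @param dataset List of items, each a list with `volume` (`afno_volume`)
#'   and `labels` (`afno_labelmap`) — e.g. phantoms from
#'   [generate_dataset()].
#' @param config An [train_config()].
#' @param val_set Optional explicit validation list; by default
#'   `val_fraction` of `dataset` is held out (with a single item, the item
#'   validates itself).
#' @param normalize Apply [normalize_zscore()] to each volume once up front?
#' @param verbose Print one line per epoch?
#' @return List with `model` (best parameters), `history` (one row per
#'   epoch: `train_loss`, `val_loss`, `val_mean_dice`), `best_epoch`,
#'   `stop_reason` (`"early_stop"` or `"max_epochs"`).
#' @export
train <- function(model, dataset, config = train_config(), val_set = NULL,
                  normalize = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "afno_model"))
  if (length(dataset) < 1L) stop("dataset is empty")
  prep <- function(item) {
    v <- if (normalize) normalize_zscore(item$volume) else item$volume
    list(x = v$data, gt = item$labels)
  }
  items <- lapply(dataset, prep)
  if (is.null(val_set)) {
    if (length(items) == 1L) {
      tr <- items; va <- items
    } else {
      n_val <- max(1L, round(config$val_fraction * length(items)))
      perm <- withr::with_seed(config$seed + 7L, sample.int(length(items)))
      va <- items[perm[seq_len(n_val)]]
      tr <- items[perm[-seq_len(n_val)]]
    }
  } else {
    tr <- items
    va <- lapply(val_set, prep)
  }
  params <- model$params
  state <- adamw_init(params)
  best <- list(dice = -Inf, epoch = 0L, params = params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_mean_dice = numeric(0))
  stop_reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    ord <- withr::with_seed(config$seed + epoch, sample.int(length(tr)))
    acc <- NULL
    n_acc <- 0L
    ep_loss <- 0
    model$params <- params
    for (ii in seq_along(ord)) {
      it <- tr[[ord[ii]]]
      x <- it$x; gt <- it$gt
      if (config$augment) {
        aug_seed <- as.integer(((config$seed %% 19997) * 1000 +
                                  epoch * 100 + ii) %% 2147483647)
        aug <- augment(as_volume(x, spacing = gt$spacing), gt,
                       config, seed = aug_seed)
        x <- aug$volume$data; gt <- aug$labels
      }
      fw <- model_forward(model, x, keep_cache = TRUE)
      lo <- seg_loss(fw$logits, gt, config$loss_weights)
      ep_loss <- ep_loss + lo$loss
      g <- model_backward(model, lo$dlogits, fw)
      acc <- tree_add(acc, g)
      n_acc <- n_acc + 1L
      if (n_acc == config$batch_size || ii == length(ord)) {
        acc <- tree_map(function(x) x / n_acc, acc)
        st <- adamw_step(params, acc, state, lr = config$learning_rate,
                         weight_decay = config$weight_decay)
        params <- st$params
        state <- st$state
        model$params <- params
        acc <- NULL
        n_acc <- 0L
      }
    }
    model$params <- params
    val_loss <- 0
    val_dice <- 0
    for (it in va) {
      fw <- model_forward(model, it$x, keep_cache = FALSE)
      lo <- seg_loss(fw$logits, it$gt, config$loss_weights)
      val_loss <- val_loss + lo$loss
      pr <- predict_labels_from_probs(softmax4(fw$logits), it$gt$spacing)
      val_dice <- val_dice + hard_mean_dice(pr$labels, it$gt)
    }
    val_loss <- val_loss / length(va)
    val_dice <- val_dice / length(va)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(tr),
                                   val_loss = val_loss,
                                   val_mean_dice = val_dice))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val dice %.4f",
                      epoch, ep_loss / length(tr), val_loss, val_dice))
    }
    if (val_dice > best$dice + 1e-12) {
      best <- list(dice = val_dice, epoch = epoch, params = params)
    } else if (epoch - best$epoch >= config$early_stop_patience) {
      stop_reason <- "early_stop"
      break
    }
  }
  model$params <- best$params
  list(model = model,
       history = structure(hist, class = c("afno_train_history",
                                           "data.frame")),
       best_epoch = best$epoch, stop_reason = stop_reason)
}
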