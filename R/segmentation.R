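#' Segmentation configuration
#'
#' Hyperparameters for the encoder-decoder vessel segmenter.  The
#' architecture is a compact U-net style network: `depth` resolution
#' levels with one 3x3 convolution + ReLU per level, 2x2 max pooling,
#' nearest-neighbour upsampling with skip-connection concatenation, and a
#' 1x1 sigmoid output head; channel width starts at `base_channels` and
#' doubles per level.  Kept deliberately small so that CPU training on
#' synthetic tiles finishes in minutes.
#'
#' @param threshold score threshold for [binarize()]; vessel iff
#'   score >= threshold (inclusive).  Must be in (0, 1).
#' @param depth number of encoder levels (including the bottleneck).
#' @param base_channels channels at the finest level.
#' @param tile_size,tile_overlap tiling for inference on large images
#'   (px); overlapping tiles are blended with linear feathering.
#' @param lr Adam learning rate.
#' @param batch_size images per gradient step (stochastic steps iterate
#'   single tiles).
#' @param max_epochs maximum training epochs.
#' @param patience early stopping: stop after this many epochs without
#'   improvement of the validation Dice score.
#' @param flip_prob probability of a horizontal and (independently) a
#'   vertical flip during augmentation.
#' @param rotations set of rotation angles (degrees, multiples of 90)
#'   sampled during augmentation.
#' @param color_shift amplitude of the additive per-channel color shift
#'   (image only) on the `[0, 1]` intensity scale.
#' @param spatial_shift maximum augmentation translation in px.
#' @param seed seed from which all training randomness (weight
#'   initialisation, augmentation, batch order) flows.
#' @return a `vascam_seg_config` list.
#' @export
seg_config <- function(threshold = 0.5, depth = 4, base_channels = 16,
                       tile_size = 256, tile_overlap = 32,
                       lr = 1e-3, batch_size = 1,
                       max_epochs = 10, patience = 4,
                       flip_prob = 0.5, rotations = c(0, 90, 180, 270),
                       color_shift = 0.05, spatial_shift = 16,
                       seed = 42L) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (tile_overlap >= tile_size) stopf("tile_overlap must be < tile_size")
  structure(list(threshold = threshold, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 tile_size = as.integer(tile_size),
                 tile_overlap = as.integer(tile_overlap),
                 lr = lr, batch_size = batch_size,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 flip_prob = flip_prob, rotations = rotations,
                 color_shift = color_shift,
                 spatial_shift = as.integer(spatial_shift),
                 seed = as.integer(seed)),
            class = "vascam_seg_config")
}

# He-normal initialisation of all weights; uses the current RNG stream.
init_params <- function(depth, base) {
  ch <- base * 2^(seq_len(depth) - 1)
  p <- list()
  cin <- 3L
  for (l in seq_len(depth)) {
    p[[paste0("eW", l)]] <- matrix(
      stats::rnorm(9 * cin * ch[l], 0, sqrt(2 / (9 * cin))), 9 * cin, ch[l])
    p[[paste0("eb", l)]] <- rep(0, ch[l])
    cin <- ch[l]
  }
  for (l in seq_len(depth - 1)) {
    cin_d <- ch[l + 1] + ch[l]
    p[[paste0("dW", l)]] <- matrix(
      stats::rnorm(9 * cin_d * ch[l], 0, sqrt(2 / (9 * cin_d))),
      9 * cin_d, ch[l])
    p[[paste0("db", l)]] <- rep(0, ch[l])
  }
  p[["oW"]] <- matrix(stats::rnorm(ch[1], 0, sqrt(1 / ch[1])), ch[1], 1)
  p[["ob"]] <- 0
  p
}

# reflect-pad an H x W (xC) array so both dims are multiples of `mult`
pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  H2 <- as.integer(ceiling(H / mult) * mult)
  W2 <- as.integer(ceiling(W / mult) * mult)
  if (H2 == H && W2 == W) return(list(x = x, H = H, W = W))
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(H2 - H)])
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(W2 - W)])
  out <- if (length(d) == 3) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
  list(x = out, H = H, W = W)
}

# raw forward pass on one image array (values on [0,1]); returns H x W scores
forward_scores <- function(params, image, depth, base) {
  stopifnot(length(dim(image)) == 3)
  pad <- pad_to_multiple(image, 2^(depth - 1))
  d <- dim(pad$x)
  inp <- matrix(as.numeric(pad$x) - 0.5, d[1] * d[2], d[3])
  res <- nn_run_cpp(params, inp, d[1], d[2], numeric(0), FALSE, depth, base)
  sc <- matrix(res$scores, d[1], d[2])
  sc[seq_len(pad$H), seq_len(pad$W), drop = FALSE]
}

# one gradient step; returns list(params, adam, loss)
train_step <- function(params, adam, image, mask, config, t) {
  depth <- config$depth; base <- config$base_channels
  pad_i <- pad_to_multiple(image, 2^(depth - 1))
  pad_m <- pad_to_multiple(mask, 2^(depth - 1))
  d <- dim(pad_i$x)
  inp <- matrix(as.numeric(pad_i$x) - 0.5, d[1] * d[2], d[3])
  res <- nn_run_cpp(params, inp, d[1], d[2], as.numeric(pad_m$x),
                    TRUE, depth, base)
  if (!is.finite(res$loss))
    stopf("non-finite training loss at step %d; aborting", t)
  g <- res$grads
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- config$lr * sqrt(1 - b2^t) / (1 - b1^t)
  for (nm in names(params)) {
    gi <- g[[nm]]
    adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * gi
    adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * gi^2
    params[[nm]] <- params[[nm]] -
      lr_t * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + eps)
  }
  list(params = params, adam = adam, loss = res$loss)
}

as_seg_sample <- function(s) {
  if (inherits(s, "vascam_sample"))
    return(list(image = s$image, mask = s$truth_mask, seed = s$seed))
  if (is.list(s) && !is.null(s$image) && !is.null(s$mask))
    return(list(image = s$image, mask = s$mask, seed = s$seed))
  stopf("samples must be vascam_sample objects or list(image, mask)")
}

#' Apply training-time augmentation to an image/mask pair
#'
#' Geometric transforms (flips, rotations by multiples of 90 degrees,
#' integer translations) are applied identically to image and mask; the
#' additive color shift is applied to the image only.  The mask stays
#' binary.  Randomness comes from the current RNG stream.
#'
#' @param image rows x cols x 3 array on `[0, 1]`.
#' @param mask matching 0/1 matrix.
#' @param config a `vascam_seg_config` providing the augmentation ranges.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, config = seg_config()) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  apply_geom <- function(f, img, msk) {
    img <- simplify2array(lapply(seq_len(dim(img)[3]),
                                 function(ch) f(img[, , ch])))
    list(img = img, msk = f(msk))
  }
  if (stats::runif(1) < config$flip_prob) {
    r <- apply_geom(function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
                    image, mask)
    image <- r$img; mask <- r$msk
  }
  if (stats::runif(1) < config$flip_prob) {
    r <- apply_geom(function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
                    image, mask)
    image <- r$img; mask <- r$msk
  }
  rot <- config$rotations[sample.int(length(config$rotations), 1)]
  if (rot %% 360 != 0) {
    k <- (rot %/% 90) %% 4
    r <- apply_geom(function(m) rot90_k(m, k), image, mask)
    image <- r$img; mask <- r$msk
  }
  if (config$spatial_shift > 0) {
    dxy <- sample(seq(-config$spatial_shift, config$spatial_shift), 2,
                  replace = TRUE)
    shift_one <- function(m, fill_edge) {
      H <- nrow(m); W <- ncol(m)
      ri <- seq_len(H) - dxy[2]; ci <- seq_len(W) - dxy[1]
      if (fill_edge) {
        ri <- pmin(pmax(ri, 1), H); ci <- pmin(pmax(ci, 1), W)
        m[ri, ci, drop = FALSE]
      } else {
        out <- matrix(0L, H, W)
        rok <- ri >= 1 & ri <= H; cok <- ci >= 1 & ci <= W
        out[which(rok), which(cok)] <- m[ri[rok], ci[cok], drop = FALSE]
        out
      }
    }
    image <- simplify2array(lapply(seq_len(dim(image)[3]),
                                   function(ch) shift_one(image[, , ch], TRUE)))
    mask <- shift_one(mask, FALSE)
  }
  if (config$color_shift > 0) {
    shift <- stats::runif(3, -config$color_shift, config$color_shift)
    for (ch in 1:3) image[, , ch] <- clamp01(image[, , ch] + shift[ch])
  }
  list(image = image, mask = mask)
}

pooled_val_metrics <- function(params, val, config) {
  tp <- fp <- fn <- 0
  for (s in val) {
    sc <- forward_scores(params, s$image, config$depth, config$base_channels)
    pred <- sc >= config$threshold
    truth <- s$mask == 1
    tp <- tp + sum(pred & truth)
    fp <- fp + sum(pred & !truth)
    fn <- fn + sum(!pred & truth)
  }
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  precision <- if (tp + fp == 0) (if (fn == 0) 1 else 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) (if (fp == 0) 1 else 0) else tp / (tp + fn)
  list(dice = dice, precision = precision, recall = recall)
}

#' Train the encoder-decoder vessel segmenter
#'
#' Minimises the per-pixel binary cross-entropy with Adam over augmented
#' training samples, monitors the pooled validation Dice score after every
#' epoch, and returns the checkpoint with the best validation Dice.
#' Training stops early after `config$patience` epochs without
#' improvement.  Fully reproducible given `config$seed`.  When `init` is a
#' previously trained model, its weights are fine-tuned with the learning
#' rate reduced tenfold.
#'
#' @param train_samples,val_samples lists of `vascam_sample` objects or
#'   `list(image, mask)` pairs; the validation set must be disjoint from
#'   the training set.
#' @param config a `vascam_seg_config`.
#' @param init optional `vascam_model` to fine-tune from.
#' @return list with `model` (class `vascam_model`) and `log` (data frame
#'   of per-epoch training loss and validation Dice).
#' @export
train_segmenter <- function(train_samples, val_samples,
                            config = seg_config(), init = NULL) {
  if (length(train_samples) < 1) stopf("empty training dataset")
  if (length(val_samples) < 1) stopf("empty validation dataset")
  train <- lapply(train_samples, as_seg_sample)
  val <- lapply(val_samples, as_seg_sample)
  tseeds <- unlist(lapply(train, `[[`, "seed"))
  vseeds <- unlist(lapply(val, `[[`, "seed"))
  if (length(tseeds) && length(vseeds) &&
      length(intersect(tseeds, vseeds)) > 0)
    warning("validation set shares sample seeds with the training set; ",
            "validation metrics will be optimistic", call. = FALSE)

  cfg_hash <- hash_obj(unclass(config))
  withr::with_seed(config$seed, {
    if (!is.null(init)) {
      params <- init$params
      config$lr <- config$lr * 0.1  # fine-tuning mode
    } else {
      params <- init_params(config$depth, config$base_channels)
    }
    adam <- list(m = lapply(params, function(p) p * 0),
                 v = lapply(params, function(p) p * 0))
    best <- list(dice = -Inf, params = params, epoch = 0L)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_dice = numeric(0))
    t <- 0L
    wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(train))
      losses <- numeric(length(ord))
      for (i in seq_along(ord)) {
        s <- train[[ord[i]]]
        aug <- augment_pair(s$image, s$mask, config)
        t <- t + 1L
        st <- train_step(params, adam, aug$image, aug$mask, config, t)
        params <- st$params; adam <- st$adam; losses[i] <- st$loss
      }
      vm <- pooled_val_metrics(params, val, config)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_dice = vm$dice))
      if (vm$dice > best$dice + 1e-6) {
        best <- list(dice = vm$dice, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    model <- structure(list(params = best$params, config = config,
                            config_hash = cfg_hash,
                            epochs_run = nrow(log),
                            best_epoch = best$epoch,
                            best_val_dice = best$dice),
                       class = "vascam_model")
    list(model = model, log = log)
  })
}

#' @export
print.vascam_model <- function(x, ...) {
  cat(sprintf(
    "<vascam_model> depth %d, base %d | best val Dice %.4f (epoch %d/%d)\n",
    x$config$depth, x$config$base_channels, x$best_val_dice,
    x$best_epoch, x$epochs_run))
  invisible(x)
}

#' Save / load a trained segmentation model
#'
#' The checkpoint embeds the full configuration and its hash; a loaded
#' model is bit-identical to the saved one.
#'
#' @param model a `vascam_model`.
#' @param path file path for the checkpoint.
#' @return `read_model` returns the `vascam_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "vascam_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "vascam_model")) stopf("'%s' is not a model checkpoint", path)
  m
}

#' Predict a per-pixel vessel score map
#'
#' Runs the network over the image and returns one score in `[0, 1]` per
#' pixel.  Images larger than the configured tile size are processed in
#' overlapping tiles blended with linear feathering; smaller images are
#' padded reflectively and cropped back.
#'
#' @param model a trained `vascam_model`.
#' @param image rows x cols x 3 array on `[0, 1]`, or a `vascam_sample`.
#' @param config optional `vascam_seg_config` override (defaults to the
#'   model's training config).
#' @return numeric matrix of scores with the input's spatial shape.
#' @export
predict_scoremap <- function(model, image, config = model$config) {
  if (inherits(image, "vascam_sample")) image <- image$image
  stopifnot(length(dim(image)) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  ts <- config$tile_size; ov <- config$tile_overlap
  depth <- model$config$depth; base <- model$config$base_channels
  if (H <= ts && W <= ts)
    return(forward_scores(model$params, image, depth, base))

  starts <- function(n) {
    if (n <= ts) return(1L)
    s <- seq(1L, n - ts + 1L, by = ts - ov)
    if (s[length(s)] != n - ts + 1L) s <- c(s, n - ts + 1L)
    s
  }
  ramp <- pmin(pmin(seq_len(ts), rev(seq_len(ts))), ov + 1L)
  wt <- outer(ramp, ramp, pmin)
  acc <- matrix(0, H, W)
  den <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rr <- r0:min(H, r0 + ts - 1L)
      cc <- c0:min(W, c0 + ts - 1L)
      sc <- forward_scores(model$params,
                           image[rr, cc, , drop = FALSE], depth, base)
      w <- wt[seq_along(rr), seq_along(cc), drop = FALSE]
      acc[rr, cc] <- acc[rr, cc] + sc * w
      den[rr, cc] <- den[rr, cc] + w
    }
  }
  acc / den
}

#' Binarize a score map
#'
#' A pixel is vessel iff its score is greater than or equal to the
#' threshold (inclusive).
#'
#' @param score_map numeric matrix of scores in `[0, 1]`.
#' @param threshold threshold in (0, 1); default 0.5.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(score_map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must be inside (0, 1)")
  if (any(score_map < 0 | score_map > 1))
    stopf("score map values must lie in [0, 1]")
  out <- matrix(0L, nrow(score_map), ncol(score_map))
  out[score_map >= threshold] <- 1L
  out
}

#' Pixel-wise segmentation metrics
#'
#' Dice = 2TP/(2TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN).
#' If both masks are empty all three metrics are 1; if exactly one is
#' empty they are 0.
#'
#' @param pred_mask,truth_mask binary matrices of equal shape.
#' @return list with `dice`, `precision`, `recall` and the raw `tp`,
#'   `fp`, `fn` counts.
#' @export
evaluate_segmentation <- function(pred_mask, truth_mask) {
  pred_mask <- assert_binary_mask(pred_mask, "pred_mask")
  truth_mask <- assert_binary_mask(truth_mask, "truth_mask")
  if (!all(dim(pred_mask) == dim(truth_mask)))
    stopf("pred and truth masks must have the same shape")
  p <- pred_mask == 1; t <- truth_mask == 1
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0)
    return(list(dice = 1, precision = 1, recall = 1, tp = tp, fp = fp, fn = fn))
  list(
    dice = 2 * tp / (2 * tp + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn
  )
}

#' Per-vessel detection against a ground-truth tree
#'
#' A superficial tree segment counts as detected when at least 50% of its
#' rasterized pixels are predicted vessel pixels.  Reports per-segment
#' flags and the diameter range covered by the detected segments.
#'
#' @param pred_mask binary predicted mask on the tree's canvas.
#' @param tree a `vascam_tree`.
#' @return list with `segments` (data frame: id, diameter_px, n_pixels,
#'   coverage, detected) and `diameter_range` (min/max diameter among
#'   detected segments; `NA` if none).
#' @export
per_vessel_detection <- function(pred_mask, tree) {
  pred_mask <- assert_binary_mask(pred_mask, "pred_mask")
  H <- nrow(pred_mask); W <- ncol(pred_mask)
  sup <- Filter(function(s) !s$deep, tree$segments)
  rows <- lapply(sup, function(s) {
    m <- raster_capsules_cpp(tree_pieces(list(s)), H, W)
    npx <- sum(m)
    cov <- if (npx == 0) 0 else sum(pred_mask[m == 1]) / npx
    data.frame(id = s$id, diameter_px = 2 * s$radius, n_pixels = npx,
               coverage = cov, detected = npx > 0 && cov >= 0.5)
  })
  segments <- do.call(rbind, rows)
  det <- segments$diameter_px[segments$detected]
  list(segments = segments,
       diameter_range = if (length(det)) range(det) else c(NA_real_, NA_real_))
}
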