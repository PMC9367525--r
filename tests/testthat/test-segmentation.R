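test_that("augmentation with zero amplitudes is the identity", {
  smp <- simulate_cam_sample(c(64, 64), seed = 1)
  cfg <- seg_config(flip_prob = 0, rotations = 0, color_shift = 0,
                    spatial_shift = 0)
  out <- augment_pair(smp$image, smp$truth_mask, cfg)
  expect_identical(out$image, smp$image)
  expect_identical(out$mask, smp$truth_mask)
})

test_that("a forced horizontal flip is an involution", {
  smp <- simulate_cam_sample(c(64, 64), seed = 2)
  cfg <- seg_config(flip_prob = 1, rotations = 0, color_shift = 0,
                    spatial_shift = 0)
  once <- augment_pair(smp$image, smp$truth_mask, cfg)
  twice <- augment_pair(once$image, once$mask, cfg)
  expect_identical(twice$image, smp$image)
  expect_identical(twice$mask, smp$truth_mask)
})

test_that("geometric transforms stay aligned and masks stay binary", {
  smp <- simulate_cam_sample(c(64, 64), seed = 3)
  cfg <- seg_config()
  set.seed(1)
  for (i in 1:10) {
    out <- augment_pair(smp$image, smp$truth_mask, cfg)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_equal(dim(out$image)[1:2], dim(out$mask))
    # vessels remain darker than background after any transform
    g <- out$image[, , 2]
    if (sum(out$mask) > 50)
      expect_lt(mean(g[out$mask == 1]), mean(g[out$mask == 0]))
  }
})

test_that("flip frequency matches the configured probability", {
  set.seed(98)
  img <- array(runif(4 * 4 * 3, 0.1, 1), c(4, 4, 3))
  img[1, 1, 1] <- 0  # unique marker; tracks the corner through flips
  msk <- matrix(0L, 4, 4)
  cfg <- seg_config(flip_prob = 0.5, rotations = 0, color_shift = 0,
                    spatial_shift = 0)
  set.seed(99)
  hflips <- vapply(1:1000, function(i) {
    out <- augment_pair(img, msk, cfg)
    pos <- which(out$image[, , 1] == 0, arr.ind = TRUE)
    pos[1, 2] == 4L  # marker in the last column iff horizontally flipped
  }, logical(1))
  expect_gte(mean(hflips), 0.45)
  expect_lte(mean(hflips), 0.55)
})

test_that("network gradients match finite differences", {
  set.seed(4)
  depth <- 2L; base <- 2L
  p <- vascam:::init_params(depth, base)
  H <- 8L; W <- 8L
  img <- array(runif(H * W * 3), c(H, W, 3))
  msk <- matrix(rbinom(H * W, 1, 0.3), H, W)
  inp <- matrix(as.numeric(img) - 0.5, H * W, 3)
  res <- vascam:::nn_run_cpp(p, inp, H, W, as.numeric(msk), TRUE,
                             depth, base)
  eps <- 1e-3
  for (nm in names(p)) {
    idx <- 1L
    p2 <- p
    p2[[nm]][idx] <- p2[[nm]][idx] + eps
    l1 <- vascam:::nn_run_cpp(p2, inp, H, W, as.numeric(msk), TRUE,
                              depth, base)$loss
    p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
    l2 <- vascam:::nn_run_cpp(p2, inp, H, W, as.numeric(msk), TRUE,
                              depth, base)$loss
    fd <- (l1 - l2) / (2 * eps)
    an <- res$grads[[nm]][idx]
    expect_lt(abs(fd - an), max(0.06 * abs(fd), 2e-4))
  }
})

test_that("training is deterministic and returns the best checkpoint", {
  train <- lapply(1:2, function(sd) simulate_cam_sample(c(64, 64), seed = sd))
  val <- lapply(11:12, function(sd) simulate_cam_sample(c(64, 64), seed = sd))
  cfg <- seg_config(max_epochs = 2, patience = 2, seed = 5)
  f1 <- train_segmenter(train, val, cfg)
  f2 <- train_segmenter(train, val, cfg)
  expect_identical(f1$model$best_val_dice, f2$model$best_val_dice)
  expect_identical(f1$model$params, f2$model$params)
  expect_gte(f1$model$best_val_dice, f1$log$val_dice[1])
})

test_that("training rejects empty datasets", {
  val <- list(simulate_cam_sample(c(64, 64), seed = 1))
  expect_error(train_segmenter(list(), val), "empty training")
  expect_error(train_segmenter(val, list()), "empty validation")
})

test_that("the segmenter overfits a single easy image", {
  smp <- simulate_cam_sample(c(96, 96), seed = 31)
  cfg <- seg_config(max_epochs = 8, patience = 8, seed = 1,
                    spatial_shift = 4, color_shift = 0.02)
  fit <- suppressWarnings(train_segmenter(list(smp), list(smp), cfg))
  sc <- predict_scoremap(fit$model, smp$image)
  m <- evaluate_segmentation(binarize(sc, 0.5), smp$truth_mask)
  expect_gte(m$dice, 0.95)
})

test_that("score maps respect shape and range and are deterministic", {
  model <- tiny_model()
  smp <- simulate_cam_sample(c(96, 96), seed = 77)
  s1 <- predict_scoremap(model, smp$image)
  s2 <- predict_scoremap(model, smp$image)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(96, 96))
  expect_gte(min(s1), 0)
  expect_lte(max(s1), 1)
  # non-tile-aligned size goes through reflective padding
  odd <- simulate_cam_sample(c(70, 85), seed = 78)
  so <- predict_scoremap(model, odd$image)
  expect_equal(dim(so), c(70, 85))
})

test_that("tiled inference agrees with single-pass inference", {
  model <- tiny_model()
  smp <- simulate_cam_sample(c(320, 320), seed = 79)
  cfg_single <- model$config
  cfg_single$tile_size <- 320L
  single <- predict_scoremap(model, smp$image, cfg_single)
  cfg_tiled <- model$config
  cfg_tiled$tile_size <- 96L
  cfg_tiled$tile_overlap <- 16L
  tiled <- predict_scoremap(model, smp$image, cfg_tiled)
  expect_lte(mean(abs(single - tiled)), 0.02)
})

test_that("binarize applies an inclusive threshold", {
  expect_equal(sum(binarize(matrix(0, 5, 5))), 0)
  sc <- matrix(c(0.49, 0.50, 0.51), 1, 3)
  expect_identical(as.vector(binarize(sc, 0.5)), c(0L, 1L, 1L))
  expect_error(binarize(sc, 0), "threshold")
  expect_error(binarize(sc, 1), "threshold")
  expect_error(binarize(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("raising the threshold never adds vessel pixels", {
  set.seed(6)
  for (i in 1:10) {
    sc <- matrix(runif(400), 20, 20)
    m1 <- binarize(sc, 0.3)
    m2 <- binarize(sc, 0.5)
    m3 <- binarize(sc, 0.8)
    expect_true(all(m2 <= m1))
    expect_true(all(m3 <= m2))
  }
})

test_that("segmentation metrics follow their definitions", {
  a <- matrix(0L, 10, 30); a[3:5, 3:12] <- 1L
  same <- evaluate_segmentation(a, a)
  expect_equal(c(same$dice, same$precision, same$recall), c(1, 1, 1))

  b <- matrix(0L, 10, 30); b[8:9, 20:29] <- 1L
  disj <- evaluate_segmentation(a, b)
  expect_equal(c(disj$dice, disj$precision, disj$recall), c(0, 0, 0))

  # truth 100 px, pred = truth plus 100 disjoint px
  truth <- matrix(0L, 20, 30); truth[2:11, 2:11] <- 1L
  truth[1:10, 1:10] <- 0L; truth <- matrix(0L, 20, 30)
  truth[1:10, 1:10] <- 1L
  pred <- truth
  pred[11:20, 20:29] <- 1L
  m <- evaluate_segmentation(pred, truth)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$dice, 2 / 3, tolerance = 1e-12)

  both_empty <- evaluate_segmentation(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(c(both_empty$dice, both_empty$precision, both_empty$recall),
               c(1, 1, 1))
  one_empty <- evaluate_segmentation(matrix(0L, 4, 4), a[1:4, 1:4])
  expect_equal(one_empty$recall, 0)
  expect_error(evaluate_segmentation(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               "shape")
})

test_that("swapping pred and truth swaps precision and recall", {
  set.seed(7)
  for (i in 1:10) {
    p <- matrix(rbinom(100, 1, 0.3), 10, 10)
    t <- matrix(rbinom(100, 1, 0.3), 10, 10)
    m1 <- evaluate_segmentation(p, t)
    m2 <- evaluate_segmentation(t, p)
    expect_equal(m1$precision, m2$recall)
    expect_equal(m1$recall, m2$precision)
    expect_equal(m1$dice, m2$dice)
  }
})

test_that("per-vessel detection flags segments by pixel coverage", {
  tr <- two_segment_tree()
  truth <- rasterize_tree(tr)$mask
  all_det <- per_vessel_detection(truth, tr)
  expect_true(all(all_det$segments$detected))
  expect_equal(all_det$diameter_range, c(8, 8))

  none <- per_vessel_detection(matrix(0L, 200, 200), tr)
  expect_false(any(none$segments$detected))
  expect_true(all(is.na(none$diameter_range)))

  # cover exactly the first segment
  only1 <- vascam:::raster_capsules_cpp(
    vascam:::tree_pieces(tr$segments[1]), 200L, 200L)
  part <- per_vessel_detection(only1, tr)
  expect_identical(part$segments$detected, c(TRUE, FALSE))
})

test_that("model checkpoints round-trip bit-exactly", {
  model <- tiny_model()
  tf <- tempfile(fileext = ".rds")
  write_model(model, tf)
  back <- read_model(tf)
  expect_identical(back, model)
  unlink(tf)
})
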