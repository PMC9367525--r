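test_that("vessel_area counts pixels after component filtering", {
  expect_equal(vessel_area(matrix(0L, 10, 10)), 0)
  m <- matrix(0L, 30, 40)
  m[3:7, 11:30] <- 1L
  expect_equal(vessel_area(m), 100)
  # a 3 px speckle below the minimum component size is suppressed
  m[20, 35:37] <- 1L
  expect_equal(vessel_area(m, min_component = 10), 100)
  expect_equal(vessel_area(m, min_component = 1), 103)
  expect_error(vessel_area(matrix(2L, 3, 3)), "binary")
})

test_that("skeletonization gives a thin centerline inside the mask", {
  expect_equal(sum(skeletonize_mask(matrix(0L, 10, 10))), 0)
  m <- matrix(0L, 20, 60)
  m[8:12, 6:55] <- 1L
  sk <- skeletonize_mask(m)
  expect_true(all(m[sk == 1] == 1))               # subset of the mask
  expect_equal(branch_points(sk), 0L, ignore_attr = TRUE)
  idx <- which(sk == 1, arr.ind = TRUE)
  expect_true(all(idx[, 1] == 10))                 # single centre row
  expect_lte(min(idx[, 2]) - 6, 3)                 # endpoints near bar ends
  expect_gte(max(idx[, 2]) - 55, -3)
  # idempotence
  expect_identical(skeletonize_mask(sk), sk)
})

test_that("skeletonization preserves component count", {
  set.seed(1)
  tr <- generate_vessel_tree(c(256, 256), n_roots = 2, deep_fraction = 0,
                             seed = 12)
  m <- rasterize_tree(tr)$mask
  sk <- skeletonize_mask(m)
  n_mask <- max(vascam:::cc_label_cpp(m))
  n_skel <- max(vascam:::cc_label_cpp(sk))
  expect_equal(n_skel, n_mask)
})

test_that("vessel_length follows the declared step conventions", {
  expect_equal(vessel_length(matrix(0L, 5, 5)), 0)
  m <- matrix(0L, 10, 120)
  m[5, 11:110] <- 1L                               # 100-px horizontal run
  expect_equal(vessel_length(m), 99)
  expect_equal(vessel_length(m, method = "chain"), 99)
  d <- matrix(0L, 60, 60)
  for (i in 1:50) d[i + 2, i + 2] <- 1L            # 50-px diagonal run
  expect_equal(vessel_length(d), 49 * sqrt(2), tolerance = 1e-12)
  expect_equal(vessel_length(d, method = "chain"), 49 * sqrt(2),
               tolerance = 1e-12)
})

test_that("branch points are counted and clustered correctly", {
  line <- matrix(0L, 20, 40)
  line[10, 5:35] <- 1L
  expect_equal(branch_points(line), 0L, ignore_attr = TRUE)

  # Y: three 20-px arms meeting at one pixel
  y <- matrix(0L, 50, 50)
  y[25:44, 25] <- 1L                                # downward arm
  for (i in 0:19) {
    y[25 - i, 25 - i] <- 1L                         # up-left arm
    y[25 - i, 25 + i] <- 1L                         # up-right arm
  }
  expect_equal(branch_points(y), 1L, ignore_attr = TRUE)

  # plus: four arms, one junction region
  pl <- matrix(0L, 50, 50)
  pl[25, 5:45] <- 1L
  pl[5:45, 25] <- 1L
  expect_equal(branch_points(pl), 1L, ignore_attr = TRUE)

  # brute-force oracle on the Y: candidate pixels by crossing number,
  # then single-linkage clustering, implemented independently here
  nb_transitions <- function(sk, r, c) {
    at <- function(rr, cc) {
      if (rr < 1 || rr > nrow(sk) || cc < 1 || cc > ncol(sk)) 0L
      else sk[rr, cc]
    }
    seq8 <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1),
              at(r + 1, c + 1), at(r + 1, c), at(r + 1, c - 1),
              at(r, c - 1), at(r - 1, c - 1), at(r - 1, c))
    sum(seq8[-9] == 0 & seq8[-1] == 1)
  }
  cand <- which(y == 1, arr.ind = TRUE)
  cand <- cand[apply(cand, 1, function(p)
    nb_transitions(y, p[1], p[2]) >= 3), , drop = FALSE]
  expect_equal(nrow(cand), 1)                      # oracle agrees: 1 cluster
})

test_that("mean thickness matches the distance-transform convention", {
  line <- matrix(0L, 10, 40)
  line[5, 5:35] <- 1L
  expect_equal(mean_thickness(line), 1.0)

  rect <- matrix(0L, 30, 220)
  rect[10:20, 11:210] <- 1L                        # 11 x 200 bar
  # brute-force EDT oracle on the centre row
  sk <- skeletonize_mask(rect)
  bg <- which(rect == 0, arr.ind = TRUE)
  edt_oracle <- function(r, c)
    sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  idx <- which(sk == 1, arr.ind = TRUE)
  oracle <- mean(2 * apply(idx, 1, function(p)
    edt_oracle(p[1], p[2])) - 1)
  expect_equal(mean_thickness(rect, sk), oracle, tolerance = 1e-9)
  expect_lt(abs(mean_thickness(rect) - 11) / 11, 0.05)

  expect_error(mean_thickness(matrix(0L, 5, 5)), "empty skeleton")
})

test_that("quantify composes the four readouts", {
  tr <- straight_tree(x0 = 60, y0 = 100, len = 100, r = 5)
  ras <- rasterize_tree(tr)
  q <- quantify(ras$mask)
  expect_equal(q$area_px2, ras$morphometrics$area_px2)  # area is exact
  expect_lt(abs(q$length_px - 100) / 100, 0.05)
  expect_lt(abs(q$thickness_px - 11) / 11, 0.10)  # discrete width of d=10
  expect_equal(q$branch_points, 0L)

  empty <- quantify(matrix(0L, 20, 20))
  expect_equal(empty$area_px2, 0)
  expect_equal(empty$length_px, 0)
  expect_equal(empty$thickness_px, 0)
  expect_equal(empty$branch_points, 0L)
  expect_true("empty_skeleton" %in% empty$flags)
})

test_that("two well-separated Y-trees give two branch points", {
  mk_y <- function(m, r0, c0) {
    m[r0:(r0 + 19), c0] <- 1L
    for (i in 0:19) {
      m[r0 - i, c0 - i] <- 1L
      m[r0 - i, c0 + i] <- 1L
    }
    m
  }
  m <- matrix(0L, 140, 140)
  m <- mk_y(m, 40, 40)
  m <- mk_y(m, 100, 100)
  q <- quantify(m, min_component = 10, prune_px = 0)
  expect_equal(q$branch_points, 2L)
})

test_that("readouts are translation invariant away from borders", {
  tr <- oracle_tree(2)
  m <- rasterize_tree(tr, c(512, 512))$mask
  # embed with two different offsets in a larger canvas
  big1 <- matrix(0L, 600, 600); big1[10 + 1:512, 20 + 1:512] <- m
  big2 <- matrix(0L, 600, 600); big2[60 + 1:512, 45 + 1:512] <- m
  q1 <- quantify(big1); q2 <- quantify(big2)
  expect_equal(q1$area_px2, q2$area_px2)
  expect_equal(q1$length_px, q2$length_px)
  expect_equal(q1$thickness_px, q2$thickness_px)
  expect_equal(q1$branch_points, q2$branch_points)
})

test_that("rotation by 90 degrees preserves the readouts", {
  tr <- oracle_tree(3)
  m <- rasterize_tree(tr, c(512, 512))$mask
  mr <- t(m)[ncol(m):1, , drop = FALSE]
  q <- quantify(m); qr <- quantify(mr)
  expect_equal(qr$area_px2, q$area_px2)            # exact
  expect_equal(qr$branch_points, q$branch_points)  # exact
  expect_lt(abs(qr$length_px - q$length_px) / q$length_px, 0.02)
  expect_lt(abs(qr$thickness_px - q$thickness_px) / q$thickness_px, 0.02)
})

test_that("scaling radii up raises thickness, leaves branch count fixed", {
  scale_tree <- function(tr, f) {
    tr$segments <- lapply(tr$segments, function(s) {
      s$radius <- s$radius * f
      s
    })
    tr
  }
  # pick a tree that stays well separated after scaling, so the branch
  # structure remains measurable in both versions
  done <- FALSE
  for (sd in 1:40) {
    tr <- oracle_tree(sd)
    tr2 <- scale_tree(tr, 1.25)
    if (nrow(tr$branch_points) >= 2 &&
        tree_well_separated(tr, 4) && tree_well_separated(tr2, 4)) {
      q1 <- quantify(rasterize_tree(tr)$mask)
      q2 <- quantify(rasterize_tree(tr2)$mask)
      expect_gt(q2$thickness_px, q1$thickness_px)
      expect_equal(q2$branch_points, q1$branch_points)
      done <- TRUE
      break
    }
  }
  expect_true(done)
})

test_that("quantify agrees with analytic truth on well-separated trees", {
  seeds <- oracle_suite_seeds(8)
  expect_gte(length(seeds), 8)
  for (sd in seeds) {
    ras <- rasterize_tree(oracle_tree(sd))
    q <- quantify(ras$mask)
    t <- ras$morphometrics
    expect_equal(q$area_px2, t$area_px2)
    expect_lt(abs(q$length_px - t$length_px) / t$length_px, 0.05)
    expect_lt(abs(q$thickness_px - t$thickness_px) / t$thickness_px, 0.10)
    expect_equal(q$branch_points, t$branch_points)
  }
})
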