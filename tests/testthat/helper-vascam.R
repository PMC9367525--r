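# shared fixtures, all generated in code

# a minimal hand-built tree: one straight horizontal segment at fractional
# coordinates (avoids the degenerate integer-phase rasterization tie)
straight_tree <- function(x0 = 60.37, y0 = 100.37, len = 100, r = 5,
                          canvas = c(200L, 220L), deep = FALSE) {
  seg <- list(id = 1L, parent = NA_integer_,
              xy = rbind(c(x0, y0), c(x0 + len, y0)),
              radius = r, depth = 1L, deep = deep)
  structure(list(segments = list(seg),
                 branch_points = data.frame(x = numeric(0), y = numeric(0),
                                            deep = logical(0)),
                 canvas = canvas, diameter_range = c(2 * r, 2 * r),
                 seed = NULL),
            class = "vascam_tree")
}

# two far-apart straight segments (detection fixtures)
two_segment_tree <- function(canvas = c(200L, 200L)) {
  s1 <- list(id = 1L, parent = NA_integer_,
             xy = rbind(c(20, 50), c(180, 50)), radius = 4, depth = 1L,
             deep = FALSE)
  s2 <- list(id = 2L, parent = NA_integer_,
             xy = rbind(c(20, 150), c(180, 150)), radius = 4, depth = 1L,
             deep = FALSE)
  structure(list(segments = list(s1, s2),
                 branch_points = data.frame(x = numeric(0), y = numeric(0),
                                            deep = logical(0)),
                 canvas = canvas, diameter_range = c(8, 8), seed = NULL),
            class = "vascam_tree")
}

# parameters of the morphometry oracle suite: well-separated trees with
# moderate curvature and diameters where the <= 1 px discretisation bias
# of the thickness estimator stays well under the 10% tolerance
oracle_tree <- function(seed) {
  generate_vessel_tree(c(512L, 512L), n_roots = 2, branch_probability = 0.2,
                       branch_angle_spread = pi / 2,
                       diameter_range = c(16, 36), taper_factor = 0.85,
                       deep_fraction = 0, step_px = 8, max_steps = 45,
                       max_segments = 9, min_branch_gap = 6, max_depth = 3,
                       curvature_sd = 0.07, seed = seed)
}

oracle_suite_seeds <- function(n = 50, max_seed = 3000) {
  ok <- integer(0)
  sd <- 0L
  while (length(ok) < n && sd < max_seed) {
    sd <- sd + 1L
    tr <- oracle_tree(sd)
    sup <- Filter(function(s) !s$deep, tr$segments)
    big_enough <- length(tr$segments) >= 4 &&
      sum(vapply(sup, function(s) {
        d <- diff(s$xy)
        sum(sqrt(rowSums(d^2)))
      }, numeric(1))) >= 500
    if (big_enough && tree_well_separated(tr, clearance = 4))
      ok <- c(ok, sd)
  }
  ok
}

# one small trained model, cached per test session (micro training run on
# a 96 px easy sample; enough for pipeline plumbing tests)
.vascam_test_env <- new.env(parent = emptyenv())

tiny_model <- function() {
  if (!is.null(.vascam_test_env$model)) return(.vascam_test_env$model)
  train <- lapply(1:4, function(sd) simulate_cam_sample(c(96, 96), seed = sd))
  val <- lapply(11:12, function(sd) simulate_cam_sample(c(96, 96), seed = sd))
  cfg <- seg_config(max_epochs = 6, patience = 6, tile_size = 96,
                    tile_overlap = 16, seed = 7)
  fit <- train_segmenter(train, val, cfg)
  .vascam_test_env$model <- fit$model
  fit$model
}

# hand-crafted PNG bytes (independent of the package's own writer): gray,
# given bit depth, uncompressed deflate blocks + adler32, for reader tests
make_gray_png <- function(path, values, bit_depth = 8) {
  h <- nrow(values); w <- ncol(values)
  be32 <- function(x) {
    x <- as.numeric(x) %% 2^32   # may exceed .Machine$integer.max
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256,
             x %% 256))
  }
  crc_table <- local({
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) == 1L)
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) else
          bitwShiftR(bitwAnd(c, -2L), 1)
      tab[n + 1] <- c
    }
    tab
  })
  crc32 <- function(bytes) {
    c <- -1L
    for (b in as.integer(bytes))
      c <- bitwXor(crc_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                   bitwShiftR(bitwAnd(c, -256L), 8))
    be32(bitwXor(c, -1L) %% 2^32)
  }
  chunk <- function(type, data) {
    td <- c(charToRaw(type), data)
    c(be32(length(data)), td, crc32(td))
  }
  # raw scanlines with filter byte 0
  if (bit_depth == 8) {
    rows <- lapply(seq_len(h), function(r)
      c(as.raw(0), as.raw(values[r, ])))
  } else {
    rows <- lapply(seq_len(h), function(r) {
      v <- as.integer(values[r, ])
      c(as.raw(0), as.raw(rbind(v %/% 256, v %% 256)))
    })
  }
  raw_data <- do.call(c, rows)
  # zlib stream with stored (uncompressed) deflate blocks
  adler32 <- function(bytes) {
    a <- 1; b <- 0
    for (x in as.integer(bytes)) {
      a <- (a + x) %% 65521
      b <- (b + a) %% 65521
    }
    be32(b * 65536 + a)
  }
  stored <- raw(0)
  i <- 1
  n <- length(raw_data)
  while (i <= n) {
    j <- min(n, i + 65534)
    blk <- raw_data[i:j]
    final <- if (j == n) as.raw(1) else as.raw(0)
    ln <- length(blk)
    stored <- c(stored, final,
                as.raw(c(ln %% 256, ln %/% 256,
                         255 - ln %% 256, 255 - ln %/% 256)), blk)
    i <- j + 1
  }
  zstream <- c(as.raw(c(0x78, 0x01)), stored, adler32(raw_data))
  ihdr <- c(be32(w), be32(h), as.raw(c(bit_depth, 0, 0, 0, 0)))
  png <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", zstream),
           chunk("IEND", raw(0)))
  writeBin(png, path)
  invisible(path)
}
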