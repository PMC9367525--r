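#' Generate a random branching vessel tree
#'
#' Grows a parametric vascular tree on a pixel canvas by a midpoint-jittered
#' random walk with stochastic tip bifurcation, emulating the curvilinear
#' branching vasculature of the chick chorioallantoic membrane (CAM).  Each
#' segment carries a constant radius; at a bifurcation the parent segment
#' ends and two children start with radius scaled by `taper_factor`, so a
#' child is never thicker than its parent.  Whole trees rooted at a "deep"
#' root model sub-membrane vessels: they are rendered blurred by
#' [render_cam_image()] and excluded from the ground-truth mask.
#'
#' @param canvas_size integer `c(rows, cols)` of the target raster; each
#'   side must be at least 64 px.
#' @param n_roots number of root vessels entering from the canvas border.
#' @param branch_probability per-step probability that a growing tip
#'   bifurcates (in `[0, 1]`); 0 yields one unbranched segment per root.
#' @param branch_angle_spread full opening angle (radians) between the two
#'   children at a bifurcation.
#' @param diameter_range allowed vessel diameters `c(min, max)` in px;
#'   must lie within `[1, min(canvas_size)/2]`.  Default: 3 px up to the
#'   smaller of 220 px and half the canvas.
#' @param taper_factor multiplicative radius taper applied to children at
#'   each bifurcation (in `(0, 1]`).  Children that would fall below the
#'   minimum diameter are clamped to it and stop branching, so deep
#'   branching trees contain segments at the lower diameter bound.
#' @param deep_fraction probability that a root (and hence its whole
#'   subtree) is a blurred sub-membrane distractor.  At least one root is
#'   always superficial.
#' @param root_diameters optional explicit root diameters (recycled);
#'   values are clamped into `diameter_range`.
#' @param step_px random-walk step length in px.
#' @param max_steps maximum steps a single segment may grow.
#' @param max_segments cap on the number of segments in the tree.
#' @param min_branch_gap minimum number of steps a segment must grow
#'   before it may bifurcate (keeps branch points apart).
#' @param max_depth maximum bifurcation depth.
#' @param curvature_sd standard deviation (radians) of the per-step
#'   direction jitter; larger values give wigglier, more tortuous
#'   vessels.
#' @param seed integer seed; the tree is a pure function of the parameters
#'   and the seed.  `NULL` uses the current RNG stream.
#' @return an object of class `vascam_tree`: a list with `segments` (each
#'   with `id`, `xy` polyline matrix of (x, y) pixel coordinates, `radius`
#'   in px, `depth`, `deep` flag), `branch_points` (data frame of branch
#'   vertex coordinates and their `deep` flag), `canvas`, `diameter_range`
#'   and `seed`.
#' @export
generate_vessel_tree <- function(canvas_size = c(512L, 512L),
                                 n_roots = 3,
                                 branch_probability = 0.4,
                                 branch_angle_spread = pi / 3,
                                 diameter_range = NULL,
                                 taper_factor = 0.8,
                                 deep_fraction = 0.15,
                                 root_diameters = NULL,
                                 step_px = 6,
                                 max_steps = 60,
                                 max_segments = 80,
                                 min_branch_gap = 4,
                                 max_depth = 6,
                                 curvature_sd = 0.22,
                                 seed = NULL) {
  canvas_size <- as.integer(canvas_size)
  if (length(canvas_size) != 2 || any(canvas_size < 64))
    stopf("degenerate canvas: each side must be >= 64 px, got %s",
          paste(canvas_size, collapse = "x"))
  H <- canvas_size[1]; W <- canvas_size[2]
  if (is.null(diameter_range))
    diameter_range <- c(3, min(220, floor(min(canvas_size) / 2)))
  if (diameter_range[1] < 1 || diameter_range[2] > min(canvas_size) / 2 ||
      diameter_range[1] > diameter_range[2])
    stopf("diameter_range must lie within [1, %d]", min(canvas_size) %/% 2)
  if (branch_probability < 0 || branch_probability > 1)
    stopf("branch_probability must be in [0, 1]")
  if (taper_factor <= 0 || taper_factor > 1)
    stopf("taper_factor must be in (0, 1]")

  maybe_with_seed(seed, {
    deep_flags <- stats::runif(n_roots) < deep_fraction
    if (all(deep_flags)) deep_flags[1] <- FALSE
    if (is.null(root_diameters)) {
      dlo <- max(diameter_range[1], min(6, diameter_range[2]))
      root_diameters <- exp(stats::runif(n_roots, log(dlo),
                                         log(diameter_range[2])))
    } else {
      root_diameters <- rep_len(root_diameters, n_roots)
    }
    root_diameters <- pmin(pmax(root_diameters, diameter_range[1]),
                           diameter_range[2])

    segs <- list()
    events <- list()  # bifurcation events; counted only if both children materialize
    tips <- list()
    for (i in seq_len(n_roots)) {
      side <- sample.int(4L, 1L)
      if (side == 1L) {        # left
        x <- 1; y <- stats::runif(1, 1, H); theta <- 0
      } else if (side == 2L) { # right
        x <- W; y <- stats::runif(1, 1, H); theta <- pi
      } else if (side == 3L) { # top
        x <- stats::runif(1, 1, W); y <- 1; theta <- pi / 2
      } else {                 # bottom
        x <- stats::runif(1, 1, W); y <- H; theta <- -pi / 2
      }
      theta <- theta + stats::runif(1, -pi / 6, pi / 6)
      tips[[i]] <- list(x = x, y = y, theta = theta,
                        r = root_diameters[i] / 2, depth = 1L,
                        deep = deep_flags[i], parent = NA_integer_,
                        event = NA_integer_)
    }

    nseg <- 0L
    while (length(tips) > 0 && nseg < max_segments) {
      tip <- tips[[length(tips)]]
      tips[[length(tips)]] <- NULL
      x <- tip$x; y <- tip$y; theta <- tip$theta
      pts <- matrix(c(x, y), ncol = 2)
      branched <- FALSE
      for (s in seq_len(max_steps)) {
        theta <- theta + stats::rnorm(1, 0, curvature_sd)
        nx <- x + step_px * cos(theta)
        ny <- y + step_px * sin(theta)
        if (nx < 1 || nx > W || ny < 1 || ny > H) break
        x <- nx; y <- ny
        pts <- rbind(pts, c(x, y))
        can_branch <- s >= min_branch_gap && tip$depth < max_depth &&
          nseg + length(tips) + 2L <= max_segments
        if (can_branch && stats::runif(1) < branch_probability) {
          branched <- TRUE
          break
        }
      }
      if (nrow(pts) < 2) next
      nseg <- nseg + 1L
      segs[[nseg]] <- list(id = nseg, parent = tip$parent, xy = pts,
                           radius = tip$r, depth = tip$depth,
                           deep = tip$deep)
      if (!is.na(tip$event))
        events[[tip$event]]$children <- events[[tip$event]]$children + 1L
      if (branched) {
        events[[length(events) + 1L]] <-
          list(x = x, y = y, deep = tip$deep, children = 0L)
        ev_id <- length(events)
        rc <- tip$r * taper_factor
        child_depth <- tip$depth + 1L
        if (2 * rc < diameter_range[1]) {
          rc <- diameter_range[1] / 2  # clamp at the lower diameter bound
          child_depth <- as.integer(max_depth)  # terminal: no more branching
        }
        for (sgn in c(-1, 1)) {
          half <- branch_angle_spread / 2 * stats::runif(1, 0.5, 1)
          tips[[length(tips) + 1L]] <-
            list(x = x, y = y, theta = theta + sgn * half, r = rc,
                 depth = child_depth, deep = tip$deep, parent = nseg,
                 event = ev_id)
        }
      }
    }

    # a bifurcation is a branch point only if both children materialized;
    # with one child it is a bend, with none an ordinary tip
    real <- Filter(function(e) e$children >= 2L, events)
    structure(list(
      segments = segs,
      branch_points = data.frame(
        x = vapply(real, `[[`, numeric(1), "x"),
        y = vapply(real, `[[`, numeric(1), "y"),
        deep = vapply(real, `[[`, logical(1), "deep")),
      canvas = canvas_size,
      diameter_range = diameter_range,
      seed = seed
    ), class = "vascam_tree")
  })
}

#' @export
print.vascam_tree <- function(x, ...) {
  ns <- length(x$segments)
  nd <- sum(vapply(x$segments, function(s) s$deep, logical(1)))
  cat(sprintf(
    "<vascam_tree> %d segments (%d deep distractors), %d branch points, %dx%d canvas\n",
    ns, nd, nrow(x$branch_points), x$canvas[1], x$canvas[2]))
  invisible(x)
}

# consecutive-vertex capsule pieces for a set of segments:
# matrix columns x0, y0, x1, y1, r0, r1
tree_pieces <- function(segments) {
  if (length(segments) == 0)
    return(matrix(numeric(0), ncol = 6))
  do.call(rbind, lapply(segments, function(s) {
    n <- nrow(s$xy)
    if (n < 2) return(NULL)
    cbind(s$xy[-n, 1], s$xy[-n, 2], s$xy[-1, 1], s$xy[-1, 2],
          s$radius, s$radius)
  }))
}

seg_arclength <- function(s) {
  d <- diff(s$xy)
  sum(sqrt(rowSums(d^2)))
}

#' Test whether a tree's segments are well separated
#'
#' Skeleton-based morphometry can only be compared exactly against the
#' analytic tree when distinct vessels neither cross nor run within
#' touching distance of each other and branch vertices are far apart.
#' This predicate checks, purely on the tree geometry: (1) all branch
#' vertices are at least `3 * max(radius)` apart; (2) for every pair of
#' segments that do not share a branch vertex, the minimum distance
#' between their polylines exceeds the sum of their radii plus
#' `clearance`; (3) for parent/child and sibling pairs the same holds
#' outside an exclusion zone around the shared vertex.  Used to build
#' oracle validation suites by rejection sampling.
#'
#' @param tree a `vascam_tree`.
#' @param clearance extra separation margin in px.
#' @return TRUE if the tree is well separated.
#' @export
tree_well_separated <- function(tree, clearance = 3) {
  segs <- tree$segments
  n <- length(segs)
  if (n == 0) return(FALSE)
  maxr <- max(vapply(segs, function(s) s$radius, numeric(1)))
  bp <- tree$branch_points
  if (nrow(bp) >= 2) {
    d <- stats::dist(bp[, c("x", "y")])
    if (any(d < 3 * maxr)) return(FALSE)
  }
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      si <- segs[[i]]; sj <- segs[[j]]
      related <- (!is.na(sj$parent) && sj$parent == si$id) ||
        (!is.na(si$parent) && si$parent == sj$id) ||
        (!is.na(si$parent) && !is.na(sj$parent) && si$parent == sj$parent)
      pi_ <- si$xy; pj <- sj$xy
      if (related) {
        # shared vertex: the child's first point
        v <- if (!is.na(sj$parent) && sj$parent == si$id) pj[1, ]
             else pi_[1, ]
        excl <- 2 * (si$radius + sj$radius) + 2 * clearance
        keep_i <- sqrt((pi_[, 1] - v[1])^2 + (pi_[, 2] - v[2])^2) > excl
        keep_j <- sqrt((pj[, 1] - v[1])^2 + (pj[, 2] - v[2])^2) > excl
        pi2 <- pi_[keep_i, , drop = FALSE]
        pj2 <- pj[keep_j, , drop = FALSE]
        # a segment fully inside the exclusion zone never emerges from the
        # junction blob; its branch vertex would not be measurable
        if (nrow(pi2) == 0 || nrow(pj2) == 0) return(FALSE)
      } else {
        pi2 <- pi_; pj2 <- pj
      }
      if (nrow(pi2) == 0 || nrow(pj2) == 0) next
      dd <- outer(pi2[, 1], pj2[, 1], `-`)^2 +
        outer(pi2[, 2], pj2[, 2], `-`)^2
      if (min(dd) < (si$radius + sj$radius + clearance)^2) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a vessel tree into a ground-truth mask with analytic readouts
#'
#' Only superficial segments contribute: deep-distractor segments are by
#' definition not part of the measurable vasculature.  The analytic
#' morphometrics are: total length = sum of superficial polyline arc
#' lengths; branching points = number of superficial bifurcation vertices;
#' total area = number of rasterized superficial pixels; mean thickness =
#' length-weighted mean segment diameter.
#'
#' @param tree a `vascam_tree`.
#' @param canvas_size raster size `c(rows, cols)`; defaults to the canvas
#'   the tree was grown on.
#' @return list with `mask` (0/1 integer matrix) and `morphometrics`
#'   (class `vascam_morphometrics`).
#' @export
rasterize_tree <- function(tree, canvas_size = tree$canvas) {
  H <- canvas_size[1]; W <- canvas_size[2]
  sup <- Filter(function(s) !s$deep, tree$segments)
  if (length(sup) == 0) {
    mask <- matrix(0L, H, W)
    morph <- new_morphometrics(0, 0, 0, 0L)
    return(list(mask = mask, morphometrics = morph))
  }
  pieces <- tree_pieces(sup)
  mask <- raster_capsules_cpp(pieces, H, W)
  lens <- vapply(sup, seg_arclength, numeric(1))
  diams <- vapply(sup, function(s) 2 * s$radius, numeric(1))
  morph <- new_morphometrics(
    area_px2 = sum(mask),
    length_px = sum(lens),
    thickness_px = stats::weighted.mean(diams, lens),
    branch_points = sum(!tree$branch_points$deep)
  )
  list(mask = mask, morphometrics = morph)
}

#' Rendering style for synthetic CAM images
#'
#' Visual parameters for [render_cam_image()], loosely matched to the look
#' of in ovo CAM microscopy: dark red vessels on a pink-yellow membrane,
#' blurred paler sub-membrane vessels, an optional pale tumor disc, a
#' low-frequency illumination gradient and additive sensor noise.  All
#' colors and intensities are on `[0, 1]`.
#'
#' @param background_rgb mean background color.
#' @param gradient_amp amplitude of the multiplicative low-frequency
#'   illumination field.
#' @param vessel_rgb color of superficial vessels.
#' @param deep_rgb color of deep (sub-membrane) distractor vessels.
#' @param blur_superficial Gaussian blur sigma (px) for superficial
#'   vessels.
#' @param blur_deep blur sigma (px) for deep vessels; must exceed
#'   `blur_superficial`.
#' @param noise_sd additive Gaussian sensor noise SD.
#' @param tumor either `NULL` (no tumor) or a list with optional `center`
#'   (x, y), `radius` (px) and `rgb`; missing entries are drawn at render
#'   time.
#' @return a `vascam_style` list.
#' @export
cam_style <- function(background_rgb = c(0.92, 0.80, 0.70),
                      gradient_amp = 0.10,
                      vessel_rgb = c(0.60, 0.19, 0.22),
                      deep_rgb = c(0.72, 0.45, 0.48),
                      blur_superficial = 0.8,
                      blur_deep = 4,
                      noise_sd = 0.025,
                      tumor = list()) {
  if (blur_deep <= blur_superficial)
    stopf("blur_deep must be strictly greater than blur_superficial")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(background_rgb = background_rgb,
                 gradient_amp = gradient_amp,
                 vessel_rgb = vessel_rgb, deep_rgb = deep_rgb,
                 blur_superficial = blur_superficial, blur_deep = blur_deep,
                 noise_sd = noise_sd, tumor = tumor),
            class = "vascam_style")
}

#' Render a synthetic CAM image from a vessel tree
#'
#' Deterministic per seed.  Deep-distractor segments are drawn with a
#' strong Gaussian blur and a paler color and are excluded from the
#' returned ground-truth mask; superficial vessels are drawn darker than
#' the membrane background (in particular in the green channel).
#'
#' @param tree a `vascam_tree`.
#' @param style a `vascam_style`, see [cam_style()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an object of class `vascam_sample`: list with `image`
#'   (rows x cols x 3 array on `[0, 1]`), `truth_mask` (0/1 matrix,
#'   superficial vessels only), `truth_morphometrics`, `tree` and `seed`.
#' @export
render_cam_image <- function(tree, style = cam_style(), seed = NULL) {
  H <- tree$canvas[1]; W <- tree$canvas[2]
  ras <- rasterize_tree(tree)
  maybe_with_seed(seed, {
    gx <- matrix(rep(seq_len(W) / W, each = H), H, W)
    gy <- matrix(rep(seq_len(H) / H, times = W), H, W)
    ab <- stats::runif(2, -1, 1)
    fr <- stats::runif(2, 0.5, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    illum <- 1 + style$gradient_amp *
      (ab[1] * (gx - 0.5) + ab[2] * (gy - 0.5) +
         0.5 * sin(2 * pi * (fr[1] * gx + fr[2] * gy) + ph))

    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- style$background_rgb[ch]

    # tumor disc: drawn under the vessels (vessels grow over the graft)
    if (!is.null(style$tumor)) {
      tum <- style$tumor
      if (is.null(tum$center))
        tum$center <- c(W / 2, H / 2) + stats::runif(2, -0.08, 0.08) * c(W, H)
      if (is.null(tum$radius))
        tum$radius <- stats::runif(1, 0.10, 0.16) * min(H, W)
      if (is.null(tum$rgb)) tum$rgb <- c(0.82, 0.76, 0.62)
      dd <- sqrt((gx * W - tum$center[1])^2 + (gy * H - tum$center[2])^2)
      alpha <- 1 / (1 + exp((dd - tum$radius) / 2))
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + tum$rgb[ch] * alpha
    }

    deep <- Filter(function(s) s$deep, tree$segments)
    if (length(deep) > 0) {
      dmask <- raster_capsules_cpp(tree_pieces(deep), H, W)
      alpha <- gauss_blur_cpp(dmask + 0, style$blur_deep) * 0.85
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + style$deep_rgb[ch] * alpha
    }

    if (sum(ras$mask) > 0) {
      alpha <- gauss_blur_cpp(ras$mask + 0, style$blur_superficial) * 0.95
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + style$vessel_rgb[ch] * alpha
    }

    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * illum +
        stats::rnorm(H * W, 0, style$noise_sd)
    }
    img <- clamp01(img)

    structure(list(image = img, truth_mask = ras$mask,
                   truth_morphometrics = ras$morphometrics,
                   tree = tree, seed = seed),
              class = "vascam_sample")
  })
}

#' Simulate one synthetic CAM sample (tree, image, mask, truth)
#'
#' Convenience wrapper seeding one master RNG stream per sample, from
#' which all stochastic draws (tree growth, rendering, noise) flow.
#'
#' @param canvas_size raster size `c(rows, cols)`.
#' @param seed master seed for the sample.
#' @param tree_params named list of overrides for [generate_vessel_tree()].
#' @param style rendering style, see [cam_style()].
#' @return a `vascam_sample`.
#' @export
simulate_cam_sample <- function(canvas_size = c(512L, 512L), seed = 1L,
                                tree_params = list(), style = cam_style()) {
  maybe_with_seed(seed, {
    tree <- do.call(generate_vessel_tree,
                    c(list(canvas_size = canvas_size), tree_params,
                      list(seed = NULL)))
    smp <- render_cam_image(tree, style, seed = NULL)
    smp$seed <- seed
    smp
  })
}

#' @export
print.vascam_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<vascam_sample> %dx%d image, %d vessel px, seed %s\n",
              d[1], d[2], sum(x$truth_mask),
              if (is.null(x$seed)) "<stream>" else x$seed))
  invisible(x)
}

#' Generate synthetic LSCI-style perfusion frame sequences
#'
#' Builds a sequence of perfusion maps (arbitrary perfusion units, PU)
#' over the vessel geometry of `tree`.  Unlike the photographic ground
#' truth, perfusion includes both superficial and deep segments, mirroring
#' how laser speckle contrast imaging picks up sub-membrane flow.  Each
#' segment carries one PU level drawn from `pu_vessel_range`; frames add
#' per-pixel Gaussian noise, and frames listed in `motion_frames` receive
#' a global additive PU perturbation that emulates embryo motion.
#'
#' @param tree a `vascam_tree`.
#' @param pu_vessel_range range `c(lo, hi)` of per-segment PU levels.
#' @param pu_background PU level of non-vessel tissue.
#' @param n_frames number of frames (one frame per second of recording).
#' @param motion_frames integer indices (1-based) of frames perturbed by
#'   motion; must lie in `[1, n_frames]`.
#' @param pixel_pitch_mm physical pixel size in mm.
#' @param noise_sd per-pixel, per-frame Gaussian noise SD in PU.
#' @param motion_amp global PU offset added to motion frames.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return class `vascam_frames`: list with `frames` (list of matrices),
#'   `pixel_pitch_mm`, `truth` (the noiseless PU map), `motion_frames`
#'   and `seed`.
#' @export
generate_perfusion_frames <- function(tree,
                                      pu_vessel_range = c(1200, 2600),
                                      pu_background = 120,
                                      n_frames = 20,
                                      motion_frames = integer(0),
                                      pixel_pitch_mm = 0.1,
                                      noise_sd = 20,
                                      motion_amp = 600,
                                      seed = NULL) {
  if (length(motion_frames) > 0 &&
      (any(motion_frames < 1) || any(motion_frames > n_frames)))
    stopf("motion_frames must lie in [1, n_frames]")
  if (pixel_pitch_mm <= 0) stopf("pixel_pitch_mm must be > 0")
  H <- tree$canvas[1]; W <- tree$canvas[2]
  maybe_with_seed(seed, {
    truth <- matrix(pu_background, H, W)
    for (s in tree$segments) {
      pu <- stats::runif(1, pu_vessel_range[1], pu_vessel_range[2])
      m <- raster_capsules_cpp(tree_pieces(list(s)), H, W)
      truth[m == 1] <- pu
    }
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      f <- truth + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      if (i %in% motion_frames) f <- f + motion_amp
      frames[[i]] <- pmax(f, 0)
    }
    structure(list(frames = frames, pixel_pitch_mm = pixel_pitch_mm,
                   truth = truth, motion_frames = motion_frames,
                   seed = seed),
              class = "vascam_frames")
  })
}
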