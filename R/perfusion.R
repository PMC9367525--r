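#' Perfusion map with physical calibration
#'
#' A 2D field of arbitrary perfusion units (PU) as produced by laser
#' speckle contrast imaging, together with the pixel-to-mm calibration.
#'
#' @param values numeric matrix of PU values (>= 0).
#' @param pixel_pitch_mm physical size of one pixel side in mm (> 0).
#' @return an object of class `vascam_pumap`.
#' @export
perfusion_map <- function(values, pixel_pitch_mm) {
  if (!is.matrix(values) || any(values < 0))
    stopf("perfusion values must be a matrix of non-negative PU")
  if (pixel_pitch_mm <= 0) stopf("pixel_pitch_mm must be > 0")
  structure(list(values = values, pixel_pitch_mm = pixel_pitch_mm),
            class = "vascam_pumap")
}

#' Perfusion analysis configuration
#'
#' @param filter_lo,filter_hi PU band retained by [apply_pu_filter()];
#'   both bounds inclusive.  Defaults 800 and 3000 PU.
#' @param k_frames number of consecutive still frames averaged by
#'   [stable_window()]; default 10.
#' @param stability_tol maximum allowed frame-to-frame mean absolute PU
#'   difference within the selected window.
#' @return a `vascam_pu_config` list.
#' @export
perfusion_config <- function(filter_lo = 800, filter_hi = 3000,
                             k_frames = 10, stability_tol = 150) {
  if (filter_lo < 0 || filter_lo >= filter_hi)
    stopf("need 0 <= filter_lo < filter_hi")
  if (k_frames < 1) stopf("k_frames must be >= 1")
  structure(list(filter_lo = filter_lo, filter_hi = filter_hi,
                 k_frames = as.integer(k_frames),
                 stability_tol = stability_tol),
            class = "vascam_pu_config")
}

frames_as_list <- function(frames) {
  if (inherits(frames, "vascam_frames"))
    return(list(frames = frames$frames, pitch = frames$pixel_pitch_mm))
  if (is.list(frames) && all(vapply(frames, is.matrix, logical(1))))
    return(list(frames = frames, pitch = NULL))
  stopf("frames must be a vascam_frames object or a list of matrices")
}

#' Select the most stable consecutive-frame window and average it
#'
#' Emulates the recording protocol of waiting for `k_frames` consecutive
#' images during which the embryo stays still: among all windows of
#' `k_frames` consecutive frames the one minimising the maximum
#' frame-to-frame mean absolute PU difference is chosen (ties broken by
#' the earliest window), and the pixel-wise mean over that window is
#' returned.  It is an error if no window meets the stability tolerance.
#'
#' @param frames a `vascam_frames` object or list of equally sized
#'   matrices.
#' @param config a `vascam_pu_config`.
#' @param pixel_pitch_mm calibration used when `frames` is a plain list.
#' @return list with `start` (1-based index of the window start), `map`
#'   (averaged `vascam_pumap`) and `stability` (the window's criterion
#'   value).
#' @export
stable_window <- function(frames, config = perfusion_config(),
                          pixel_pitch_mm = NULL) {
  fl <- frames_as_list(frames)
  pitch <- if (!is.null(pixel_pitch_mm)) pixel_pitch_mm else fl$pitch
  if (is.null(pitch)) stopf("pixel_pitch_mm is required for plain frame lists")
  fr <- fl$frames
  n <- length(fr)
  k <- config$k_frames
  if (n < k) stopf("need at least k_frames = %d frames, got %d", k, n)
  dims <- vapply(fr, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must have the same shape")

  if (k == 1) {
    # no frame-to-frame difference is defined; earliest frame by tie-break
    best <- 1L; best_stat <- 0
  } else {
    d <- vapply(seq_len(n - 1),
                function(i) mean(abs(fr[[i + 1]] - fr[[i]])), numeric(1))
    stats_w <- vapply(seq_len(n - k + 1),
                      function(s) max(d[s:(s + k - 2)]), numeric(1))
    best <- which.min(stats_w)          # earliest on ties
    best_stat <- stats_w[best]
    if (best_stat > config$stability_tol)
      stopf(paste0("no stable window: best frame-to-frame mean |dPU| ",
                   "%.1f exceeds tolerance %.1f"),
            best_stat, config$stability_tol)
  }
  avg <- Reduce(`+`, fr[best:(best + k - 1)]) / k
  list(start = best, map = perfusion_map(avg, pitch), stability = best_stat)
}

#' Perfusion-band filter
#'
#' A pixel is perfused iff `filter_lo <= PU <= filter_hi`, both bounds
#' inclusive.
#'
#' @param map a `vascam_pumap`.
#' @param config a `vascam_pu_config`.
#' @return logical matrix of perfused pixels.
#' @export
apply_pu_filter <- function(map, config = perfusion_config()) {
  stopifnot(inherits(map, "vascam_pumap"))
  map$values >= config$filter_lo & map$values <= config$filter_hi
}

#' Summarize perfusion: mean PU, perfused area and mean blood flow
#'
#' The mean blood flow is the product of the mean perfusion value over
#' perfused pixels (PU) and the perfused area (mm^2); pixels outside the
#' configured PU band never contribute.
#'
#' @param map a `vascam_pumap`.
#' @param config a `vascam_pu_config`.
#' @return class `vascam_perfusion`: list with `mean_perfusion` (PU),
#'   `perfused_area_mm2`, `mean_blood_flow` (PU mm^2) and `n_pixels`.
#' @export
summarize_perfusion <- function(map, config = perfusion_config()) {
  stopifnot(inherits(map, "vascam_pumap"))
  sel <- apply_pu_filter(map, config)
  n <- sum(sel)
  area <- n * map$pixel_pitch_mm^2
  mean_pu <- if (n == 0) 0 else mean(map$values[sel])
  structure(list(mean_perfusion = mean_pu, perfused_area_mm2 = area,
                 mean_blood_flow = mean_pu * area, n_pixels = n),
            class = "vascam_perfusion")
}

#' @export
print.vascam_perfusion <- function(x, ...) {
  cat(sprintf(
    "<vascam_perfusion> mean %.1f PU | area %.2f mm^2 | flow %.1f PU.mm^2\n",
    x$mean_perfusion, x$perfused_area_mm2, x$mean_blood_flow))
  invisible(x)
}

#' Speckle contrast flow index (optional utility)
#'
#' Computes the local speckle contrast K = sd/mean of a raw speckle
#' intensity image over a square window and the associated relative flow
#' index 1/K^2.  This utility implements the textbook LSCI principle; the
#' perfusion pipeline itself operates on instrument PU maps and does not
#' use it.
#'
#' @param intensity raw speckle intensity matrix.
#' @param window odd window side in px.
#' @return list with matrices `K` and `flow_index`.
#' @export
speckle_contrast <- function(intensity, window = 7) {
  if (window %% 2 != 1 || window < 3) stopf("window must be odd and >= 3")
  pad <- (window - 1) / 2
  run1 <- function(m) {  # centered running mean down columns, edge padded
    mp <- m[c(rep(1, pad), seq_len(nrow(m)), rep(nrow(m), pad)), ,
            drop = FALSE]
    sm <- apply(mp, 2, function(col)
      as.numeric(stats::filter(col, rep(1 / window, window), sides = 2)))
    sm[pad + seq_len(nrow(m)), , drop = FALSE]
  }
  box <- function(m) t(run1(t(run1(m))))
  mu <- box(intensity)
  mu2 <- box(intensity^2)
  v <- pmax(mu2 - mu^2, 0)
  K <- sqrt(v) / pmax(mu, .Machine$double.eps)
  list(K = K, flow_index = 1 / pmax(K, .Machine$double.eps)^2)
}
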