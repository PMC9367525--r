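#' Read and write 8-bit PNG images and masks
#'
#' `read_image` returns intensities on `[0, 1]` as a rows x cols x
#' channels array (alpha channels are dropped); 16-bit files raise a
#' format error instead of being silently cast.  `read_mask` expects an
#' 8-bit grayscale PNG with values 0/255 only and returns a 0/1 integer
#' matrix; `write_mask` writes the reverse encoding.
#'
#' @param path file path.
#' @param image rows x cols x 3 (or x 1) array on `[0, 1]`.
#' @param mask 0/1 integer matrix.
#' @return `read_image`: numeric array; `read_mask`: integer matrix.
#' @export
read_image <- function(path) {
  r <- png_read_cpp(path)
  a <- array(r$data / 255, dim = c(r$height, r$width, r$channels))
  if (r$channels == 4) a <- a[, , 1:3, drop = FALSE]
  if (r$channels == 2) a <- a[, , 1, drop = FALSE]
  a
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  d <- dim(image)
  if (!d[3] %in% c(1, 3)) stopf("image must have 1 or 3 channels")
  png_write_cpp(path, as.integer(round(as.numeric(image) * 255)),
                d[1], d[2], d[3])
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  r <- png_read_cpp(path)
  if (r$channels != 1)
    stopf("mask PNG '%s' must be 8-bit grayscale, got %d channels",
          path, r$channels)
  v <- r$data
  if (!all(v %in% c(0L, 255L)))
    stopf("mask PNG '%s' contains values other than 0/255", path)
  matrix(as.integer(v == 255L), r$height, r$width)
}

#' @rdname read_image
#' @export
write_mask <- function(mask, path) {
  mask <- assert_binary_mask(mask)
  png_write_cpp(path, as.integer(mask * 255L), nrow(mask), ncol(mask), 1L)
  invisible(path)
}

# ---- minimal multi-page 32-bit float TIFF (little-endian, uncompressed) ----

#' Read and write perfusion frames as 32-bit float TIFF
#'
#' Multi-page, uncompressed, little-endian TIFF with one grayscale
#' float32 page per frame -- the interchange format for perfusion-map
#' sequences.
#'
#' @param frames list of numeric matrices (equal shapes).
#' @param path file path.
#' @return `read_frames` returns a list of matrices.
#' @export
write_frames <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, all(vapply(frames, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count); w32(value)
  }
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  # layout: header(8) | per page: pixel data, then its IFD
  nbytes <- vapply(frames, function(f) 4 * length(f), numeric(1))
  page_bytes <- nbytes + ifd_size
  data_off <- 8 + cumsum(c(0, page_bytes[-length(page_bytes)]))
  ifd_off <- data_off + nbytes
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42)
  w32(ifd_off[1])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    H <- nrow(f); W <- ncol(f)
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")  # row-major
    w16(n_tags)
    tag(256, 4, 1, W)               # ImageWidth
    tag(257, 4, 1, H)               # ImageLength
    tag(258, 3, 1, 32)              # BitsPerSample
    tag(259, 3, 1, 1)               # Compression: none
    tag(262, 3, 1, 1)               # Photometric: BlackIsZero
    tag(273, 4, 1, data_off[i])     # StripOffsets
    tag(277, 3, 1, 1)               # SamplesPerPixel
    tag(278, 4, 1, H)               # RowsPerStrip
    tag(279, 4, 1, nbytes[i])       # StripByteCounts
    tag(339, 3, 1, 3)               # SampleFormat: IEEE float
    w32(if (i == length(frames)) 0 else ifd_off[i + 1])
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stopf("'%s' is not a little-endian TIFF", path)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2) != 42) stopf("'%s' is not a TIFF file", path)
  ifd <- u32(4)
  frames <- list()
  while (ifd != 0) {
    nt <- u16(ifd)
    tags <- list()
    for (j in seq_len(nt)) {
      off <- ifd + 2 + (j - 1) * 12
      tags[[as.character(u16(off))]] <- u32(off + 8)
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    if (is.null(W) || is.null(H)) stopf("TIFF page missing dimensions")
    if (is.null(tags[["258"]]) || tags[["258"]] != 32 ||
        is.null(tags[["339"]]) || tags[["339"]] != 3)
      stopf("only 32-bit float TIFF pages are supported")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stopf("compressed TIFF is not supported")
    doff <- tags[["273"]]
    vals <- readBin(raw[(doff + 1):(doff + 4 * H * W)], "numeric",
                    n = H * W, size = 4, endian = "little")
    frames[[length(frames) + 1]] <- matrix(vals, H, W, byrow = TRUE)
    ifd <- u32(ifd + 2 + nt * 12)
  }
  frames
}

# ---- CSV tables with a provenance comment line ----

#' Write / read a results table with a provenance header
#'
#' Comma-separated UTF-8 with a leading `#` provenance comment recording
#' the package version, a config hash and the seed, so every artifact is
#' reproducible from (inputs, config, seed).
#'
#' @param df data frame.
#' @param path file path.
#' @param provenance named list recorded in the header comment.
#' @return `read_results` returns the data frame.
#' @export
write_results <- function(df, path, provenance = list()) {
  prov <- c(list(package = paste0("vascam ",
                                  as.character(utils::packageVersion("vascam")))),
            provenance)
  hdr <- paste0("# ", paste(names(prov), unlist(prov), sep = "=",
                            collapse = " | "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- vessel tree JSON sidecars ----

#' Write / read a vessel tree as a JSON sidecar
#'
#' @param tree a `vascam_tree`.
#' @param path file path.
#' @return `read_tree_json` returns the `vascam_tree`.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    canvas = tree$canvas,
    diameter_range = tree$diameter_range,
    seed = if (is.null(tree$seed)) NULL else tree$seed,
    branch_points = tree$branch_points,
    segments = lapply(tree$segments, function(s)
      list(id = s$id, radius = s$radius, depth = s$depth, deep = s$deep,
           x = s$xy[, 1], y = s$xy[, 2]))
  )
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = 8, null = "null")),
             path)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  segs <- lapply(seq_len(nrow(obj$segments)), function(i) {
    s <- obj$segments[i, ]
    list(id = as.integer(s$id), xy = cbind(s$x[[1]], s$y[[1]]),
         radius = s$radius, depth = as.integer(s$depth), deep = s$deep)
  })
  bp <- obj$branch_points
  if (length(bp) == 0 || is.null(nrow(bp)) || nrow(bp) == 0)
    bp <- data.frame(x = numeric(0), y = numeric(0), deep = logical(0))
  structure(list(segments = segs, branch_points = bp,
                 canvas = as.integer(obj$canvas),
                 diameter_range = obj$diameter_range,
                 seed = obj$seed),
            class = "vascam_tree")
}
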