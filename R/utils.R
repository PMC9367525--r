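# internal helpers shared across modules

# Run `code` under a fixed seed when one is given, otherwise use the
# current RNG stream (so a caller may seed once for a whole sample).
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

clamp01 <- function(x) {  # keeps dim attributes, unlike pmin/pmax(0, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# md5 of the JSON serialization of a config-like list; used for provenance
hash_obj <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE,
                         null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# 90 degree counter-clockwise rotation of a matrix
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rot90_k <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- rot90_ccw(m)
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_binary_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask)) stopf("%s must be a matrix", arg)
  if (!all(mask %in% c(0, 1)))
    stopf("%s must be binary (0/1); got other values", arg)
  storage.mode(mask) <- "integer"
  mask
}
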