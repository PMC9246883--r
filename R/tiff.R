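# Minimal baseline-TIFF I/O (uncompressed grayscale, multi-page), enough for
# the video and library bundles this package exchanges. No R TIFF bindings
# are assumed; only little-endian files with one strip per page are written,
# and only uncompressed single-sample pages are read.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_counts = 279L, sample_format = 339L)

#' Write a grayscale image stack as a multi-page TIFF
#'
#' @param frames A list of numeric matrices (rows = y, columns = x) with
#'   intensities in \[0, 1\], or a single matrix.
#' @param path Output file path.
#' @param bits Bit depth, 8 or 16 (default 16).
#' @export
write_tiff_stack <- function(frames, path, bits = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL)
  w2(42L)
  w4(8L)                                    # first IFD right after header
  pos <- 8L
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  maxval <- 2^bits - 1
  for (i in seq_along(frames)) {
    img <- frames[[i]]
    h <- nrow(img); w <- ncol(img)
    nbytes <- h * w * (bits / 8L)
    data_off <- pos + ifd_size
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    w2(n_entries)
    entry(TIFF_TAGS[["width"]], 3L, 1L, w)
    entry(TIFF_TAGS[["length"]], 3L, 1L, h)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)   # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off)
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, h)
    entry(TIFF_TAGS[["strip_counts"]], 4L, 1L, nbytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    next_ifd <- if (i < length(frames)) data_off + nbytes else 0L
    w4(next_ifd)
    vals <- as.integer(round(clamp01(t(img)) * maxval))  # row-major pixel order
    writeBin(vals, con, size = bits / 8L, endian = "little")
    pos <- data_off + nbytes
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a list of matrices
#'
#' Supports the uncompressed single-sample files written by
#' [write_tiff_stack()] (and equivalent files from other tools). Intensities
#' are rescaled to \[0, 1\].
#'
#' @param path TIFF file path.
#' @return List of numeric matrices.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stopf("TIFF file not found: %s", path)
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stopf("not a TIFF file: %s", path)
  rd <- function(off, size, n = 1L)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = (size == 4L))  # unsigned reads only for size <= 2
  if (rd(2, 2) != 42L) stopf("not a TIFF file: %s", path)
  ifd_off <- rd(4, 4)
  frames <- list()
  while (ifd_off != 0L) {
    n_ent <- rd(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd(base, 2)
      type <- rd(base + 2, 2)
      count <- rd(base + 4, 4)
      val <- if (type == 3L) rd(base + 8, 2) else rd(base + 8, 4)
      if (count > 1L && type == 4L) {           # offset to LONG array
        val <- rd(rd(base + 8, 4), 4, n = count)
      } else if (count > 1L && type == 3L) {
        val <- if (count <= 2L) rd(base + 8, 2, n = count) else
          rd(rd(base + 8, 4), 2, n = count)
      }
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF page missing required tag %s", tag)
        default
      } else v
    }
    if (need("compression", 1L)[1] != 1L) stopf("only uncompressed TIFF supported")
    w <- need("width")[1]; h <- need("length")[1]
    bits <- need("bits", 8L)[1]
    if (!bits %in% c(8L, 16L)) stopf("only 8/16-bit grayscale TIFF supported")
    offs <- need("strip_offsets")
    cnts <- need("strip_counts")
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw_all[(offs[i] + 1):(offs[i] + cnts[i])]))
    vals <- readBin(bytes, "integer", n = w * h, size = bits / 8L,
                    endian = endian, signed = FALSE)
    frames[[length(frames) + 1L]] <- t(matrix(vals / (2^bits - 1), nrow = w, ncol = h))
    ifd_off <- rd(ifd_off + 2L + n_ent * 12L, 4)
  }
  frames
}
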