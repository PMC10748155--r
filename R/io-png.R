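#' Write an 8-bit grayscale PNG
#'
#' Minimal encoder for the single-channel page renders produced by the
#' synthetic cohort generator: color type 0, bit depth 8, no interlacing,
#' scanline filter "None" throughout (deterministic byte stream).
#'
#' @param pixels integer matrix of intensities in 0..255; rows are image rows
#'   (row 1 = top of the page).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png_gray <- function(pixels, path) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  px <- as.integer(pixels)
  if (anyNA(px) || any(px < 0L | px > 255L))
    stopf("pixel intensities must be integers in 0..255")
  h <- nrow(pixels); w <- ncol(pixels)
  be32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(be32(length(data)), body, be32(crc32_raw(body)))
  }
  ihdr <- c(be32(w), be32(h), as.raw(c(8L, 0L, 0L, 0L, 0L)))
  # filter byte 0 in front of each row; rows are top-to-bottom
  scan <- matrix(0L, nrow = w + 1L, ncol = h)
  scan[-1L, ] <- matrix(px, nrow = h, ncol = w, byrow = FALSE) |> t()
  raw_scan <- as.raw(scan)
  idat <- memCompress(raw_scan, "gzip")   # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' Companion decoder to [write_png_gray()]: supports color type 0, bit depth
#' 8, scanline filters None/Sub/Up.
#'
#' @param path PNG file path.
#' @return integer matrix of intensities (rows = image rows, top first).
#' @export
read_png_gray <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(raw[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stopf("%s: not a PNG file", path)
  u32 <- function(i) sum(as.integer(raw[i:(i + 3)]) * c(16777216, 65536, 256, 1))
  pos <- 9L
  w <- h <- NULL
  idat <- list()
  while (pos <= length(raw)) {
    len <- u32(pos)
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    data_at <- pos + 8L
    if (type == "IHDR") {
      w <- u32(data_at); h <- u32(data_at + 4L)
      depth <- as.integer(raw[data_at + 8L])
      ctype <- as.integer(raw[data_at + 9L])
      if (depth != 8L || ctype != 0L)
        stopf("%s: only 8-bit grayscale PNG supported", path)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- raw[data_at:(data_at + len - 1L)]
    } else if (type == "IEND") break
    pos <- data_at + len + 4L
  }
  bytes <- as.integer(memDecompress(do.call(c, idat), "gzip"))
  stride <- w + 1L
  if (length(bytes) != stride * h) stopf("%s: corrupt scanline data", path)
  rows <- matrix(bytes, nrow = stride, ncol = h)
  img <- matrix(0L, nrow = h, ncol = w)
  prev <- integer(w)
  for (r in seq_len(h)) {
    filt <- rows[1L, r]
    line <- rows[-1L, r]
    if (filt == 1L) {          # Sub
      for (i in 2:w) line[i] <- (line[i] + line[i - 1L]) %% 256L
    } else if (filt == 2L) {   # Up
      line <- (line + prev) %% 256L
    } else if (filt != 0L) stopf("%s: unsupported PNG filter %d", path, filt)
    img[r, ] <- line
    prev <- line
  }
  img
}
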