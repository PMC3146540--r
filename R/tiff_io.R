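# Minimal baseline-TIFF codec for 16-bit grayscale images.
#
# No TIFF library is required at runtime: the package writes uncompressed,
# little-endian, single-strip baseline TIFF and reads back exactly that
# subset (which covers everything the synthetic generators produce and what
# standard viewers/ImageJ open without fuss). It is an edge adapter: the
# analysis pipeline itself operates on in-memory integer matrices.

#' Write a 16-bit grayscale TIFF
#'
#' @param image integer or numeric matrix, values in \[0, 65535\];
#'   rows are image rows (y), columns are x.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  v <- round(image)
  storage.mode(v) <- "integer"
  if (anyNA(v) || any(v < 0L) || any(v > 65535L))
    stop("image values must be finite and within [0, 65535]", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little endian
  writeBin(c(42L), con, size = 2, endian = "little")   # magic
  writeBin(8L, con, size = 4, endian = "little")       # IFD offset
  tags <- list( # tag id, type (3 = SHORT, 4 = LONG), value
    c(256L, 4L, w),             # ImageWidth
    c(257L, 4L, h),             # ImageLength
    c(258L, 3L, 16L),           # BitsPerSample
    c(259L, 3L, 1L),            # Compression: none
    c(262L, 3L, 1L),            # Photometric: BlackIsZero
    c(273L, 4L, 0L),            # StripOffsets (patched below)
    c(277L, 3L, 1L),            # SamplesPerPixel
    c(278L, 4L, h),             # RowsPerStrip: single strip
    c(279L, 4L, 2L * w * h)     # StripByteCounts
  )
  data_offset <- 8L + 2L + length(tags) * 12L + 4L
  tags[[6]][3] <- data_offset
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT padded to 4 bytes
      writeBin(tg[3], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[3], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  # pixel data, row-major
  writeBin(as.integer(t(v)), con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff()]
#'
#' Supports the uncompressed little-endian single-strip subset this package
#' writes; anything else is rejected with an informative error.
#'
#' @param path file path.
#' @return integer matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 2)
  if (!identical(rawToChar(hdr), "II"))
    stop("unsupported TIFF: not little-endian", call. = FALSE)
  magic <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (magic != 42L) stop("not a TIFF file", call. = FALSE)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, ifd_off)
  ntags <- readBin(con, "integer", 1, size = 2, endian = "little")
  fields <- list()
  for (i in seq_len(ntags)) {
    id <- readBin(con, "integer", 1, size = 2, endian = "little")
    type <- readBin(con, "integer", 1, size = 2, endian = "little")
    readBin(con, "integer", 1, size = 4, endian = "little") # count (1)
    val <- if (type == 3L) {
      x <- readBin(con, "integer", 1, size = 2, endian = "little",
                   signed = FALSE)
      readBin(con, "integer", 1, size = 2, endian = "little")
      x
    } else {
      readBin(con, "integer", 1, size = 4, endian = "little")
    }
    fields[[as.character(id)]] <- val
  }
  need <- function(id) {
    v <- fields[[as.character(id)]]
    if (is.null(v)) stop("unsupported TIFF: missing tag ", id, call. = FALSE)
    v
  }
  if (need(259L) != 1L) stop("unsupported TIFF: compressed", call. = FALSE)
  if (need(258L) != 16L) stop("unsupported TIFF: not 16-bit", call. = FALSE)
  w <- need(256L); h <- need(257L)
  seek(con, need(273L))
  px <- readBin(con, "integer", w * h, size = 2, endian = "little",
                signed = FALSE)
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
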