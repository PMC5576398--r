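#' @include patch-imaging.R
NULL

#' Read and write patch images as PNG
#'
#' Grayscale PNG round-trip for [PatchImage-class] objects. The dpi is
#' stored in (and recovered from) the PNG resolution metadata when
#' available.
#'
#' @param image a [PatchImage-class].
#' @param path file path.
#' @param dpi fallback resolution when the file carries none.
#' @return \code{writePatchPng}: the path, invisibly;
#'   \code{readPatchPng}: a [PatchImage-class].
#' @export
writePatchPng <- function(image, path) {
  stopifnot(is(image, "PatchImage"))
  png::writePNG(image@pixels, target = path, dpi = image@dpi)
  invisible(path)
}

#' @rdname writePatchPng
#' @export
readPatchPng <- function(path, dpi = 1200) {
  px <- png::readPNG(path, info = TRUE)
  info <- attr(px, "info")
  if (!is.null(info) && !is.null(info$dpi) && all(is.finite(info$dpi)))
    dpi <- mean(info$dpi)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # first channel of RGB(A)
  patchImage(matrix(as.numeric(px), nrow(px), ncol(px)), dpi)
}

# Minimal uncompressed 24-bit BMP codec ("bitmap format"). Grayscale is
# stored as equal B, G, R bytes; rows are bottom-up and padded to 4-byte
# boundaries; resolution is carried in pixels-per-meter header fields.

#' Read and write patch images as BMP
#'
#' Uncompressed 24-bit Windows BMP ("bitmap format", as used for film
#' scans). Intensities are written as 8-bit gray; the dpi is stored in
#' the BMP pixels-per-meter fields and recovered on read.
#'
#' @param image a [PatchImage-class].
#' @param path file path.
#' @param dpi fallback resolution when the file header carries none.
#' @return \code{writePatchBmp}: the path, invisibly;
#'   \code{readPatchBmp}: a [PatchImage-class].
#' @export
writePatchBmp <- function(image, path) {
  stopifnot(is(image, "PatchImage"))
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  rowBytes <- w * 3L
  pad <- (4L - rowBytes %% 4L) %% 4L
  imgSize <- (rowBytes + pad) * h
  ppm <- as.integer(round(image@dpi / 25.4 * 1000))
  gray <- matrix(as.integer(round(pmin(pmax(px, 0), 1) * 255)), h, w)

  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  writeBin(as.raw(c(0x42, 0x4d)), con)          # "BM"
  wInt(54L + imgSize, 4L)                        # file size
  wInt(0L, 4L)                                   # reserved
  wInt(54L, 4L)                                  # pixel data offset
  wInt(40L, 4L)                                  # BITMAPINFOHEADER size
  wInt(w, 4L); wInt(h, 4L)                       # width, height (bottom-up)
  wInt(1L, 2L); wInt(24L, 2L)                    # planes, bits per pixel
  wInt(0L, 4L); wInt(imgSize, 4L)                # no compression, data size
  wInt(ppm, 4L); wInt(ppm, 4L)                   # x, y pixels per meter
  wInt(0L, 4L); wInt(0L, 4L)                     # palette fields
  padRaw <- as.raw(rep(0L, pad))
  for (i in h:1) {                               # bottom row first
    g <- as.raw(gray[i, ])
    writeBin(c(as.raw(as.vector(rbind(g, g, g))), padRaw), con)
  }
  invisible(path)
}

#' @rdname writePatchBmp
#' @export
readPatchBmp <- function(path, dpi = 1200) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(size, signed = TRUE)
    readBin(con, "integer", 1L, size = size, signed = signed,
            endian = "little")
  magic <- readBin(con, "raw", 2L)
  if (!identical(magic, as.raw(c(0x42, 0x4d))))
    stop("not a BMP file: ", path, call. = FALSE)
  invisible(rInt(4L)); invisible(rInt(4L))
  offset <- rInt(4L)
  headerSize <- rInt(4L)
  if (headerSize < 40L)
    stop("unsupported BMP header (size ", headerSize, ")", call. = FALSE)
  w <- rInt(4L); hRaw <- rInt(4L)
  topDown <- hRaw < 0L
  h <- abs(hRaw)
  invisible(rInt(2L))
  bpp <- rInt(2L, signed = FALSE)
  compression <- rInt(4L)
  if (bpp != 24L || compression != 0L)
    stop("only uncompressed 24-bit BMP is supported", call. = FALSE)
  invisible(rInt(4L))
  ppmX <- rInt(4L)
  if (ppmX > 0) dpi <- ppmX * 25.4 / 1000
  seek(con, offset)
  rowBytes <- w * 3L
  pad <- (4L - rowBytes %% 4L) %% 4L
  px <- matrix(0, h, w)
  for (r in seq_len(h)) {
    bytes <- readBin(con, "raw", rowBytes + pad)
    i <- if (topDown) r else h - r + 1L
    px[i, ] <- as.integer(bytes[seq(1L, rowBytes, by = 3L)]) / 255
  }
  patchImage(px, dpi)
}
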