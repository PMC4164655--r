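# Image reading and writing: PNG and TIFF through the png/tiff packages,
# PGM (both ASCII P2 and binary P5, 8- and 16-bit) parsed directly since no
# installed package reads portable graymaps.

readPgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens: magic, width, height, maxval (comments skipped)
  buf <- character(0)
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM header in ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tok <- c(tok, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (mx < 256) {
    as.integer(readBin(con, "integer", n = n, size = 1, signed = FALSE))
  } else {
    readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated PGM pixel data in ", path)
  GrayImage(matrix(vals / mx, h, w, byrow = TRUE),
            bitDepth = if (mx < 256) 8L else 16L)
}

#' Read a grayscale image
#'
#' Supports PGM (P2/P5), PNG and TIFF, 8- or 16-bit. Multichannel images
#' are accepted only when all channels are identical (or with an alpha
#' channel, which is dropped); values are mapped to `[0, 1]` and the source
#' bit depth kept as provenance.
#'
#' @param path file path; format inferred from the extension.
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(readPgm(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path))
  depth <- attr(arr, "bitdepth")
  if (is.null(depth)) depth <- 8L
  if (length(dim(arr)) == 3) {
    ch <- dim(arr)[3]
    rgb <- arr[, , 1:min(ch, 3), drop = FALSE]
    if (ch >= 3 && (max(abs(rgb[, , 1] - rgb[, , 2])) > 0 ||
                    max(abs(rgb[, , 1] - rgb[, , 3])) > 0))
      stop("ambiguous multichannel image (channels differ): ", path)
    arr <- arr[, , 1]
  }
  GrayImage(arr, bitDepth = as.integer(depth))
}

#' Write a grayscale image
#'
#' PGM output is binary P5 at the requested bit depth; PNG output goes
#' through the png package.
#'
#' @param image a [GrayImage-class] with values in `[0, 1]`.
#' @param path output path ending in .pgm or .png.
#' @param bitDepth 8 or 16; defaults to the image's provenance (or 8).
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path, bitDepth = NULL) {
  m <- image@.Data
  if (min(m) < 0 || max(m) > 1)
    stop("image values must lie in [0, 1] for writing")
  if (is.null(bitDepth))
    bitDepth <- if (is.na(image@bitDepth)) 8L else image@bitDepth
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext == "pgm") {
    mx <- 2L^bitDepth - 1L
    vals <- as.integer(round(t(m) * mx))   # row-major pixel order
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(m), nrow(m), mx), con,
              eos = NULL)
    writeBin(vals, con, size = if (bitDepth <= 8) 1 else 2, endian = "big")
  } else stop("unsupported output format: ", ext)
  invisible(path)
}

#' Crop a rectangular region of interest
#'
#' @param image a [GrayImage-class].
#' @param roi integer(4): `x0, y0, width, height`, 0-based, half-open.
#' @param minSide minimum accepted side after cropping (default 256, the
#'   inclusion rule for lesion analysis); set 0 to override.
#' @return a [GrayImage-class].
#' @export
cropRoi <- function(image, roi, minSide = 256) {
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image))
    stop("ROI extends outside the image")
  if (w < minSide || h < minSide)
    stop(sprintf("ROI %dx%d below the minimum side %d", w, h, minSide))
  GrayImage(image@.Data[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)],
            bitDepth = image@bitDepth)
}
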