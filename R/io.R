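# Image input/output: PNG, TIFF and PGM readers (grayscale; RGB converted to
# luminance), PNG mask writer, contour CSV export.

#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM files into a numeric matrix `[row, col]`. Colour
#' images are converted to grayscale by Rec. 601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`); an alpha channel is dropped. Integer-coded
#' PNG files are rescaled to the 0-255 gray-value scale regardless of bit
#' depth; TIFF files are returned in their native values (integer or float);
#' PGM values are returned as stored.
#'
#' @param path file path; format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return numeric matrix of intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  to_gray_matrix(img)
}

to_gray_matrix <- function(img) {
  if (is.matrix(img)) return(img + 0)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    if (nch >= 3L)
      return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
    return(img[, , 1L] + 0)  # gray (+alpha)
  }
  stop("unsupported image layout")
}

# Minimal PGM (P2 ascii / P5 binary) reader; values returned as stored.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with '#' comments allowed
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1L]
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (!magic %in% c("P2", "P5") || anyNA(c(w, h, maxval)) || w < 1L ||
      h < 1L || maxval < 1L)
    stop("not a valid PGM file: ", path)
  npx <- w * h
  vals <- if (magic == "P5") {
    size <- if (maxval > 255L) 2L else 1L
    v <- readBin(con, "integer", n = npx, size = size, signed = FALSE,
                 endian = "big")
    if (length(v) < npx) stop("truncated PGM pixel data")
    v
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    rest <- gsub("#[^\n]*", " ", rest)
    v <- suppressWarnings(as.integer(strsplit(trimws(rest),
                                              "[[:space:]]+")[[1L]]))
    if (length(v) < npx || anyNA(v[seq_len(npx)]))
      stop("truncated PGM pixel data")
    v[seq_len(npx)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Background pixels are written as 0, foreground as 255.
#'
#' @param mask binary matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG((mask != 0) * 1.0, path)
  invisible(path)
}

#' Write phantom / gray images as 8-bit PNG
#'
#' Intensities are clamped to `[0, 255]` and quantised to 8 bit.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gray_png <- function(image, path) {
  check_image(image)
  img <- round(pmin(pmax(image, 0), 255)) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Export a contour as CSV
#'
#' One `(x, y)` row per contour point, in ray order.
#'
#' @param contour `n x 2` matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L)
  df <- data.frame(x = contour[, 1L], y = contour[, 2L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
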