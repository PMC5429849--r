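# Cut vector -> contour polygon -> binary mask, plus collapse detection.

#' Convert a cut vector into contour points
#'
#' For ray `r` with `k[r] >= 1` the boundary point is placed at radial
#' distance midway between the last lesion-side node and the first
#' tissue-side node (i.e. `(k[r] + 0.5) * radius / L`), capped at the
#' template radius when `k[r] = L`; the midpoint is unbiased between the last
#' inside and first outside sample. For `k[r] = 0` the boundary point is the
#' seed itself (collapsed ray).
#'
#' @param k a `cut_vector` object or integer vector of per-ray cut levels.
#' @param template the [build_template()] object the cut was computed on.
#' @return `R x 2` matrix of `(x, y)` contour points in ray (clockwise)
#'   order.
#' @export
cut_to_contour <- function(k, template) {
  if (inherits(k, "cut_vector")) k <- k$k
  stopifnot(inherits(template, "circular_template"))
  if (length(k) != template$R)
    stop("length of 'k' must equal the number of template rays")
  if (any(k < 0 | k > template$L))
    stop("cut levels must lie in 0..L")
  dist <- ifelse(k == 0, 0,
                 pmin(k + 0.5, template$L) * template$radius / template$L)
  cbind(x = template$seed[1L] + dist * cos(template$angles),
        y = template$seed[2L] + dist * sin(template$angles))
}

#' Rasterise a closed contour polygon into a binary mask
#'
#' The contour points are treated as a closed polygon in ray order and filled
#' with the standard even-odd scanline rule (half-open in both axes, so a
#' square of side `s` covers exactly `s^2` pixel centres); the result is
#' clipped to the image bounds. Fewer than 3 distinct points give an empty
#' mask.
#'
#' @param contour `n x 2` matrix of `(x, y)` polygon vertices.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return integer matrix of 0/1, dimensions `dim`.
#' @export
contour_to_mask <- function(contour, dim) {
  stopifnot(is.matrix(contour), ncol(contour) == 2L, length(dim) == 2L)
  nr <- as.integer(dim[1L]); nc <- as.integer(dim[2L])
  mask <- matrix(0L, nr, nc)
  pts <- unique(round(contour, 9))
  if (nrow(pts) < 3L) return(mask)

  px <- contour[, 1L]; py <- contour[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  y_lo <- max(0L, floor(min(py)))
  y_hi <- min(nr - 1L, ceiling(max(py)))
  if (y_hi < y_lo) return(mask)
  for (y in y_lo:y_hi) {
    crosses <- (py <= y & qy > y) | (qy <= y & py > y)
    if (!any(crosses)) next
    xc <- px[crosses] +
      (y - py[crosses]) * (qx[crosses] - px[crosses]) /
      (qy[crosses] - py[crosses])
    xc <- sort(xc)
    for (j in seq(1L, length(xc) - 1L, by = 2L)) {
      x0 <- ceiling(xc[j] - 1e-9)
      x1 <- ceiling(xc[j + 1L] - 1e-9) - 1L
      x0 <- max(x0, 0L); x1 <- min(x1, nc - 1L)
      if (x1 >= x0) mask[y + 1L, (x0:x1) + 1L] <- 1L
    }
  }
  mask
}
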