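# Evaluation metrics: Dice similarity coefficient and Hausdorff distance
# between binary masks, with boundary extraction at pixel level.

check_mask <- function(m, name = "mask") {
  if (!is.matrix(m) || !(is.numeric(m) || is.logical(m)))
    stop(sprintf("'%s' must be a numeric or logical matrix", name))
  v <- as.numeric(m)
  if (any(!v %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (values 0/1)", name))
  invisible(TRUE)
}

check_mask_pair <- function(a, ref) {
  check_mask(a, "a"); check_mask(ref, "ref")
  if (!all(dim(a) == dim(ref)))
    stop("masks must have identical dimensions")
  invisible(TRUE)
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A n R| / (|A| + |R|)` with `|.|` the foreground pixel count:
#' the relative overlap between an algorithmic and a reference segmentation,
#' 1 for identical masks and 0 for disjoint ones.
#'
#' @param a,ref binary matrices of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, ref) {
  check_mask_pair(a, ref)
  na <- sum(a != 0); nr <- sum(ref != 0)
  if (na + nr == 0L)
    stop("Dice coefficient is undefined for two empty masks")
  2 * sum(a != 0 & ref != 0) / (na + nr)
}

#' Boundary pixel centres of a binary mask
#'
#' A boundary pixel is a foreground pixel with at least one background
#' 4-neighbour, or a foreground pixel on the image edge.
#'
#' @param mask binary matrix.
#' @return `n x 2` matrix of `(x, y)` coordinates (0-based pixel centres).
#' @export
mask_boundary_points <- function(mask) {
  check_mask(mask)
  fg <- mask != 0
  nr <- nrow(fg); nc <- ncol(fg)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up <- pad[1:nr, 2:(nc + 1L)]
  dn <- pad[3:(nr + 2L), 2:(nc + 1L)]
  lf <- pad[2:(nr + 1L), 1:nc]
  rt <- pad[2:(nr + 1L), 3:(nc + 2L)]
  bnd <- core & !(up & dn & lf & rt)
  idx <- which(bnd, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Directed Hausdorff distance between two point sets
#'
#' `h(A, B) = max over a in A of min over b in B of ||a - b||`: the worst
#' nearest-neighbour Euclidean distance from the first set into the second.
#' Not symmetric.
#'
#' @param a,b `n x 2` matrices of point coordinates (both non-empty).
#' @return scalar distance (same units as the coordinates).
#' @export
directed_hausdorff <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 2L, ncol(b) == 2L)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("point sets must be non-empty")
  # all-pairs squared distances, chunked over 'a' to bound memory
  worst <- 0
  step <- max(1L, floor(2e6 / nrow(b)))
  for (start in seq(1L, nrow(a), by = step)) {
    ii <- start:min(start + step - 1L, nrow(a))
    d2 <- outer(a[ii, 1L], b[, 1L], "-")^2 +
      outer(a[ii, 2L], b[, 2L], "-")^2
    worst <- max(worst, max(apply(d2, 1L, min)))
  }
  sqrt(worst)
}

#' Hausdorff distance between two binary masks
#'
#' Symmetric Hausdorff distance `H(A, R) = max(h(A, R), h(R, A))` of the
#' boundary pixel centres of the two masks (see [mask_boundary_points()]),
#' reported in pixels.
#'
#' @inheritParams dice
#' @return scalar distance in pixels.
#' @export
hausdorff_distance <- function(a, ref) {
  check_mask_pair(a, ref)
  if (sum(a != 0) == 0L || sum(ref != 0) == 0L)
    stop("Hausdorff distance is undefined for an empty mask")
  pa <- mask_boundary_points(a)
  pr <- mask_boundary_points(ref)
  max(directed_hausdorff(pa, pr), directed_hausdorff(pr, pa))
}

#' Per-case and aggregate evaluation of predicted vs reference masks
#'
#' Computes Dice and Hausdorff distance for every mask pair. An empty
#' prediction against a non-empty reference is recorded with `dsc = 0` and
#' `hd_pixels = NA` (the Hausdorff distance is undefined there); such cases
#' are excluded from the aggregate HD mean/sd but flagged in the result.
#'
#' @param pred,ref lists of binary matrices (paired by position).
#' @param case_id optional character vector of case labels.
#' @return `data.frame` with columns `case_id`, `dsc`, `hd_pixels`,
#'   `area_pred_px`, `area_ref_px`, `empty_pred`; aggregate means/sds are
#'   attached as attribute `"aggregate"`.
#' @export
evaluate_masks <- function(pred, ref, case_id = NULL) {
  stopifnot(is.list(pred), is.list(ref))
  if (length(pred) != length(ref))
    stop("'pred' and 'ref' must have the same length")
  n <- length(pred)
  if (n == 0L) stop("no mask pairs to evaluate")
  if (is.null(case_id)) case_id <- sprintf("case_%03d", seq_len(n))

  rows <- lapply(seq_len(n), function(i) {
    p <- pred[[i]]; r <- ref[[i]]
    check_mask_pair(p, r)
    empty_pred <- sum(p != 0) == 0L
    data.frame(
      case_id = case_id[i],
      dsc = if (empty_pred) 0 else dice(p, r),
      hd_pixels = if (empty_pred) NA_real_ else hausdorff_distance(p, r),
      area_pred_px = sum(p != 0),
      area_ref_px = sum(r != 0),
      empty_pred = empty_pred)
  })
  out <- do.call(rbind, rows)
  hd_ok <- out$hd_pixels[!is.na(out$hd_pixels)]
  attr(out, "aggregate") <- data.frame(
    dsc_mean = mean(out$dsc), dsc_sd = sd(out$dsc),
    hd_mean = if (length(hd_ok)) mean(hd_ok) else NA_real_,
    hd_sd = if (length(hd_ok) > 1L) sd(hd_ok) else NA_real_,
    n = n, n_empty_pred = sum(out$empty_pred))
  out
}
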