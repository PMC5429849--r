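# Circular ray template: seed-centred geometry along which graph nodes are
# sampled, plus intensity sampling (bilinear) and the seed-region average.

#' Build a seed-centred circular ray template
#'
#' Constructs the geometric scaffold of the segmentation graph: `rays` ray
#' directions distributed equidistantly and clockwise (screen coordinates,
#' y down) starting at angle 0 (east), with `nodes` sample positions per ray.
#' Node `i` (0-based) lies at distance `(i + 1) * radius / nodes` from the
#' seed, so the innermost node is offset from the seed and the outermost node
#' sits exactly on the template circle. The seed itself is never a node: it
#' only contributes the reference region statistic (see [seed_average()]).
#'
#' Construction is pure geometry; node positions may fall outside the image,
#' clamping to the image border happens later in [sample_rays()].
#'
#' @param seed numeric length-2, `(x, y)` pixel coordinate of the seed
#'   (0-based, origin top-left).
#' @param radius template radius in pixels (> 0).
#' @param rays number of rays `R` (integer >= 3).
#' @param nodes number of nodes per ray `L` (integer >= 2).
#' @return An object of class `circular_template`: a list with elements
#'   `seed`, `radius`, `R`, `L`, `angles` (length `R`, radians) and
#'   `node_x`, `node_y` (`R x L` matrices of continuous positions).
#' @examples
#' tpl <- build_template(c(50, 50), radius = 9, rays = 4, nodes = 3)
#' tpl$node_x[1, 1]  # ray 0 (east), innermost node: x = 53
#' @export
build_template <- function(seed, radius, rays = 60L, nodes = 40L) {
  if (!is.numeric(seed) || length(seed) != 2L || !all(is.finite(seed)))
    stop("'seed' must be a finite numeric (x, y) pair")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("'radius' must be a single positive number")
  rays <- as.integer(rays)
  nodes <- as.integer(nodes)
  if (is.na(rays) || rays < 3L) stop("'rays' must be an integer >= 3")
  if (is.na(nodes) || nodes < 2L) stop("'nodes' must be an integer >= 2")

  angles <- 2 * pi * (seq_len(rays) - 1L) / rays
  dists <- seq_len(nodes) * radius / nodes
  # y grows downwards, so +sin turns ray order clockwise on screen
  node_x <- seed[1L] + outer(cos(angles), dists)
  node_y <- seed[2L] + outer(sin(angles), dists)

  structure(
    list(seed = as.numeric(seed), radius = as.numeric(radius),
         R = rays, L = nodes, angles = angles,
         node_x = node_x, node_y = node_y),
    class = "circular_template")
}

#' @export
print.circular_template <- function(x, ...) {
  cat("Circular ray template\n")
  cat(sprintf("  seed    : (%.2f, %.2f)\n", x$seed[1L], x$seed[2L]))
  cat(sprintf("  radius  : %.2f px\n", x$radius))
  cat(sprintf("  rays R  : %d (angle step %.3f rad, clockwise from east)\n",
              x$R, 2 * pi / x$R))
  cat(sprintf("  nodes L : %d per ray (spacing %.3f px)\n",
              x$L, x$radius / x$L))
  invisible(x)
}

# Bilinear interpolation at continuous 0-based (x, y); positions outside the
# image are clamped to the nearest border pixel first.
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- pmin(pmax(x, 0), nc - 1L)
  y <- pmin(pmax(y, 0), nr - 1L)
  x0 <- pmin(floor(x), nc - 2L); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), nr - 2L); y0 <- pmax(y0, 0)
  if (nc == 1L) x0 <- rep_len(0, length(x))
  if (nr == 1L) y0 <- rep_len(0, length(y))
  fx <- x - x0
  fy <- y - y0
  i00 <- cbind(y0 + 1L, x0 + 1L)
  i01 <- cbind(y0 + 1L, pmin(x0 + 2L, nc))
  i10 <- cbind(pmin(y0 + 2L, nr), x0 + 1L)
  i11 <- cbind(pmin(y0 + 2L, nr), pmin(x0 + 2L, nc))
  (1 - fy) * ((1 - fx) * image[i00] + fx * image[i01]) +
    fy * ((1 - fx) * image[i10] + fx * image[i11])
}

#' Sample image intensities along template rays
#'
#' One intensity per template node, by bilinear interpolation of the four
#' surrounding pixel centres. Node positions outside the image are clamped
#' to the nearest border pixel before interpolation, so the sample matrix is
#' always complete regardless of where the seed sits.
#'
#' @param image numeric matrix (grayscale image, `[row, col]`).
#' @param template a [build_template()] object.
#' @param seed_avg optional precomputed seed-region average; if `NULL`,
#'   [seed_average()] with `avg_radius` is used.
#' @param avg_radius radius (px) of the seed averaging disc.
#' @return An object of class `ray_samples`: list with `template`,
#'   `gray` (`R x L` matrix) and `seed_avg`.
#' @export
sample_rays <- function(image, template, seed_avg = NULL, avg_radius = 3) {
  check_image(image)
  stopifnot(inherits(template, "circular_template"))
  gray <- matrix(bilinear_sample(image, as.vector(template$node_x),
                                 as.vector(template$node_y)),
                 nrow = template$R, ncol = template$L)
  if (is.null(seed_avg))
    seed_avg <- seed_average(image, template$seed, avg_radius)
  structure(list(template = template, gray = gray,
                 seed_avg = as.numeric(seed_avg)),
            class = "ray_samples")
}

#' Average gray value around the seed point
#'
#' Arithmetic mean of all pixels whose centre lies within Euclidean distance
#' `avg_radius` of the seed; with `avg_radius = 0` this is the seed pixel
#' alone. This local average is the reference intensity from which all node
#' costs are measured.
#'
#' @inheritParams sample_rays
#' @param seed `(x, y)` pixel coordinate, must lie inside the image.
#' @param avg_radius averaging disc radius in pixels (>= 0).
#' @return scalar mean intensity.
#' @export
seed_average <- function(image, seed, avg_radius = 3) {
  check_image(image)
  if (!is.numeric(seed) || length(seed) != 2L || !all(is.finite(seed)))
    stop("'seed' must be a finite numeric (x, y) pair")
  if (seed[1L] < 0 || seed[1L] > ncol(image) - 1L ||
      seed[2L] < 0 || seed[2L] > nrow(image) - 1L)
    stop("seed point lies outside the image")
  if (!is.numeric(avg_radius) || length(avg_radius) != 1L || avg_radius < 0)
    stop("'avg_radius' must be a single number >= 0")

  if (avg_radius == 0)
    return(image[round(seed[2L]) + 1L, round(seed[1L]) + 1L])

  cx <- ceiling(seed[1L] - avg_radius):floor(seed[1L] + avg_radius)
  cy <- ceiling(seed[2L] - avg_radius):floor(seed[2L] + avg_radius)
  cx <- cx[cx >= 0 & cx <= ncol(image) - 1L]
  cy <- cy[cy >= 0 & cy <= nrow(image) - 1L]
  gx <- rep(cx, each = length(cy))
  gy <- rep(cy, times = length(cx))
  keep <- (gx - seed[1L])^2 + (gy - seed[2L])^2 <= avg_radius^2
  if (!any(keep))  # disc smaller than pixel spacing: fall back to seed pixel
    return(image[round(seed[2L]) + 1L, round(seed[1L]) + 1L])
  mean(image[cbind(gy[keep] + 1L, gx[keep] + 1L)])
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L)
    stop("'image' must be a non-empty numeric matrix")
  invisible(TRUE)
}
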