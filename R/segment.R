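# High-level entry point: one seed click -> star-shaped lesion segmentation.

#' Segment a lesion around a seed point
#'
#' Runs the full template-cut pipeline on one seed: build the circular ray
#' template, sample intensities, compute costs and terminal weights, build
#' the s-t graph, solve the minimum cut and convert it into a closed contour
#' and binary mask. The function is deterministic and fast enough to be
#' re-invoked per mouse position, which is how the interactive loop is
#' emulated: sweep the seed, watch the contour.
#'
#' Two situations are reported as a *collapse* (empty mask, contour at the
#' seed): the minimum cut keeps no node on the lesion side, or the canonical
#' minimum cut is the full template (all `k[r] = L`), meaning no intensity
#' boundary was found anywhere inside the template -- both indicate that no
#' star-shaped object surrounds the seed, the intended feedback when
#' hovering homogeneous tissue.
#'
#' @param image numeric matrix (grayscale, `[row, col]`).
#' @param seed `(x, y)` pixel coordinate of the seed (0-based), inside the
#'   image.
#' @param radius template radius in pixels; must exceed the expected lesion
#'   radius.
#' @param rays number of rays `R` (default 60: sub-degree-scale angular
#'   spacing at typical lesion radii while keeping the graph interactive).
#' @param nodes nodes per ray `L` (default 40).
#' @param delta_r smoothness parameter (default 2): maximum cut-level
#'   difference between adjacent rays.
#' @param avg_radius radius of the seed averaging disc (default 3 px).
#' @return An object of class `starcut`: list with `k` (per-ray cut levels;
#'   zeros when collapsed), `cut_cost`, `contour` (`R x 2`), `mask`
#'   (integer 0/1 matrix, image-shaped), `collapsed`, `collapse_reason`
#'   (`"none"`, `"empty"` or `"no_boundary"`), `seed`, `seed_avg`,
#'   `template`, `params`, `elapsed` (seconds).
#' @examples
#' img <- matrix(100, 80, 80)
#' img[outer(0:79, 0:79, function(y, x) (x - 40)^2 + (y - 40)^2 < 15^2)] <- 60
#' fit <- segment_lesion(img, seed = c(40, 40), radius = 30)
#' sum(fit$mask)                        # close to pi * 15^2
#' @export
segment_lesion <- function(image, seed, radius = 60, rays = 60L, nodes = 40L,
                           delta_r = 2L, avg_radius = 3) {
  t0 <- proc.time()[["elapsed"]]
  check_image(image)
  if (seed[1L] < 0 || seed[1L] > ncol(image) - 1L ||
      seed[2L] < 0 || seed[2L] > nrow(image) - 1L)
    stop("seed point lies outside the image")

  template <- build_template(seed, radius, rays, nodes)
  samples <- sample_rays(image, template, avg_radius = avg_radius)
  profile <- compute_costs(samples)
  graph <- build_graph(profile, delta_r)
  cut <- solve_min_cut(graph)

  k <- cut$k
  reason <- "none"
  if (all(k == 0L)) {
    reason <- "empty"
  } else if (all(k == template$L)) {
    # even the full template is a minimum cut: no boundary inside the
    # template at all, so there is nothing star-shaped to outline
    k <- integer(length(k))
    reason <- "no_boundary"
  }
  collapsed <- !is.null(reason) && reason != "none"

  contour <- cut_to_contour(k, template)
  mask <- if (collapsed) matrix(0L, nrow(image), ncol(image)) else
    contour_to_mask(contour, dim(image))

  structure(
    list(k = k, cut_cost = cut$cut_cost, contour = contour, mask = mask,
         collapsed = collapsed, collapse_reason = reason,
         seed = as.numeric(seed), seed_avg = samples$seed_avg,
         template = template,
         params = list(radius = radius, rays = template$R,
                       nodes = template$L, delta_r = as.integer(delta_r),
                       avg_radius = avg_radius),
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "starcut")
}

#' @export
print.starcut <- function(x, ...) {
  cat("Star-shaped template-cut segmentation\n")
  cat(sprintf("  seed (%.1f, %.1f), seed average %.2f\n",
              x$seed[1L], x$seed[2L], x$seed_avg))
  cat(sprintf("  template: radius %.1f px, %d rays x %d nodes, delta_r %d\n",
              x$params$radius, x$params$rays, x$params$nodes,
              x$params$delta_r))
  if (x$collapsed) {
    cat(sprintf("  contour collapsed (%s): no lesion boundary at this seed\n",
                x$collapse_reason))
  } else {
    cat(sprintf("  foreground: %d px, cut cost %.4g\n",
                sum(x$mask), x$cut_cost))
  }
  cat(sprintf("  solved in %.3f s\n", x$elapsed))
  invisible(x)
}

#' @export
summary.starcut <- function(object, ...) {
  rad <- sqrt((object$contour[, 1L] - object$seed[1L])^2 +
              (object$contour[, 2L] - object$seed[2L])^2)
  out <- list(collapsed = object$collapsed,
              collapse_reason = object$collapse_reason,
              area_px = sum(object$mask),
              equivalent_diameter_px = 2 * sqrt(sum(object$mask) / pi),
              boundary_radius = c(min = min(rad), mean = mean(rad),
                                  max = max(rad)),
              cut_cost = object$cut_cost,
              seed_avg = object$seed_avg,
              params = object$params)
  class(out) <- "summary.starcut"
  out
}

#' @export
print.summary.starcut <- function(x, ...) {
  if (x$collapsed) {
    cat(sprintf("Collapsed segmentation (%s); area 0 px\n",
                x$collapse_reason))
  } else {
    cat(sprintf("Segmented area: %d px (equivalent diameter %.1f px)\n",
                x$area_px, x$equivalent_diameter_px))
    cat(sprintf("Boundary radius [px]: min %.1f, mean %.1f, max %.1f\n",
                x$boundary_radius[["min"]], x$boundary_radius[["mean"]],
                x$boundary_radius[["max"]]))
  }
  cat(sprintf("Cut cost %.4g at seed average %.2f\n", x$cut_cost,
              x$seed_avg))
  invisible(x)
}

#' Per-ray boundary radii of a segmentation
#'
#' @param object a `starcut` object.
#' @param ... unused.
#' @return named numeric vector: radial distance (px) of the contour point on
#'   each ray (0 for collapsed rays).
#' @export
coef.starcut <- function(object, ...) {
  rad <- sqrt((object$contour[, 1L] - object$seed[1L])^2 +
              (object$contour[, 2L] - object$seed[2L])^2)
  names(rad) <- sprintf("ray%02d", seq_along(rad) - 1L)
  rad
}

#' Plot a segmentation result over its image
#'
#' Displays the grayscale image with the contour polygon, the contour points
#' and the seed overlaid, mimicking the on-screen feedback of the interactive
#' tool.
#'
#' @param x a `starcut` object.
#' @param image the image that was segmented (numeric matrix); required
#'   because the result object does not retain pixel data.
#' @param ... passed to [graphics::lines()] for the contour.
#' @export
plot.starcut <- function(x, image, ...) {
  check_image(image)
  nr <- nrow(image); nc <- ncol(image)
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) else
    matrix(0.5, nr, nc)
  op <- par(mar = c(2, 2, 2, 1))
  on.exit(par(op))
  plot.new()
  plot.window(xlim = c(-0.5, nc - 0.5), ylim = c(nr - 0.5, -0.5),
              asp = 1)
  rasterImage(img01, -0.5, nr - 0.5, nc - 0.5, -0.5, interpolate = FALSE)
  if (!x$collapsed) {
    poly <- rbind(x$contour, x$contour[1L, , drop = FALSE])
    lines(poly[, 1L], poly[, 2L], col = "red", lwd = 2, ...)
    points(x$contour[, 1L], x$contour[, 2L], col = "red", pch = 20,
           cex = 0.6)
  }
  points(x$seed[1L], x$seed[2L], col = "white", pch = 19)
  invisible(x)
}
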