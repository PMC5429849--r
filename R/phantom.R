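# Synthetic B-mode speckle phantoms: piecewise-constant echogenicity maps
# (elliptical lesion, optional hypoechoic halo rim) under unit-mean
# multiplicative gamma speckle and a Gaussian point-spread blur, with exact
# ground-truth masks. Covers the five standard echo-pattern classes:
# hyperechoic, isoechoic, hypoechoic, and iso-/hyperechoic with halo.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic lesion phantom
#'
#' Describes a B-mode-like test image: a uniform parenchyma background, one
#' elliptical lesion (rotated ellipse), an optional hypoechoic halo ring
#' around it, multiplicative speckle and a point-spread blur. Echogenicity
#' levels are mean gray values on the usual 0-255 8-bit scale.
#'
#' @param image_shape `c(nrow, ncol)` of the image.
#' @param background_level mean background echogenicity (> 0).
#' @param center lesion centre `(x, y)`; defaults to the image centre.
#' @param semi_axes lesion ellipse semi-axes `(a, b)` in pixels.
#' @param rotation ellipse rotation in radians (clockwise on screen).
#' @param lesion_level mean echogenicity inside the lesion (> 0);
#'   hypoechoic if below, hyperechoic if above, isoechoic if within 2% of
#'   the background level.
#' @param halo_width width of the hypoechoic rim in pixels (0 = no halo).
#' @param halo_level mean echogenicity of the rim; must be darker than both
#'   lesion and background.
#' @param speckle_scale dispersion (sd) of the unit-mean multiplicative
#'   speckle factor; 0 disables speckle.
#' @param blur_sigma Gaussian point-spread sigma in pixels; 0 disables
#'   blurring.
#' @param rng_seed integer seed making the phantom reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(160L, 160L), background_level = 100,
                         center = (rev(image_shape) - 1) / 2,
                         semi_axes = c(20, 20), rotation = 0,
                         lesion_level = 60, halo_width = 0,
                         halo_level = NULL, speckle_scale = 0.25,
                         blur_sigma = 1.5, rng_seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            length(center) == 2L, length(semi_axes) == 2L)
  if (background_level <= 0 || lesion_level <= 0)
    stop("echogenicity levels must be > 0")
  if (any(semi_axes <= 0)) stop("'semi_axes' must be positive")
  if (halo_width < 0) stop("'halo_width' must be >= 0")
  if (speckle_scale < 0) stop("'speckle_scale' must be >= 0")
  if (blur_sigma < 0) stop("'blur_sigma' must be >= 0")
  if (halo_width > 0) {
    if (is.null(halo_level)) halo_level <- 0.5 * min(lesion_level,
                                                     background_level)
    if (halo_level <= 0 || halo_level >= min(lesion_level, background_level))
      stop("'halo_level' must be positive and darker than both lesion and background")
  } else halo_level <- NULL
  outer_r <- max(semi_axes) + halo_width
  if (center[1L] - outer_r < 0 || center[1L] + outer_r > image_shape[2L] - 1 ||
      center[2L] - outer_r < 0 || center[2L] + outer_r > image_shape[1L] - 1)
    stop("lesion (plus halo) does not fit inside the image")

  structure(list(image_shape = image_shape,
                 background_level = background_level,
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation),
                 lesion_level = lesion_level,
                 halo_width = halo_width, halo_level = halo_level,
                 speckle_scale = speckle_scale, blur_sigma = blur_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Echo-pattern class of a phantom specification
#'
#' @param spec a [phantom_spec()] object.
#' @return one of `"hyper"`, `"iso"`, `"hypo"`, `"hyper_halo"`,
#'   `"iso_halo"` (a lesion is isoechoic when its level is within 2% of the
#'   background).
#' @export
echo_class <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rel <- spec$lesion_level / spec$background_level
  base <- if (abs(rel - 1) <= 0.02) "iso" else if (rel > 1) "hyper" else
    "hypo"
  if (spec$halo_width > 0) paste0(base, "_halo") else base
}

# Signed ellipse indicator on the pixel grid: TRUE where the pixel centre is
# inside or on the (rotated, possibly dilated) ellipse.
ellipse_mask <- function(shape, center, semi_axes, rotation, grow = 0) {
  nr <- shape[1L]; nc <- shape[2L]
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc) - center[1L]
  y <- matrix(rep(0:(nr - 1L), times = nc), nr, nc) - center[2L]
  u <- x * cos(rotation) + y * sin(rotation)
  v <- -x * sin(rotation) + y * cos(rotation)
  (u / (semi_axes[1L] + grow))^2 + (v / (semi_axes[2L] + grow))^2 <= 1
}

#' Generate a phantom image and its ground-truth mask
#'
#' Builds the piecewise-constant echogenicity map (background, elliptical
#' lesion, optional halo ring), multiplies every pixel by an independent
#' gamma-distributed factor with mean 1 and standard deviation
#' `speckle_scale` (a standard caricature of fully developed speckle), and
#' finally applies a Gaussian blur of `blur_sigma` pixels emulating the
#' system point-spread function. The ground-truth mask marks the lesion
#' interior only; the halo is excluded.
#'
#' @param spec a [phantom_spec()] object.
#' @return object of class `phantom`: list with `image` (numeric matrix),
#'   `mask` (integer 0/1 matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$image_shape
  lesion <- ellipse_mask(shape, spec$center, spec$semi_axes, spec$rotation)
  img <- matrix(spec$background_level, shape[1L], shape[2L])
  if (spec$halo_width > 0) {
    ring <- ellipse_mask(shape, spec$center, spec$semi_axes, spec$rotation,
                         grow = spec$halo_width) & !lesion
    img[ring] <- spec$halo_level
  }
  img[lesion] <- spec$lesion_level

  if (spec$speckle_scale > 0) {
    shp <- 1 / spec$speckle_scale^2  # gamma: mean 1, sd = speckle_scale
    fac <- with_seed(spec$rng_seed,
                     matrix(rgamma(length(img), shape = shp, rate = shp),
                            shape[1L], shape[2L]))
    img <- img * fac
  }
  if (spec$blur_sigma > 0)
    img <- matrix(EBImage::imageData(EBImage::gblur(img,
                                                    sigma = spec$blur_sigma)),
                  shape[1L], shape[2L])

  structure(list(image = img, mask = matrix(as.integer(lesion),
                                            shape[1L], shape[2L]),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Phantom (%s): %dx%d px, background %.0f, lesion %.0f",
              echo_class(s), s$image_shape[1L], s$image_shape[2L],
              s$background_level, s$lesion_level))
  if (s$halo_width > 0)
    cat(sprintf(", halo %.0f (width %.1f px)", s$halo_level, s$halo_width))
  cat(sprintf("\n  speckle %.2f, blur sigma %.1f px, seed %d; lesion area %d px\n",
              s$speckle_scale, s$blur_sigma, s$rng_seed, sum(x$mask)))
  invisible(x)
}

largest_remainder <- function(n, prop) {
  raw <- n * prop
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Generate a reproducible suite of randomised phantoms
#'
#' Allocates `n` cases to echo-pattern classes by largest-remainder rounding
#' of `class_mix`, then draws lesion geometry and levels uniformly within
#' fixed, realistic bounds (semi-axes 15-28 px, mild eccentricity, hypo
#' levels 55-70, hyper levels 130-150, halo 4-7 px wide at level 45-60,
#' centre jittered by up to 5 px). The whole suite is a pure function of
#' `rng_seed`.
#'
#' @param n number of phantoms (>= 1).
#' @param class_mix named proportions over
#'   `c("hypo", "iso", "hyper", "hypo_halo", "iso_halo", "hyper_halo")`
#'   subsets; must sum to 1.
#' @param image_shape image dimensions for all cases.
#' @param speckle_scale,blur_sigma noise settings applied to all cases.
#' @param rng_seed master seed for the suite.
#' @return list of class `phantom_suite`: `phantoms` (list of [generate_phantom()]
#'   results) and `manifest` (one data.frame row per case).
#' @export
phantom_suite <- function(n, class_mix = c(hypo = 0.8, iso_halo = 0.1,
                                           hyper = 0.1),
                          image_shape = c(160L, 160L), speckle_scale = 0.25,
                          blur_sigma = 1.5, rng_seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  if (is.null(names(class_mix)) || any(!nzchar(names(class_mix))))
    stop("'class_mix' must be a named vector of proportions")
  allowed <- c("hypo", "iso", "hyper", "hypo_halo", "iso_halo", "hyper_halo")
  if (!all(names(class_mix) %in% allowed))
    stop("unknown phantom class in 'class_mix'")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("'class_mix' proportions must be non-negative and sum to 1")

  counts <- largest_remainder(n, class_mix)
  classes <- rep(names(class_mix), counts)

  draws <- with_seed(rng_seed, {
    lapply(seq_len(n), function(i) {
      a <- runif(1, 15, 28)
      list(a = a, b = a * runif(1, 0.7, 1),
           rot = runif(1, 0, pi),
           jitter = runif(2, -5, 5),
           hypo = runif(1, 55, 70), hyper = runif(1, 130, 150),
           iso = runif(1, 98, 100),
           halo = runif(1, 45, 60), halo_w = runif(1, 4, 7),
           seed = sample.int(.Machine$integer.max - 1L, 1L))
    })
  })

  phantoms <- vector("list", n)
  rows <- vector("list", n)
  ctr0 <- (rev(image_shape) - 1) / 2
  for (i in seq_len(n)) {
    cl <- classes[i]; d <- draws[[i]]
    base <- sub("_halo$", "", cl)
    # "iso" draws are nearly isoechoic (within the 2% iso band, slightly
    # hypo): an exactly level-matched lesion is invisible to an intensity
    # cost even across a halo, since all cuts beyond the rim tie
    lesion_level <- switch(base, hypo = d$hypo, hyper = d$hyper,
                           iso = d$iso)
    has_halo <- grepl("_halo$", cl)
    spec <- phantom_spec(
      image_shape = image_shape, background_level = 100,
      center = ctr0 + d$jitter, semi_axes = c(d$a, d$b), rotation = d$rot,
      lesion_level = lesion_level,
      halo_width = if (has_halo) d$halo_w else 0,
      halo_level = if (has_halo) min(d$halo, lesion_level - 5, 95) else NULL,
      speckle_scale = speckle_scale, blur_sigma = blur_sigma,
      rng_seed = d$seed)
    phantoms[[i]] <- generate_phantom(spec)
    rows[[i]] <- data.frame(
      case_id = sprintf("phantom_%03d", i), class = cl,
      center_x = spec$center[1L], center_y = spec$center[2L],
      semi_a = spec$semi_axes[1L], semi_b = spec$semi_axes[2L],
      rotation = spec$rotation, lesion_level = spec$lesion_level,
      halo_width = spec$halo_width,
      halo_level = if (has_halo) spec$halo_level else NA_real_,
      speckle_scale = speckle_scale, blur_sigma = blur_sigma,
      rng_seed = spec$rng_seed, area_px = sum(phantoms[[i]]$mask))
  }
  structure(list(phantoms = phantoms, manifest = do.call(rbind, rows)),
            class = "phantom_suite")
}

#' @export
print.phantom_suite <- function(x, ...) {
  cat(sprintf("Phantom suite: %d cases\n", length(x$phantoms)))
  print(table(x$manifest$class))
  invisible(x)
}
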