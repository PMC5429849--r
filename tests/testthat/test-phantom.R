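test_that("noise-free phantoms are exact two-level (or three-level) images", {
  sp <- phantom_spec(lesion_level = 60, speckle_scale = 0, blur_sigma = 0)
  ph <- generate_phantom(sp)
  expect_setequal(unique(as.vector(ph$image)), c(60, 100))
  expect_true(all(ph$image[ph$mask == 1] == 60))
  expect_true(all(ph$image[ph$mask == 0] == 100))
  expect_equal(dim(ph$image), c(160L, 160L))

  # halo adds a third level, excluded from the ground-truth mask
  sph <- phantom_spec(lesion_level = 140, halo_width = 5, halo_level = 50,
                      speckle_scale = 0, blur_sigma = 0)
  phh <- generate_phantom(sph)
  expect_setequal(unique(as.vector(phh$image)), c(50, 100, 140))
  expect_true(all(phh$image[phh$mask == 1] == 140))

  expect_error(phantom_spec(semi_axes = c(90, 90)), "fit")
  expect_error(phantom_spec(lesion_level = -5), "> 0")
  expect_error(phantom_spec(halo_width = 4, halo_level = 120,
                            lesion_level = 60), "darker")
})

test_that("echo-pattern class derives from levels and halo", {
  expect_equal(echo_class(phantom_spec(lesion_level = 140)), "hyper")
  expect_equal(echo_class(phantom_spec(lesion_level = 60)), "hypo")
  expect_equal(echo_class(phantom_spec(lesion_level = 99)), "iso")
  expect_equal(echo_class(phantom_spec(lesion_level = 99, halo_width = 4,
                                       halo_level = 50)), "iso_halo")
  expect_equal(echo_class(phantom_spec(lesion_level = 140, halo_width = 4,
                                       halo_level = 50)), "hyper_halo")
})

test_that("identical spec and seed give bitwise-identical phantoms", {
  sp <- phantom_spec(lesion_level = 60, rng_seed = 42)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)

  p3 <- generate_phantom(phantom_spec(lesion_level = 60, rng_seed = 43))
  expect_false(identical(p1$image, p3$image))
})

test_that("speckle is multiplicative with unit mean and preserves level contrast", {
  # unit-mean of the gamma factor field
  set.seed(99)
  s <- 0.3
  fac <- rgamma(2e5, shape = 1 / s^2, rate = 1 / s^2)
  expect_lt(abs(mean(fac) - 1), 0.01)
  expect_lt(abs(sd(fac) - s), 0.01)

  # hypo lesion keeps its mean gap under speckle
  sp <- phantom_spec(lesion_level = 60, semi_axes = c(40, 40),
                     image_shape = c(200L, 200L), speckle_scale = 0.3,
                     blur_sigma = 0, rng_seed = 8)
  ph <- generate_phantom(sp)
  gap <- mean(ph$image[ph$mask == 0]) - mean(ph$image[ph$mask == 1])
  expect_lt(abs(gap - 40) / 40, 0.1)
  expect_lt(mean(ph$image[ph$mask == 1]), mean(ph$image[ph$mask == 0]))
})

test_that("hypo lesions stay darker in expectation across speckle levels", {
  for (s in c(0.1, 0.25, 0.4)) {
    gaps <- vapply(1:10, function(i) {
      sp <- phantom_spec(lesion_level = 60, speckle_scale = s,
                         rng_seed = 1000 + i)
      ph <- generate_phantom(sp)
      seed_average(ph$image, sp$center, 3) - mean(ph$image[ph$mask == 0])
    }, numeric(1))
    expect_lt(mean(gaps), 0)
  }
})

test_that("suite allocation, bounds and reproducibility hold", {
  st <- phantom_suite(20, class_mix = c(hypo = 0.8, iso = 0.1, hyper = 0.1),
                      rng_seed = 3)
  cnt <- table(st$manifest$class)
  expect_equal(cnt[["hypo"]], 16L)
  expect_equal(cnt[["iso"]], 2L)
  expect_equal(cnt[["hyper"]], 2L)
  expect_equal(length(st$phantoms), 20)
  for (ph in st$phantoms) {
    expect_gt(sum(ph$mask), 0)
    expect_equal(dim(ph$mask), dim(ph$image))
  }

  st2 <- phantom_suite(20, class_mix = c(hypo = 0.8, iso = 0.1,
                                         hyper = 0.1), rng_seed = 3)
  expect_identical(st$manifest, st2$manifest)
  expect_identical(st$phantoms[[7]]$image, st2$phantoms[[7]]$image)

  expect_error(phantom_suite(5, class_mix = c(hypo = 0.5, iso = 0.2)),
               "sum to 1")
  expect_error(phantom_suite(5, class_mix = c(weird = 1)), "unknown")
})

test_that("noise-free recovery reaches high Dice for detectable classes", {
  presets <- list(
    hyper = list(level = 140, halo = 0),
    hypo = list(level = 60, halo = 0),
    hyper_halo = list(level = 140, halo = 5),
    iso_halo = list(level = 98, halo = 5))
  for (nm in names(presets)) {
    p <- presets[[nm]]
    sp <- phantom_spec(lesion_level = p$level, halo_width = p$halo,
                       halo_level = if (p$halo > 0) 50 else NULL,
                       semi_axes = c(22, 18), rotation = 0.4,
                       speckle_scale = 0, blur_sigma = 0)
    ph <- generate_phantom(sp)
    fit <- segment_lesion(ph$image, sp$center, radius = 45)
    expect_false(fit$collapsed)
    expect_gte(dice(fit$mask, ph$mask), 0.9)
  }
})
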