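test_that("white/dark calibration satisfies its defining identities", {
  wl <- tiny_grid(80)
  cb <- flat_cubes(wl = wl)
  # S = W -> R = 1; S = D -> R = 0; S = (W+D)/2 -> R = 0.5
  expect_equal(as.numeric(calibrate_reflectance(cb$white, cb$white, cb$dark)),
               rep(1, length(cb$white)))
  expect_equal(as.numeric(calibrate_reflectance(cb$dark, cb$white, cb$dark)),
               rep(0, length(cb$dark)))
  mid <- hyper_cube((unclass(cb$white) + unclass(cb$dark)) / 2, wl)
  expect_equal(as.numeric(calibrate_reflectance(mid, cb$white, cb$dark)),
               rep(0.5, length(mid)))
})

test_that("calibration flags zero-signal pixels and is offset-invariant", {
  wl <- tiny_grid(80)
  cb <- flat_cubes(wl = wl)
  w <- unclass(cb$white); w[1, 1, ] <- 100  # W - D = 0 there
  bad <- calibrate_reflectance(cb$sample, hyper_cube(w, wl), cb$dark)
  expect_true(all(is.na(unclass(bad)[1, 1, ])))
  expect_false(anyNA(unclass(bad)[2, , ]))
  # adding a common offset to S, W and D leaves R unchanged
  r0 <- calibrate_reflectance(cb$sample, cb$white, cb$dark)
  shift <- function(cube, k) hyper_cube(unclass(cube) + k, wl)
  r1 <- calibrate_reflectance(shift(cb$sample, 55), shift(cb$white, 55),
                              shift(cb$dark, 55))
  expect_equal(unclass(r1), unclass(r0), tolerance = 1e-12)
})

test_that("calibration rejects mismatched shapes and grids", {
  cb <- flat_cubes()
  small <- flat_cubes(nr = 3)
  expect_error(calibrate_reflectance(small$sample, cb$white, cb$dark),
               "shapes differ")
  other <- flat_cubes(wl = tiny_grid(80) + 1)
  expect_error(calibrate_reflectance(other$sample, cb$white, cb$dark),
               "grids differ")
  refl <- calibrate_reflectance(cb$sample, cb$white, cb$dark)
  expect_error(calibrate_reflectance(refl, cb$white, cb$dark), "raw")
})

test_that("band lookup returns the nearest band, ties toward lower", {
  expect_equal(band_index(c(600, 670, 676, 682, 800), 676), 3L)
  expect_equal(band_index(c(600, 674, 678, 800, 801), 676), 2L)
  grid <- seq(400, 800, by = 1)
  expect_equal(grid[band_index(grid, 752.4)], 752)
  expect_error(band_index(grid, 900), "outside grid span")
})

test_that("NDVI matches its formula and boundary cases", {
  wl <- c(450, 600, 676, 752, 800)
  mk <- function(nir, red) {
    a <- array(0.3, dim = c(2, 2, 5))
    a[, , 3] <- red; a[, , 4] <- nir
    hyper_cube(a, wl, "reflectance")
  }
  expect_equal(unique(as.numeric(ndvi_image(mk(0.4, 0.4)))), 0)
  expect_equal(unique(as.numeric(ndvi_image(mk(0.4, 0)))), 1)
  expect_equal(unique(as.numeric(ndvi_image(mk(0.4, 0.2)))), 1 / 3,
               tolerance = 1e-12)
  # NIR + Red = 0 -> undefined
  expect_true(all(is.na(as.numeric(ndvi_image(mk(0, 0))))))
  # raw cubes are rejected
  raw <- hyper_cube(array(1, dim = c(2, 2, 5)), wl, "raw")
  expect_error(ndvi_image(raw), "calibrated")
})

test_that("NDVI is invariant to a positive scaling of the cube", {
  sc <- quick_scene("hg", wavelengths = tiny_grid(4))
  refl <- calibrate_reflectance(sc$sample, sc$white, sc$dark)
  scaled <- hyper_cube(unclass(refl) * 3.7, cube_wavelengths(refl),
                       "reflectance")
  expect_equal(unclass(ndvi_image(scaled)), unclass(ndvi_image(refl)),
               tolerance = 1e-12)
})

test_that("ROI mean spectra average correctly and skip undefined pixels", {
  wl <- tiny_grid(80)
  a <- array(rep(seq_along(wl) / 10, each = 6), dim = c(2, 3, length(wl)))
  a[2, 1, ] <- 3 * a[2, 1, ]  # distinct pixel
  cube <- hyper_cube(a, wl, "reflectance")
  one <- matrix(FALSE, 2, 3); one[2, 1] <- TRUE
  expect_equal(as.numeric(roi_mean_spectrum(cube, one)), a[2, 1, ])
  # two-pixel average
  two <- one; two[1, 1] <- TRUE
  expect_equal(as.numeric(roi_mean_spectrum(cube, two)),
               (a[1, 1, ] + a[2, 1, ]) / 2)
  # NA pixels are skipped; all-NA band undefined
  a2 <- a; a2[1, 1, 1] <- NA; a2[, , 2][two] <- NA
  cube2 <- hyper_cube(a2, wl, "reflectance")
  sp <- roi_mean_spectrum(cube2, two)
  expect_equal(sp[1], a[2, 1, 1])
  expect_true(is.na(sp[2]))
  expect_error(roi_mean_spectrum(cube, matrix(FALSE, 2, 3)), "empty")
})

test_that("second derivative is exact for quadratics and zero for constants", {
  wl <- seq(400, 800, by = 5)
  quad <- spectrum(2e-6 * wl^2, wl)  # f = a w^2 -> f'' = 2a
  d2 <- second_derivative(quad, smooth_window = 1L)
  inner <- as.numeric(d2)[2:(length(wl) - 1)]
  expect_equal(inner, rep(4e-6, length(inner)), tolerance = 1e-9)
  flat <- spectrum(rep(0.4, length(wl)), wl)
  expect_equal(max(abs(as.numeric(second_derivative(flat, 5L))),
                   na.rm = TRUE), 0)
  expect_error(second_derivative(flat, 4L), "odd")
})

test_that("second derivative of a Gaussian dip matches the analytic curvature", {
  wl <- seq(400, 800, by = 0.5)
  a <- 0.2; mu <- 550; s <- 12
  vals <- 0.6 - a * exp(-(wl - mu)^2 / (2 * s^2))
  d2 <- second_derivative(spectrum(vals, wl), smooth_window = 1L)
  analytic <- -a * exp(-(wl - mu)^2 / (2 * s^2)) *
    ((wl - mu)^2 - s^2) / s^4
  i <- band_index(wl, mu)
  expect_lt(abs(as.numeric(d2)[i] - analytic[i]) / abs(analytic[i]), 0.01)
  # curvature maximum sits at the dip centre
  expect_equal(which.max(as.numeric(d2)[-c(1, length(wl))]) + 1L, i)
})

test_that("derivative images equal pixel-wise spectral derivatives", {
  sc <- quick_scene("hg", shape = c(24L, 32L), wavelengths = tiny_grid(2))
  refl <- calibrate_reflectance(sc$sample, sc$white, sc$dark)
  img <- second_derivative_image(refl, 507, smooth_window = 5L)
  wl <- cube_wavelengths(refl)
  i <- band_index(wl, 507)
  for (px in list(c(5L, 7L), c(12L, 20L), c(20L, 30L))) {
    spec <- spectrum(unclass(refl)[px[1], px[2], ], wl)
    expect_equal(unclass(img)[px[1], px[2]],
                 as.numeric(second_derivative(spec, 5L))[i],
                 tolerance = 1e-12)
  }
  # spatially uniform cube -> constant image
  u <- hyper_cube(array(rep(0.5 - 0.2 * sin(wl / 50), each = 12),
                        dim = c(3, 4, length(wl))), wl, "reflectance")
  expect_equal(diff(range(unclass(second_derivative_image(u, 507)))), 0)
  expect_error(second_derivative_image(refl, 400), "edge")
})

test_that("dd507 ignores affine baselines and scales with the 507 nm feature", {
  wl <- tiny_grid(2)
  base <- diatom_spectrum(0.5, wl, pigment = 0.8, g507 = 0.05)
  tilted <- spectrum(as.numeric(base) + 0.1 + 3e-4 * wl, wl)
  expect_equal(dd507(tilted), dd507(base), tolerance = 1e-10)
  # flat spectrum -> 0
  expect_equal(dd507(spectrum(rep(0.3, length(wl)), wl)), 0)
  # amplitude proportionality of the isolated degradation feature
  lo <- diatom_spectrum(0.3, wl, pigment = 0, g507 = 0.05)
  hi <- diatom_spectrum(0.75, wl, pigment = 0, g507 = 0.05)
  expect_equal(dd507(hi) / dd507(lo), 2.5, tolerance = 1e-6)
  # local-maximum search never reports less than the fixed-band value
  expect_gte(dd507(base, search_local = TRUE), dd507(base))
})
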