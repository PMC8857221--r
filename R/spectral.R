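#' Calibrate a raw hyperspectral stack to reflectance
#'
#' Converts camera counts to reflectance against a diffuse white standard
#' (e.g. 99% Spectralon) with dark-current subtraction:
#' R = (S - D) / (W - D), per pixel and band. Pixels/bands where the white
#' signal does not exceed the dark signal (W - D <= 0) are undefined (`NA`).
#'
#' Adding a common offset to both the sample and dark stacks leaves the
#' result unchanged (affine invariance of the calibration).
#'
#' @param sample raw `hyper_cube` of the specimen (S).
#' @param white raw `hyper_cube` recorded over the white standard (W).
#' @param dark raw `hyper_cube` of the dark/background signal (D).
#' @return A `hyper_cube` in `"reflectance"` state.
#' @export
calibrate_reflectance <- function(sample, white, dark) {
  for (nm in c("sample", "white", "dark")) {
    cube <- get(nm)
    if (!inherits(cube, "hyper_cube"))
      stop("`", nm, "` is not a hyper_cube")
    if (cube_state(cube) != "raw")
      stop("`", nm, "` must be in raw state")
  }
  if (!identical(dim(sample), dim(white)) || !identical(dim(sample), dim(dark)))
    stop("sample/white/dark cube shapes differ: ",
         paste(dim(sample), collapse = "x"), " vs ",
         paste(dim(white), collapse = "x"), " vs ",
         paste(dim(dark), collapse = "x"))
  if (!isTRUE(all.equal(cube_wavelengths(sample), cube_wavelengths(white))) ||
      !isTRUE(all.equal(cube_wavelengths(sample), cube_wavelengths(dark))))
    stop("sample/white/dark wavelength grids differ")
  denom <- unclass(white) - unclass(dark)
  bad <- !is.na(denom) & denom <= 0
  denom[bad] <- NA_real_
  refl <- (unclass(sample) - unclass(dark)) / denom
  hyper_cube(refl, cube_wavelengths(sample), state = "reflectance")
}

#' Nearest-band lookup
#'
#' Returns the position of the band centre nearest to a target wavelength.
#' Ties between two equidistant bands are broken toward the lower
#' wavelength, so results are deterministic on symmetric grids.
#'
#' @param wavelengths strictly increasing band-centre wavelengths (nm).
#' @param target_nm target wavelength (nm); must lie within the grid span.
#' @return Integer band index (1-based).
#' @export
band_index <- function(wavelengths, target_nm) {
  validate_grid(wavelengths)
  if (length(target_nm) != 1L || !is.finite(target_nm))
    stop("`target_nm` must be a single finite number")
  if (target_nm < wavelengths[1] || target_nm > wavelengths[length(wavelengths)])
    stop(sprintf("target %.1f nm outside grid span [%.1f, %.1f]",
                 target_nm, wavelengths[1], wavelengths[length(wavelengths)]))
  d <- abs(wavelengths - target_nm)
  # which.min already returns the first (lower-wavelength) minimiser
  which.min(d)
}

#' NDVI image from a calibrated cube
#'
#' Normalised difference vegetation index, a chlorophyll-content proxy:
#' NDVI = (NIR - Red) / (NIR + Red), using the bands nearest to the NIR and
#' red chlorophyll-absorption wavelengths (defaults 752 and 676 nm).
#' Pixels with NIR + Red = 0 or with undefined reflectance are `NA`.
#'
#' @param cube `hyper_cube` in reflectance state covering both bands.
#' @param nir_nm,red_nm band-centre targets in nm.
#' @return `scalar_image` labelled `"NDVI"`, values in [-1, 1].
#' @export
ndvi_image <- function(cube, nir_nm = 752, red_nm = 676) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` is not a hyper_cube")
  if (cube_state(cube) != "reflectance")
    stop("NDVI requires a calibrated (reflectance) cube")
  wl <- cube_wavelengths(cube)
  nir <- unclass(cube)[, , band_index(wl, nir_nm)]
  red <- unclass(cube)[, , band_index(wl, red_nm)]
  s <- nir + red
  s[!is.na(s) & s == 0] <- NA_real_
  scalar_image((nir - red) / s, label = "NDVI")
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of the reflectance over the defined pixels of a
#' mask. Undefined pixels are skipped; a band undefined at every masked
#' pixel is returned undefined.
#'
#' @param cube reflectance `hyper_cube`.
#' @param mask logical matrix matching the cube's spatial dimensions (or an
#'   integer two-column matrix of (row, col) pixel coordinates, 1-based).
#' @return A `spectrum` of kind `"reflectance"`.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` is not a hyper_cube")
  if (cube_state(cube) != "reflectance")
    stop("ROI spectra require a reflectance cube")
  d <- dim(cube)
  mask <- as_mask(mask, d[1:2])
  if (!any(mask)) stop("empty ROI mask")
  flat <- matrix(unclass(cube), nrow = d[1] * d[2], ncol = d[3])
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE], na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  spectrum(vals, cube_wavelengths(cube), kind = "reflectance")
}

# Accepts a logical matrix or an n x 2 (row, col) coordinate matrix and
# returns a logical matrix of the requested spatial shape.
as_mask <- function(mask, shape) {
  if (is.logical(mask) && is.matrix(mask)) {
    if (!identical(dim(mask), as.integer(shape)))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match image shape ", paste(shape, collapse = "x"))
    return(mask)
  }
  if (is.matrix(mask) && ncol(mask) == 2L) {
    if (any(mask[, 1] < 1 | mask[, 1] > shape[1] |
            mask[, 2] < 1 | mask[, 2] > shape[2]))
      stop("mask coordinates outside image bounds")
    out <- matrix(FALSE, shape[1], shape[2])
    out[mask] <- TRUE
    return(out)
  }
  stop("mask must be a logical matrix or an n x 2 coordinate matrix")
}

#' Second derivative of a spectrum
#'
#' Optional moving-average smoothing followed by the central second
#' difference (v[i-1] - 2 v[i] + v[i+1]) / h^2 on an (approximately)
#' uniformly spaced grid. The estimator is exact for quadratic spectra and
#' annihilates any baseline that is affine in wavelength, which is what
#' makes derivative spectroscopy sensitive to narrow absorption features.
#' Endpoint bands (and bands lost to the smoothing window) are undefined.
#'
#' @param spec `spectrum` of kind `"reflectance"` (or any numeric spectrum).
#' @param smooth_window odd moving-average width in bands; 1 = no smoothing.
#'   Default 5.
#' @return A `spectrum` of kind `"second_derivative"`.
#' @export
second_derivative <- function(spec, smooth_window = 5L) {
  if (!inherits(spec, "spectrum")) stop("`spec` is not a spectrum")
  wl <- attr(spec, "wavelengths")
  n <- length(wl)
  if (n < 3L) stop("second derivative needs at least 3 bands")
  check_window(smooth_window)
  h <- mean(diff(wl))
  v <- moving_average(as.numeric(spec), smooth_window)
  d2 <- c(NA_real_, (v[-c(n - 1L, n)] - 2 * v[-c(1L, n)] + v[-c(1L, 2L)]) / h^2,
          NA_real_)
  structure(d2, wavelengths = wl, kind = "second_derivative",
            class = "spectrum")
}

check_window <- function(w) {
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    stop("`smooth_window` must be a positive odd integer")
  invisible(w)
}

moving_average <- function(v, w) {
  if (w == 1L) return(v)
  k <- (w - 1L) %/% 2L
  n <- length(v)
  out <- stats::filter(v, rep(1 / w, w), sides = 2)
  out <- as.numeric(out)
  out[seq_len(k)] <- NA_real_
  out[seq.int(n - k + 1L, n)] <- NA_real_
  out
}

#' Second-derivative image at one wavelength
#'
#' Evaluates the per-pixel second derivative of the reflectance spectrum at
#' the band nearest `at_nm`, reconstructing a single-wavelength derivative
#' map from the full stack. Equivalent to applying [second_derivative()] to
#' every pixel spectrum and reading off that band.
#'
#' @param cube reflectance `hyper_cube`.
#' @param at_nm evaluation wavelength (nm); must be interior to the grid
#'   (with margin for the smoothing window).
#' @param smooth_window odd moving-average width in bands (default 5).
#' @return `scalar_image` labelled `"d2_<nm>"`.
#' @export
second_derivative_image <- function(cube, at_nm, smooth_window = 5L) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` is not a hyper_cube")
  if (cube_state(cube) != "reflectance")
    stop("derivative images require a reflectance cube")
  check_window(smooth_window)
  wl <- cube_wavelengths(cube)
  n <- length(wl)
  i <- band_index(wl, at_nm)
  k <- (smooth_window - 1L) %/% 2L
  if (i - 1L - k < 1L || i + 1L + k > n)
    stop(sprintf("band %.1f nm too close to the grid edge for window %d",
                 at_nm, smooth_window))
  h <- mean(diff(wl))
  # only the 2k+3 bands around i contribute
  idx <- seq.int(i - 1L - k, i + 1L + k)
  sub <- unclass(cube)[, , idx, drop = FALSE]
  d12 <- dim(sub)[1] * dim(sub)[2]
  smooth_at <- function(centre) {
    # centre is an offset within idx; moving-average of width 2k+1 around it
    sl <- sub[, , seq.int(centre - k, centre + k), drop = FALSE]
    matrix(rowMeans(matrix(sl, nrow = d12)), dim(sub)[1], dim(sub)[2])
  }
  c0 <- k + 2L  # position of band i within idx
  vm <- smooth_at(c0 - 1L); v0 <- smooth_at(c0); vp <- smooth_at(c0 + 1L)
  scalar_image((vm - 2 * v0 + vp) / h^2,
               label = sprintf("d2_%d", round(at_nm)))
}

#' Pigment-degradation index at 507 nm
#'
#' The second-derivative amplitude of the reflectance spectrum at the band
#' nearest 507 nm (peak height convention). A growing 507 nm absorption
#' feature — a marker of carotenoid degradation products — raises the local
#' curvature of the reflectance spectrum, so this index increases with
#' pigment degradation. Because the second derivative annihilates affine
#' baselines, the index is insensitive to broad background slopes.
#'
#' @param x a `spectrum` (reflectance) or a reflectance `hyper_cube`.
#' @param smooth_window odd moving-average width (default 5).
#' @param at_nm evaluation wavelength, default 507.
#' @param search_local if `TRUE`, return the maximum second-derivative
#'   value within `search_nm` of `at_nm` instead of the single nearest band
#'   (spectrum input only).
#' @param search_nm half-width of the local-maximum search window in nm
#'   (default 6).
#' @return A scalar for spectrum input; a `scalar_image` labelled
#'   `"dd507"` for cube input.
#' @export
dd507 <- function(x, smooth_window = 5L, at_nm = 507,
                  search_local = FALSE, search_nm = 6) {
  if (inherits(x, "hyper_cube")) {
    img <- second_derivative_image(x, at_nm, smooth_window)
    return(scalar_image(unclass(img), label = "dd507"))
  }
  if (!inherits(x, "spectrum")) stop("`x` must be a spectrum or hyper_cube")
  d2 <- second_derivative(x, smooth_window)
  wl <- attr(x, "wavelengths")
  if (search_local) {
    sel <- which(abs(wl - at_nm) <= search_nm)
    vals <- as.numeric(d2)[sel]
    if (all(is.na(vals))) return(NA_real_)
    return(max(vals, na.rm = TRUE))
  }
  as.numeric(d2)[band_index(wl, at_nm)]
}
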