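#' Hyperspectral cube, spectrum and scalar-image containers
#'
#' A `hyper_cube` is a rows x cols x bands numeric array with a strictly
#' increasing wavelength grid (nm) and a calibration state, either `"raw"`
#' (camera counts) or `"reflectance"` (dimensionless fraction). Undefined
#' pixels are `NA` and are never silently replaced.
#'
#' @param data numeric 3-D array, rows x cols x bands, non-negative where
#'   defined (`NA` allowed for undefined pixels).
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param state `"raw"` or `"reflectance"`.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths, state = c("raw", "reflectance")) {
  state <- match.arg(state)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x bands array")
  validate_grid(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension (", dim(data)[3], ") must equal grid length (",
         length(wavelengths), ")")
  if (any(data < 0 & state == "raw", na.rm = TRUE))
    stop("raw cube contains negative intensities")
  structure(data, wavelengths = as.numeric(wavelengths), state = state,
            class = c("hyper_cube", "array"))
}

validate_grid <- function(wavelengths) {
  if (!is.numeric(wavelengths) || length(wavelengths) < 5L)
    stop("wavelength grid must be numeric with at least 5 bands")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  invisible(wavelengths)
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x)
  wl <- attr(x, "wavelengths")
  cat(sprintf("hyper_cube [%s]: %d x %d px, %d bands (%.1f-%.1f nm)\n",
              attr(x, "state"), d[1], d[2], d[3], min(wl), max(wl)))
  invisible(x)
}

cube_wavelengths <- function(cube) attr(cube, "wavelengths")
cube_state <- function(cube) attr(cube, "state")

#' Single spectrum container
#'
#' @param values per-band numeric values (`NA` = undefined band).
#' @param wavelengths band-centre wavelengths (nm), strictly increasing.
#' @param kind `"reflectance"` or `"second_derivative"`.
#' @return Object of class `spectrum`: the value vector with `wavelengths`
#'   and `kind` attributes.
#' @export
spectrum <- function(values, wavelengths,
                     kind = c("reflectance", "second_derivative")) {
  kind <- match.arg(kind)
  validate_grid(wavelengths)
  if (length(values) != length(wavelengths))
    stop("values and wavelengths differ in length")
  if (kind == "reflectance" && any(values < 0, na.rm = TRUE))
    stop("reflectance spectrum has negative values")
  structure(as.numeric(values), wavelengths = as.numeric(wavelengths),
            kind = kind, class = "spectrum")
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = attr(x, "wavelengths"), value = as.numeric(x))
}

#' @export
print.spectrum <- function(x, ...) {
  wl <- attr(x, "wavelengths")
  cat(sprintf("spectrum [%s], %d bands (%.1f-%.1f nm)\n",
              attr(x, "kind"), length(x), min(wl), max(wl)))
  invisible(x)
}

#' Scalar image (single-band map with undefined-pixel mask)
#'
#' Undefined pixels are `NA`. NDVI-labelled images are checked to lie in
#' [-1, 1] where defined.
#'
#' @param data numeric matrix.
#' @param label short quantity label, e.g. `"NDVI"`, `"dd507"`, `"F0"`,
#'   `"FvFm"`.
#' @return Object of class `scalar_image`.
#' @export
scalar_image <- function(data, label = "value") {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (identical(label, "NDVI") &&
      any(abs(data) > 1 + 1e-12, na.rm = TRUE))
    stop("NDVI values outside [-1, 1]")
  structure(data, label = label, class = c("scalar_image", "matrix"))
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("scalar_image [%s]: %d x %d px, %d undefined\n",
              attr(x, "label"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
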