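#' PAM fluorescence image sequence
#'
#' A dark-acclimated (F0, Fm) image pair plus per-irradiance (F, F'm) image
#' pairs recorded along an increasing actinic light ladder, as produced by
#' an imaging PAM fluorometer. Pixels violating Fm >= F0 (or F'm >= F
#' within a step) are flagged undefined rather than clipped: they are
#' measurement noise, not usable yields.
#'
#' @param f0_img,fm_img `scalar_image` (or matrix): dark-acclimated minimum
#'   and maximum fluorescence yield.
#' @param steps list of steps, each `list(par = <PAR>, f_img = , fmp_img = )`
#'   with PAR in µmol photons m^-2 s^-1, strictly increasing across steps.
#' @param dark_acclimation_min dark-acclimation time (minutes; default 30).
#' @return Object of class `fluor_sequence`.
#' @export
fluor_sequence <- function(f0_img, fm_img, steps,
                           dark_acclimation_min = 30) {
  f0 <- as_img_matrix(f0_img); fm <- as_img_matrix(fm_img)
  if (!identical(dim(f0), dim(fm))) stop("F0/Fm shapes differ")
  pars <- vapply(steps, function(s) s$par, 1)
  if (length(pars) && any(diff(pars) <= 0))
    stop("PAR ladder must be strictly increasing")
  steps <- lapply(steps, function(s) {
    f <- as_img_matrix(s$f_img); fmp <- as_img_matrix(s$fmp_img)
    if (!identical(dim(f), dim(f0))) stop("step image shape mismatch")
    list(par = s$par, f_img = f, fmp_img = fmp)
  })
  structure(list(f0_img = f0, fm_img = fm, steps = steps,
                 dark_acclimation_min = dark_acclimation_min),
            class = "fluor_sequence")
}

as_img_matrix <- function(x) {
  if (inherits(x, "scalar_image")) return(unclass(x))
  if (is.matrix(x)) return(x)
  stop("expected a scalar_image or matrix")
}

#' @export
print.fluor_sequence <- function(x, ...) {
  cat(sprintf("fluor_sequence: %d x %d px, %d light steps (PAR %s)\n",
              nrow(x$f0_img), ncol(x$f0_img), length(x$steps),
              paste(vapply(x$steps, function(s) s$par, 1), collapse = ", ")))
  invisible(x)
}

#' The package's default nine-step actinic light ladder
#' (µmol photons m^-2 s^-1).
#' @export
default_par_ladder <- function() c(3, 17, 30, 50, 78, 112, 152, 201, 254)

# Shared yield kernel: (max - min)/max per pixel, undefined where max <= 0
# or min > max (noise), propagating input NAs.
yield_image <- function(min_img, max_img, label) {
  mn <- as_img_matrix(min_img); mx <- as_img_matrix(max_img)
  if (!identical(dim(mn), dim(mx))) stop("image shapes differ")
  if (all(is.na(mn)) || all(is.na(mx))) stop("all-undefined input image")
  out <- (mx - mn) / mx
  out[!is.na(mx) & mx <= 0] <- NA_real_
  out[!is.na(out) & out < 0] <- NA_real_  # min > max: flagged, not clipped
  scalar_image(out, label = label)
}

#' Maximum PSII quantum efficiency image
#'
#' Fv/Fm = (Fm - F0)/Fm per pixel from a dark-acclimated pair. Values lie
#' in [0, 1] where F0 <= Fm; pixels with Fm <= 0 or F0 > Fm are undefined.
#' Being a ratio, the result is invariant to a common detector gain.
#'
#' @param f0_img,fm_img dark-acclimated minimum/maximum fluorescence images.
#' @return `scalar_image` labelled `"FvFm"`.
#' @export
fv_fm_image <- function(f0_img, fm_img) yield_image(f0_img, fm_img, "FvFm")

#' Effective PSII quantum yield image
#'
#' phiPSII = (F'm - F)/F'm per pixel under actinic light.
#'
#' @param f_img,fmp_img steady-state and saturating-pulse fluorescence
#'   images at one irradiance step.
#' @return `scalar_image` labelled `"phiPSII"`.
#' @export
phi_psii_image <- function(f_img, fmp_img)
  yield_image(f_img, fmp_img, "phiPSII")

#' Build a rapid light curve from a fluorescence sequence
#'
#' For each light step, phiPSII is computed per pixel, averaged over the
#' defined pixels of the ROI (ratio-of-pixels, the imaging-PAM convention —
#' never the ratio of ROI-mean fluorescences), and converted to a relative
#' electron transport rate rETR = phiPSII x PAR. Steps whose ROI is fully
#' undefined are dropped with a warning.
#'
#' @param seq a `fluor_sequence`.
#' @param mask ROI: logical matrix or n x 2 coordinate matrix.
#' @param roi label for the ROI (default `"roi"`).
#' @return `rlc_data`: data frame with columns `par`, `retr` (and
#'   attribute `roi`), ordered by PAR.
#' @export
build_rlc <- function(seq, mask, roi = "roi") {
  if (!inherits(seq, "fluor_sequence")) stop("`seq` is not a fluor_sequence")
  mask <- as_mask(mask, dim(seq$f0_img))
  if (!any(mask)) stop("empty ROI mask")
  pts <- lapply(seq$steps, function(s) {
    phi <- unclass(phi_psii_image(s$f_img, s$fmp_img))[mask]
    phi <- phi[!is.na(phi)]
    if (!length(phi)) {
      warning("step at PAR ", s$par, " fully undefined in ROI; dropped")
      return(NULL)
    }
    data.frame(par = s$par, retr = mean(phi) * s$par)
  })
  out <- do.call(rbind, pts)
  if (is.null(out) || nrow(out) == 0L) stop("no usable light steps in ROI")
  out <- out[order(out$par), ]
  rownames(out) <- NULL
  structure(out, roi = roi, class = c("rlc_data", "data.frame"))
}

#' Constructor for RLC data from plain vectors
#'
#' @param par photon irradiances (µmol photons m^-2 s^-1), non-negative.
#' @param retr relative electron transport rates (a.u.), non-negative;
#'   must be 0 wherever `par` is 0.
#' @param roi ROI label.
#' @return `rlc_data` data frame ordered by PAR.
#' @export
rlc_data <- function(par, retr, roi = "roi") {
  if (length(par) != length(retr)) stop("par/retr lengths differ")
  if (any(par < 0)) stop("negative PAR")
  if (any(retr < 0)) stop("negative rETR")
  if (any(par == 0 & retr != 0)) stop("rETR must be 0 at PAR = 0")
  o <- order(par)
  structure(data.frame(par = par[o], retr = retr[o]), roi = roi,
            class = c("rlc_data", "data.frame"))
}
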