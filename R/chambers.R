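#' Chamber map: age-ordered ROI masks
#'
#' Foraminiferal test chambers are labelled by age index: 0 is the youngest
#' chamber (n, the last chamber formed), 1 is n-1, and so on. A chamber map
#' stores pairwise-disjoint pixel masks as a single integer label matrix
#' (0 = background, value k = age index k - 1), which enforces disjointness
#' by construction.
#'
#' @param labels integer matrix; 0 background, k marks the chamber with age
#'   index k - 1. Label values must be contiguous 1..K with every value
#'   present.
#' @return Object of class `chamber_map`.
#' @export
chamber_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0L, na.rm = TRUE)) stop("negative chamber labels")
  k <- max(labels, 0L, na.rm = TRUE)
  if (k < 1L) stop("chamber map has no chambers")
  present <- sort(unique(labels[labels > 0L]))
  if (!identical(present, seq_len(k)))
    stop("chamber age indices must be contiguous from 0 (labels 1..K)")
  structure(labels, class = c("chamber_map", "matrix"))
}

#' Build a chamber map from a list of masks
#'
#' @param masks list of logical matrices (or n x 2 coordinate matrices),
#'   one per chamber, in any order.
#' @param age_index integer vector of age indices (0 = youngest), one per
#'   mask; defaults to `seq_along(masks) - 1`.
#' @param shape image shape (rows, cols); defaults to the dimensions of the
#'   first logical mask.
#' @return `chamber_map`.
#' @export
chamber_map_from_masks <- function(masks, age_index = seq_along(masks) - 1L,
                                   shape = NULL) {
  if (length(masks) < 1L) stop("no masks supplied")
  if (length(age_index) != length(masks))
    stop("`age_index` must match `masks` in length")
  if (!identical(sort(as.integer(age_index)),
                 seq_len(length(masks)) - 1L))
    stop("age indices must be unique and contiguous from 0")
  if (is.null(shape)) {
    if (!is.logical(masks[[1]]))
      stop("`shape` is required when masks are coordinate matrices")
    shape <- dim(masks[[1]])
  }
  lab <- matrix(0L, shape[1], shape[2])
  for (j in seq_along(masks)) {
    m <- as_mask(masks[[j]], shape)
    if (!any(m)) stop("empty chamber mask at age index ", age_index[j])
    if (any(lab[m] != 0L)) stop("chamber masks overlap")
    lab[m] <- as.integer(age_index[j]) + 1L
  }
  chamber_map(lab)
}

#' @export
print.chamber_map <- function(x, ...) {
  cat(sprintf("chamber_map: %d chambers (n .. n-%d), %d x %d px\n",
              n_chambers(x), n_chambers(x) - 1L, nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname chamber_map
#' @param map a `chamber_map`.
#' @export
n_chambers <- function(map) max(unclass(map))

#' @rdname chamber_map
#' @param age age index (0 = chamber n).
#' @export
chamber_mask <- function(map, age) {
  if (age < 0L || age >= n_chambers(map)) stop("age index out of range")
  unclass(map) == as.integer(age) + 1L
}

chamber_name <- function(age) ifelse(age == 0L, "n", paste0("n-", age))

#' Per-chamber mean of a scalar image
#'
#' Mean and standard error over the defined pixels of each chamber mask,
#' ordered by age index (youngest first). Chambers whose pixels are all
#' undefined are reported with `NA` mean.
#'
#' @param img `scalar_image` (or plain matrix).
#' @param map `chamber_map` with matching spatial shape.
#' @return A `chamber_profile` data frame with columns
#'   `chamber`, `age_index`, `mean`, `se`, `npix` and a `quantity`
#'   attribute.
#' @export
per_chamber_mean <- function(img, map) {
  if (!inherits(map, "chamber_map")) stop("`map` is not a chamber_map")
  label <- if (inherits(img, "scalar_image")) attr(img, "label") else "value"
  img <- unclass(img)
  if (!identical(dim(img), dim(unclass(map))))
    stop("image and chamber map shapes differ")
  ages <- seq_len(n_chambers(map)) - 1L
  rows <- lapply(ages, function(a) {
    v <- img[chamber_mask(map, a)]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(chamber = chamber_name(a), age_index = a,
               mean = if (n) mean(v) else NA_real_,
               se = if (n > 1L) stats::sd(v) / sqrt(n) else
                 if (n == 1L) 0 else NA_real_,
               npix = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, quantity = label,
            class = c("chamber_profile", "data.frame"))
}

#' Per-chamber mean reflectance spectra
#'
#' [roi_mean_spectrum()] applied per chamber, ordered youngest first.
#'
#' @param cube reflectance `hyper_cube`.
#' @param map `chamber_map`.
#' @return Named list of `spectrum` objects (`"n"`, `"n-1"`, ...).
#' @export
per_chamber_spectra <- function(cube, map) {
  if (!inherits(map, "chamber_map")) stop("`map` is not a chamber_map")
  ages <- seq_len(n_chambers(map)) - 1L
  out <- lapply(ages, function(a) roi_mean_spectrum(cube, chamber_mask(map, a)))
  names(out) <- chamber_name(ages)
  out
}

#' Chamber-gradient heterogeneity test
#'
#' Tests whether a per-chamber quantity (e.g. NDVI) differs between
#' chambers, using specimens as replicates: one-way ANOVA across chamber
#' age followed by Tukey HSD with compact-letter grouping. Chambers missing
#' in some specimens are allowed; those specimens simply contribute no
#' observation for that chamber (a warning notes the imbalance).
#'
#' @param profiles list of `chamber_profile` data frames, one per specimen.
#' @return List with elements `anova` (a `test_report`), `tukey` (pairwise
#'   table + letters from [tukey_hsd()]), and `data` (the stacked
#'   specimen-by-chamber means).
#' @export
gradient_test <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 specimens")
  stacked <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(specimen = i, age_index = p$age_index, value = p$mean)
  }))
  stacked <- stacked[!is.na(stacked$value), ]
  counts <- table(stacked$age_index)
  if (length(counts) < 2L) stop("need at least 2 chambers with data")
  if (length(unique(counts)) > 1L)
    warning("unbalanced chamber coverage across specimens; ",
            "using available chambers only")
  groups <- split(stacked$value, stacked$age_index)
  an <- anova1(groups)
  tk <- tukey_hsd(groups)
  list(anova = an, tukey = tk, data = stacked)
}
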