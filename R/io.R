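#' File formats
#'
#' Images are written as TIFF with a greyscale + validity channel pair and
#' a plain-text sidecar (JSON for scalar images, CSV for cubes) recording
#' the affine offset/scale used to map values into the TIFF's [0, 1]
#' storage range (the available TIFF writer stores 32-bit scaled
#' integers), plus metadata: the encoding is lossless to ~2^-31 of the
#' data range. Undefined pixels carry validity 0. Chamber maps are 16-bit
#' label TIFFs (0 = background, value k = age index k - 1) or JSON
#' polygon lists rasterised by the even-odd rule at pixel centres
#' (half-open pixel convention, 0-based (row, col) vertices).
#'
#' @name kleptophys-io
NULL

# libtiff flags the validity channel as an undeclared extra sample (the
# writer cannot set the ExtraSamples tag); the data are read correctly,
# so silence that specific warning
read_tiff_quiet <- function(...) {
  withCallingHandlers(
    tiff::readTIFF(...),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

img_scaling <- function(vals) {
  rng <- range(vals, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  list(offset = rng[1], scale = rng[2] - rng[1])
}

encode_plane <- function(m, offset, scale) {
  v <- (m - offset) / scale
  ok <- is.finite(v)
  v[!ok] <- 0
  array(c(v, as.numeric(ok)), dim = c(nrow(m), ncol(m), 2L))
}

decode_plane <- function(a, offset, scale) {
  v <- a[, , 1] * scale + offset
  v[a[, , 2] < 0.5] <- NA_real_
  v
}

#' Write / read a hyperspectral cube
#'
#' Multi-page TIFF (one page per band, ascending wavelength, value +
#' validity channels) with a CSV sidecar `<path>.wavelengths.csv` holding
#' one wavelength per line and `# state/offset/scale` comment headers.
#'
#' @param cube a `hyper_cube`.
#' @param path output TIFF path.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   `hyper_cube`.
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` is not a hyper_cube")
  data <- unclass(cube)
  sc <- img_scaling(data)
  pages <- lapply(seq_len(dim(data)[3]), function(b)
    encode_plane(data[, , b], sc$offset, sc$scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- sub("\\.tiff?$", "", path)
  side <- paste0(side, ".wavelengths.csv")
  con <- file(side, "w")
  writeLines(c(sprintf("# state: %s", cube_state(cube)),
               sprintf("# offset: %.17g", sc$offset),
               sprintf("# scale: %.17g", sc$scale),
               "wavelength_nm",
               sprintf("%.10g", cube_wavelengths(cube))), con)
  close(con)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  side <- paste0(sub("\\.tiff?$", "", path), ".wavelengths.csv")
  if (!file.exists(side))
    stop("missing wavelength sidecar: ", side)
  lines <- readLines(side)
  meta <- lines[startsWith(lines, "#")]
  getm <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(hit)) stop("sidecar missing '", key, "' header")
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  state <- getm("state")
  offset <- as.numeric(getm("offset")); scale <- as.numeric(getm("scale"))
  body <- lines[!startsWith(lines, "#")]
  wl <- as.numeric(body[-1])
  pages <- read_tiff_quiet(path, all = TRUE)
  if (length(pages) != length(wl))
    stop("band count (", length(pages), ") != sidecar wavelengths (",
         length(wl), ")")
  planes <- lapply(pages, decode_plane, offset = offset, scale = scale)
  data <- array(unlist(planes),
                dim = c(dim(planes[[1]]), length(planes)))
  hyper_cube(data, wl, state = state)
}

#' Write / read a scalar image
#'
#' Single-page 32-bit TIFF (value + validity channels) with a JSON sidecar
#' `<path>.json` holding label, offset and scale.
#'
#' @param img a `scalar_image`.
#' @param path output TIFF path.
#' @return `write_scalar_image` returns `path` invisibly;
#'   `read_scalar_image` a `scalar_image`.
#' @export
write_scalar_image <- function(img, path) {
  if (!inherits(img, "scalar_image")) stop("`img` is not a scalar_image")
  m <- unclass(img)
  sc <- img_scaling(m)
  tiff::writeTIFF(encode_plane(m, sc$offset, sc$scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(label = attr(img, "label"), offset = sc$offset, scale = sc$scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scalar_image
#' @export
read_scalar_image <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  a <- read_tiff_quiet(path)
  scalar_image(decode_plane(a, meta$offset, meta$scale),
               label = meta$label)
}

#' Write / read a chamber map as a 16-bit label TIFF
#'
#' Pixel value 0 is background; value k marks the chamber with age index
#' k - 1.
#'
#' @param map a `chamber_map`.
#' @param path TIFF path.
#' @return `write_chamber_map` returns `path` invisibly;
#'   `read_chamber_map` a `chamber_map`.
#' @export
write_chamber_map <- function(map, path) {
  if (!inherits(map, "chamber_map")) stop("`map` is not a chamber_map")
  tiff::writeTIFF(unclass(map) / 65535, path, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_chamber_map
#' @export
read_chamber_map <- function(path) {
  lab <- tiff::readTIFF(path, as.is = TRUE)
  chamber_map(lab)
}

#' Read a chamber map from a JSON polygon list
#'
#' The JSON file is an array of objects `{age_index, vertices}` where
#' `vertices` is an array of `[row, col]` pairs in 0-based pixel
#' coordinates. Polygons are rasterised with the even-odd rule at pixel
#' centres (pixel (r, c) covers the half-open square [r, r+1) x [c, c+1),
#' centre (r + 0.5, c + 0.5)).
#'
#' @param path JSON file path.
#' @param shape image shape c(rows, cols).
#' @return A `chamber_map`.
#' @export
read_chamber_polygons <- function(path, shape) {
  polys <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  masks <- lapply(polys, function(p) {
    v <- p$vertices
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, as.numeric))
    if (ncol(v) != 2L) stop("polygon vertices must be [row, col] pairs")
    rasterize_polygon(v, shape)
  })
  ages <- vapply(polys, function(p) as.integer(p$age_index), 1L)
  chamber_map_from_masks(masks, age_index = ages, shape = shape)
}

# even-odd (crossing number) point-in-polygon at pixel centres
rasterize_polygon <- function(vertices, shape) {
  nr <- shape[1]; nc <- shape[2]
  py <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)          # row coord
  px <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)   # col coord
  inside <- matrix(FALSE, nr, nc)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write / read a chamber profile as CSV
#'
#' Columns `chamber,age_index,mean,se,npix`.
#'
#' @param profile a `chamber_profile`.
#' @param path CSV path.
#' @return `read_chamber_profile` returns a `chamber_profile`.
#' @export
write_chamber_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chamber_profile
#' @export
read_chamber_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, quantity = "value",
            class = c("chamber_profile", "data.frame"))
}

#' Write / read a spectrum as CSV (`wavelength_nm,value`)
#'
#' @param spec a `spectrum`.
#' @param path CSV path.
#' @param kind spectrum kind on reading.
#' @return `read_spectrum` returns a `spectrum`.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, kind = "reflectance") {
  df <- utils::read.csv(path)
  spectrum(df$value, df$wavelength_nm, kind = kind)
}

#' Write / read a fluorescence sequence directory
#'
#' Layout: `F0.tif`, `Fm.tif`, `F_<PAR>.tif`, `Fmp_<PAR>.tif` (each with
#' its JSON sidecar) plus `manifest.yaml` with the PAR ladder and
#' dark-acclimation time.
#'
#' @param seq a `fluor_sequence`.
#' @param dir directory (created if absent).
#' @return `read_fluor_sequence` returns a `fluor_sequence`.
#' @export
write_fluor_sequence <- function(seq, dir) {
  if (!inherits(seq, "fluor_sequence")) stop("not a fluor_sequence")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, lab, file)
    write_scalar_image(scalar_image(m, lab), file.path(dir, file))
  wr(seq$f0_img, "F0", "F0.tif")
  wr(seq$fm_img, "Fm", "Fm.tif")
  for (s in seq$steps) {
    wr(s$f_img, "F", sprintf("F_%g.tif", s$par))
    wr(s$fmp_img, "Fmp", sprintf("Fmp_%g.tif", s$par))
  }
  yaml::write_yaml(
    list(par_ladder = vapply(seq$steps, function(s) s$par, 1),
         dark_acclimation_min = seq$dark_acclimation_min),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_fluor_sequence
#' @export
read_fluor_sequence <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  manifest <- yaml::read_yaml(mf)
  rd <- function(file) {
    m <- unclass(read_scalar_image(file.path(dir, file)))
    attr(m, "label") <- NULL
    m
  }
  steps <- lapply(manifest$par_ladder, function(p)
    list(par = p, f_img = rd(sprintf("F_%g.tif", p)),
         fmp_img = rd(sprintf("Fmp_%g.tif", p))))
  fluor_sequence(rd("F0.tif"), rd("Fm.tif"), steps,
                 dark_acclimation_min =
                   manifest$dark_acclimation_min %||% 30)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write tidy pigment tables
#'
#' CSV columns `replicate,species,n_specimens,pigment,mass_ng[,basis]`.
#'
#' @param path CSV path.
#' @param basis basis used when the CSV has no `basis` column.
#' @return `read_pigment_table` returns a `pigment_profile`.
#' @export
read_pigment_table <- function(path, basis = "per_extract") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("basis" %in% names(df)) {
    b <- unique(df$basis)
    if (length(b) != 1L) stop("mixed basis values in ", path)
    basis <- b
    df$basis <- NULL
  }
  pigment_profile(df, basis = basis)
}

#' @rdname read_pigment_table
#' @param profile a `pigment_profile`.
#' @export
write_pigment_table <- function(profile, path) {
  df <- as.data.frame(profile)
  df$basis <- pigment_basis(profile)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write scene ground truth as JSON
#'
#' @param truth the `truth` element of [make_scene()] /
#'   [make_fluorescence()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
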