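#' Species presets for the synthetic-scene generator
#'
#' Two presets emulate the contrasting photophysiology of the
#' kleptoplast-bearing foraminifera this package targets:
#'
#' * `"hg"` (*Haynesina germanica*-like): moderate whole-cell NDVI
#'   (~0.2 scale), a per-chamber degradation gradient so NDVI declines
#'   from the young chambers toward the oldest, Fv/Fm around 0.25,
#'   high-light-acclimated RLC (lower alpha, higher Ek, little
#'   photoinhibition), kleptoplasts spread through the chamber interior.
#' * `"ew"` (*Elphidium williamsoni*-like): roughly twofold higher NDVI
#'   (~0.4 scale) that stays flat beyond the two youngest chambers, Fv/Fm
#'   around 0.46, low-light-acclimated RLC (higher alpha, lower Ek, higher
#'   beta), kleptoplasts concentrated at the chamber periphery.
#'
#' NDVI and Fv/Fm levels follow published whole-cell means for the two
#' species; per-chamber gradient magnitudes are free generator parameters
#' (no quantitative per-chamber values are published) and are documented
#' as such.
#'
#' @param name `"hg"` or `"ew"`.
#' @return List of class `species_preset` with fields `name`,
#'   `chamber_count`, `ndvi_young`, `degradation_gradient`,
#'   `degradation_onset`, `fill` (young-chamber pigment fill factors),
#'   `fvfm_mean`, `alpha`, `beta`, `retr_s`, `layout`, `g507`.
#' @export
species_preset <- function(name = c("hg", "ew")) {
  name <- match.arg(name)
  p <- switch(name,
    hg = list(name = "hg", chamber_count = 9L, ndvi_young = 0.28,
              degradation_gradient = 0.12, degradation_onset = 2L,
              fill = c(0.60, 0.85), fvfm_mean = 0.25,
              alpha = 0.22, beta = 0.004, retr_s = 40, layout = "internal",
              g507 = 0.05),
    ew = list(name = "ew", chamber_count = 11L, ndvi_young = 0.40,
              degradation_gradient = 0.0, degradation_onset = 2L,
              fill = c(0.70, 0.85), fvfm_mean = 0.46,
              alpha = 0.42, beta = 0.025, retr_s = 28, layout = "peripheral",
              g507 = 0.02))
  structure(p, class = "species_preset")
}

# Per-chamber degradation level d(age) in [0, 0.9]
preset_degradation <- function(preset, ages) {
  d <- preset$degradation_gradient *
    pmax(0, ages - preset$degradation_onset)
  pmin(d, 0.9)
}

# Per-chamber pigment fill factor: young chambers are not yet fully
# colonised by kleptoplasts.
preset_fill <- function(preset, ages) {
  f <- rep(1, length(ages))
  f[ages == 0L] <- preset$fill[1]
  f[ages == 1L] <- preset$fill[2]
  f
}

#' Synthetic diatom-type reflectance spectrum
#'
#' Baseline reflectance minus Gaussian absorption dips at the classic
#' diatom pigment features — 450, 585 and 675 nm (Chl a) and 635 nm
#' (Chl c) — whose depths scale with `(1 - d) * pigment`, plus a 507 nm
#' absorption feature whose amplitude scales with the degradation level
#' `d`. Increasing `d` therefore flattens the spectrum (loss of pigment
#' absorption) while raising the 507 nm curvature marker, mimicking
#' pigment-degradation products; NDVI of the generated spectrum decreases
#' monotonically in `d`.
#'
#' @param d degradation level in [0, 1].
#' @param wavelengths wavelength grid (nm).
#' @param pigment pigment-depth scale (dimensionless; depth of the 675 nm
#'   dip for `d = 0` is `0.46 * pigment` of the baseline reflectance).
#' @param g507 amplitude of the 507 nm degradation dip at `d = 1`.
#' @param baseline baseline reflectance fraction (default 0.55).
#' @return A `spectrum` of kind `"reflectance"`.
#' @export
diatom_spectrum <- function(d, wavelengths, pigment = 1, g507 = 0.05,
                            baseline = 0.55) {
  if (d < 0 || d > 1) stop("degradation d must be in [0, 1]")
  dip <- function(centre, depth, width)
    depth * exp(-(wavelengths - centre)^2 / (2 * width^2))
  pig_dips <- dip(450, 0.23, 14) + dip(585, 0.13, 13) +
    dip(635, 0.11, 11) + dip(675, 0.253, 12)
  vals <- baseline - (1 - d) * pigment * pig_dips -
    d * dip(507, g507, 7)
  vals <- pmax(vals, 0)
  spectrum(vals, wavelengths, kind = "reflectance")
}

# Solve the pigment scale so that NDVI(d = 0) hits the preset target for
# the given grid and NDVI band choice (depth is linear in `pigment`).
solve_pigment_scale <- function(ndvi_target, wavelengths, baseline = 0.55,
                                nir_nm = 752, red_nm = 676) {
  i_nir <- band_index(wavelengths, nir_nm)
  i_red <- band_index(wavelengths, red_nm)
  s1 <- as.numeric(diatom_spectrum(0, wavelengths, pigment = 1,
                                   baseline = baseline))
  depth_red_unit <- baseline - s1[i_red]   # dip depth at red band, pigment=1
  nir <- s1[i_nir]                          # ~ baseline (dips negligible)
  red_target <- nir * (1 - ndvi_target) / (1 + ndvi_target)
  (baseline - red_target) / depth_red_unit
}

#' Seeding helpers
#'
#' `with_seed()` evaluates `code` under `set.seed(seed)` and then restores
#' the caller's RNG state, so seeded generators never disturb an enclosing
#' random stream. `sub_seed()` maps a top-level seed and an index to a
#' deterministic per-task seed (kept below 2^31), the scheme used by the
#' pipeline to give every simulated specimen its own reproducible stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate under the seed.
#' @param k integer substream index.
#' @return `with_seed()` returns the value of `code`; `sub_seed()` an
#'   integer seed.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @rdname with_seed
#' @export
sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + k

# Planispiral chamber layout: elliptical chamber masks placed along an
# arc, youngest chamber largest, sizes shrinking with age.
spiral_chamber_map <- function(chamber_count, shape) {
  nr <- shape[1]; nc <- shape[2]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  ring <- 0.36 * min(nr, nc)
  theta0 <- -pi / 2
  dtheta <- 2 * pi * 0.85 / chamber_count
  a0 <- 0.88 * ring * sin(dtheta / 2)
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  masks <- vector("list", chamber_count)
  for (k in seq_len(chamber_count)) {
    age <- k - 1L
    th <- theta0 + age * dtheta
    r <- ring * (1 - 0.12 * age / chamber_count)
    mr <- cx + r * sin(th)
    mc <- cy + r * cos(th)
    a <- a0 * 0.97^age
    b <- 0.8 * a
    # ellipse axes aligned radially
    u <- ((row_idx - mr) * sin(th) + (col_idx - mc) * cos(th)) / a
    v <- ((row_idx - mr) * cos(th) - (col_idx - mc) * sin(th)) / b
    m <- u^2 + v^2 <= 1
    if (!any(m)) stop("chamber ", age, " fell outside the image")
    if (any(row_idx[m] < 1 | row_idx[m] > nr))
      stop("chamber exceeds image bounds")
    masks[[k]] <- m
  }
  chamber_map_from_masks(masks)
}

#' Generate a synthetic hyperspectral scene with ground truth
#'
#' Builds a planispiral arrangement of elliptical chamber masks, assigns
#' each chamber a degradation level from the preset's age profile, and
#' renders raw sample/white/dark stacks such that white/dark calibration
#' recovers the programmed reflectance spectra exactly at zero noise. The
#' peripheral layout concentrates pigment signal at chamber rims, the
#' internal layout spreads it uniformly.
#'
#' @param preset a `species_preset` (or preset name).
#' @param shape image shape c(rows, cols); default c(96, 128).
#' @param wavelengths wavelength grid; default 400-800 nm in 2 nm steps.
#' @param noise_sd multiplicative noise sigma on the sample stack
#'   (default 0.02); 0 gives an exact round trip.
#' @param jitter_d specimen-level sd of per-chamber degradation jitter
#'   (default 0.02), emulating between-specimen variability.
#' @param seed integer seed; same seed, same scene.
#' @return List with `sample`, `white`, `dark` (raw `hyper_cube`s), `map`
#'   (`chamber_map`), and `truth`: preset name, seed, per-chamber
#'   `age_index`, `d`, `fill`, `ndvi` (noise-free NDVI at the NDVI bands),
#'   and the preset RLC parameters.
#' @export
make_scene <- function(preset, shape = c(96L, 128L),
                       wavelengths = seq(400, 800, by = 2),
                       noise_sd = 0.02, jitter_d = 0.02, seed = 1L) {
  if (is.character(preset)) preset <- species_preset(preset)
  if (preset$chamber_count < 2L) stop("need at least 2 chambers")
  validate_grid(wavelengths)
  map <- spiral_chamber_map(preset$chamber_count, shape)
  ages <- seq_len(preset$chamber_count) - 1L
  baseline <- 0.55
  pig <- solve_pigment_scale(preset$ndvi_young, wavelengths, baseline)

  with_seed(sub_seed(seed, 1L), {
    d <- pmin(pmax(preset_degradation(preset, ages) +
                     stats::rnorm(length(ages), 0, jitter_d), 0), 1)
    fill <- preset_fill(preset, ages)

    nb <- length(wavelengths)
    nr <- shape[1]; nc <- shape[2]
    # noise-free true reflectance per chamber
    spectra <- lapply(seq_along(ages), function(k)
      as.numeric(diatom_spectrum(d[k], wavelengths, pigment = pig * fill[k],
                                 g507 = preset$g507, baseline = baseline)))
    i_nir <- band_index(wavelengths, 752)
    i_red <- band_index(wavelengths, 676)
    true_ndvi <- vapply(spectra, function(s)
      (s[i_nir] - s[i_red]) / (s[i_nir] + s[i_red]), 1)

    # spatial weighting of the pigment signal within each chamber
    refl <- array(0.15, dim = c(nr, nc, nb))  # dull background
    row_idx <- matrix(seq_len(nr), nr, nc)
    col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    bg <- rep(0.15, nb)
    for (k in seq_along(ages)) {
      m <- chamber_mask(map, ages[k])
      w <- rep(1, sum(m))
      if (preset$layout == "peripheral") {
        # weight pigment toward the mask rim: distance rank from centroid
        rr <- row_idx[m]; cc <- col_idx[m]
        dist <- sqrt((rr - mean(rr))^2 + (cc - mean(cc))^2)
        w <- 0.4 + 0.6 * (rank(dist) / length(dist))^2 * 2
        w <- w / mean(w)  # chamber mean spectrum stays the programmed one
      }
      for (b in seq_len(nb)) {
        plane <- refl[, , b]
        plane[m] <- bg[b] + w * (spectra[[k]][b] - bg[b])
        refl[, , b] <- plane
      }
    }
    refl <- pmax(refl, 0)

    # noise-free per-pixel NDVI and its chamber means: the round-trip truth
    ndvi_px <- (refl[, , i_nir] - refl[, , i_red]) /
      (refl[, , i_nir] + refl[, , i_red])
    ndvi_chamber <- vapply(ages, function(a)
      mean(ndvi_px[chamber_mask(map, a)]), 1)

    # illumination field and instrument stacks
    rad2 <- ((row_idx - (nr + 1) / 2) / nr)^2 +
      ((col_idx - (nc + 1) / 2) / nc)^2
    illum <- 1 - 0.3 * rad2 / max(rad2)
    lamp <- 1 + 0.2 * (wavelengths - 600) / 400
    dark_level <- 100
    white <- array(0, dim = c(nr, nc, nb))
    for (b in seq_len(nb))
      white[, , b] <- dark_level + 3000 * illum * lamp[b]
    dark <- array(dark_level, dim = c(nr, nc, nb))
    noise <- if (noise_sd > 0)
      array(pmax(1 + stats::rnorm(nr * nc * nb, 0, noise_sd), 0),
            dim = c(nr, nc, nb)) else 1
    sample <- dark + (white - dark) * refl * noise

    list(sample = hyper_cube(sample, wavelengths, "raw"),
         white = hyper_cube(white, wavelengths, "raw"),
         dark = hyper_cube(dark, wavelengths, "raw"),
         map = map,
         truth = list(preset = preset$name, seed = seed,
                      age_index = ages, d = d, fill = fill,
                      ndvi = ndvi_chamber, ndvi_px = ndvi_px,
                      ndvi_spectrum = true_ndvi,
                      rlc = list(alpha = preset$alpha, beta = preset$beta,
                                 retr_s = preset$retr_s)))
  })
}

#' Generate a synthetic PAM fluorescence sequence with ground truth
#'
#' Per pixel, the effective PSII quantum yield at each irradiance is taken
#' from the preset's RLC parameters, phi(PAR) = model_retr(PAR)/PAR; the
#' saturating-pulse image F'm declines with irradiance following a
#' quenching profile, and F = F'm (1 - phi). The dark pair is built from
#' the preset Fv/Fm and a per-chamber F0 pattern (default: the preset's
#' NDVI-like age profile, so F0 mirrors the chlorophyll distribution).
#' Gaussian noise is added to all fluorescence images.
#'
#' @param preset `species_preset` or name.
#' @param map `chamber_map` for the specimen.
#' @param f0_pattern per-chamber relative F0 levels (length = number of
#'   chambers); default derived from the preset degradation profile.
#' @param par_ladder actinic irradiance steps; default
#'   [default_par_ladder()].
#' @param noise_sd Gaussian noise sd as a fraction of the dark-acclimated
#'   Fm level (default 0.02); 0 gives an exact round trip.
#' @param seed integer seed.
#' @return List with `seq` (a `fluor_sequence`) and `truth` (RLC params,
#'   fvfm, f0 pattern, seed).
#' @export
make_fluorescence <- function(preset, map, f0_pattern = NULL,
                              par_ladder = default_par_ladder(),
                              noise_sd = 0.02, seed = 1L) {
  if (is.character(preset)) preset <- species_preset(preset)
  if (!inherits(map, "chamber_map")) stop("`map` is not a chamber_map")
  ages <- seq_len(n_chambers(map)) - 1L
  if (is.null(f0_pattern)) {
    d <- preset_degradation(preset, ages)
    f0_pattern <- preset_fill(preset, ages) * (1 - d)
  }
  if (length(f0_pattern) != length(ages))
    stop("f0_pattern length must equal the chamber count")
  phi <- vapply(par_ladder, function(p)
    model_retr(p, preset$alpha, preset$beta, preset$retr_s) / p, 1)
  if (any(phi <= 0 | phi >= 1))
    stop("preset RLC parameters imply phiPSII outside (0, 1)")
  if (preset$fvfm_mean <= 0 || preset$fvfm_mean >= 1)
    stop("fvfm_mean must be in (0, 1)")

  with_seed(sub_seed(seed, 2L), {
    shape <- dim(unclass(map))
    f0_base <- 400
    f0 <- matrix(0, shape[1], shape[2])
    for (k in seq_along(ages))
      f0[chamber_mask(map, ages[k])] <- f0_base * f0_pattern[k]
    fm <- f0 / (1 - preset$fvfm_mean)
    quench <- function(p) exp(-p / 600)   # NPQ-like F'm decline
    steps <- lapply(seq_along(par_ladder), function(j) {
      fmp <- fm * quench(par_ladder[j])
      f <- fmp * (1 - phi[j])
      list(par = par_ladder[j], f_img = f, fmp_img = fmp)
    })
    if (noise_sd > 0) {
      sdn <- noise_sd * max(fm)
      jiggle <- function(m) m + matrix(stats::rnorm(length(m), 0, sdn),
                                       nrow(m), ncol(m))
      f0 <- jiggle(f0); fm <- jiggle(fm)
      steps <- lapply(steps, function(s)
        list(par = s$par, f_img = jiggle(s$f_img),
             fmp_img = jiggle(s$fmp_img)))
    }
    list(seq = fluor_sequence(f0, fm, steps),
         truth = list(preset = preset$name, seed = seed,
                      alpha = preset$alpha, beta = preset$beta,
                      retr_s = preset$retr_s,
                      retr_max = retr_max(preset$alpha, preset$beta,
                                          preset$retr_s),
                      ek = rlc_ek(preset$alpha, preset$beta, preset$retr_s),
                      fvfm = preset$fvfm_mean, f0_pattern = f0_pattern,
                      phi = phi, par = par_ladder))
  })
}

#' Reference per-cell pigment contents for the two species
#'
#' Published whole-cell HPLC means (ng cell^-1, mean and SE over 3
#' replicate extracts of 100 pooled specimens) for *H. germanica* and
#' *E. williamsoni*, used as generator defaults. The partition of the
#' total degradation-product pool into phaeophytins and the two
#' fucoxanthin-like products is not published; the split used here is
#' synthetic and only its sum is meaningful.
#'
#' @return List with per-species `mean` and `se` named numeric vectors.
#' @export
foram_pigment_reference <- function() {
  list(
    hg = list(
      mean = c(chl_a = 14.56, chl_c = 1.60, fuco = 6.16, dd = 1.03,
               dt = 0.55, phaeophytins = 3.00, fuco_like_1 = 1.50,
               fuco_like_2 = 0.75),
      se = c(chl_a = 1.32, chl_c = 0.10, fuco = 0.37, dd = 0.09,
             dt = 0.03, phaeophytins = 0.60, fuco_like_1 = 0.30,
             fuco_like_2 = 0.12)),
    ew = list(
      mean = c(chl_a = 18.72, chl_c = 1.19, fuco = 5.32, dd = 1.36,
               dt = 0.56, phaeophytins = 1.00, fuco_like_1 = 0.60,
               fuco_like_2 = 0.32),
      se = c(chl_a = 2.80, chl_c = 0.18, fuco = 0.69, dd = 0.30,
             dt = 0.10, phaeophytins = 0.20, fuco_like_1 = 0.10,
             fuco_like_2 = 0.04)))
}

#' Generate a synthetic replicate pigment table
#'
#' Draws per-replicate extract masses from a truncated-at-zero normal with
#' the requested per-cell mean and between-replicate SE (sd = SE * sqrt(n
#' replicates)), on a per-extract basis (ng per pooled extract of
#' `n_specimens` cells). With `se = 0` the per-cell means reproduce the
#' inputs exactly.
#'
#' @param species_means named list: per species, a named vector of
#'   per-cell pigment means (ng cell^-1). Default
#'   [foram_pigment_reference()] means.
#' @param species_ses matching list of SEs (default the reference SEs;
#'   use 0 for exact tables).
#' @param n_replicates replicates per species (default 3).
#' @param n_specimens pooled specimens per extract (default 100).
#' @param seed integer seed.
#' @return A `pigment_profile` on the `per_extract` basis.
#' @export
make_pigment_table <- function(species_means = NULL, species_ses = NULL,
                               n_replicates = 3L, n_specimens = 100L,
                               seed = 1L) {
  ref <- foram_pigment_reference()
  if (is.null(species_means))
    species_means <- lapply(ref, `[[`, "mean")
  if (is.null(species_ses))
    species_ses <- lapply(ref, `[[`, "se")
  with_seed(sub_seed(seed, 3L), {
    rows <- list()
    for (sp in names(species_means)) {
      mu <- species_means[[sp]]
      se <- species_ses[[sp]]
      if (length(se) == 1L) se <- stats::setNames(rep(se, length(mu)),
                                                  names(mu))
      for (r in seq_len(n_replicates)) {
        per_cell_mass <- pmax(
          mu + stats::rnorm(length(mu), 0, se[names(mu)] *
                              sqrt(n_replicates)), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, species = sp, n_specimens = n_specimens,
          pigment = names(mu),
          mass_ng = unname(per_cell_mass) * n_specimens,
          stringsAsFactors = FALSE)
      }
    }
    pigment_profile(do.call(rbind, rows), basis = "per_extract")
  })
}
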