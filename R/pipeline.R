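#' Default run configuration
#'
#' Band choices (NIR 752 nm, red 676 nm, degradation index 507 nm), the
#' nine-step actinic ladder, 5-band derivative smoothing and the 5%
#' significance level are the package-wide defaults.
#'
#' @param ... overrides of the default fields.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    out_dir = "kleptophys-out",
    seed = 1L,
    nir_nm = 752, red_nm = 676, dd_nm = 507,
    smooth_window = 5L,
    par_ladder = default_par_ladder(),
    alpha_level = 0.05,
    simulate = list(presets = c("hg", "ew"), n_specimens = 6L,
                    shape = c(96L, 128L), noise_sd = 0.02),
    inputs = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Process one specimen (spectral + fluorescence side)
#'
#' Calibrates the stacks, computes the NDVI and degradation-index images,
#' per-chamber NDVI profile, whole-cell means, Fv/Fm image and the
#' whole-cell RLC fit.
#'
#' @param sample,white,dark raw `hyper_cube`s.
#' @param map `chamber_map`.
#' @param fluor optional `fluor_sequence` for the same specimen.
#' @param config a `run_config`.
#' @return List with `ndvi_profile`, `ndvi_mean`, `dd507_mean`,
#'   `fvfm_mean`, `fvfm_profile`, `rlc_fit` (the last three `NULL`
#'   without `fluor`).
#' @export
process_specimen <- function(sample, white, dark, map, fluor = NULL,
                             config = run_config()) {
  refl <- calibrate_reflectance(sample, white, dark)
  ndvi <- ndvi_image(refl, nir_nm = config$nir_nm, red_nm = config$red_nm)
  prof <- per_chamber_mean(ndvi, map)
  cell <- unclass(map) > 0L
  dd_img <- dd507(refl, smooth_window = config$smooth_window,
                  at_nm = config$dd_nm)
  out <- list(
    ndvi_profile = prof,
    ndvi_mean = mean(unclass(ndvi)[cell], na.rm = TRUE),
    dd507_mean = mean(unclass(dd_img)[cell], na.rm = TRUE),
    fvfm_mean = NULL, fvfm_profile = NULL, rlc_fit = NULL)
  if (!is.null(fluor)) {
    fvfm <- fv_fm_image(fluor$f0_img, fluor$fm_img)
    out$fvfm_mean <- mean(unclass(fvfm)[cell], na.rm = TRUE)
    out$fvfm_profile <- per_chamber_mean(fvfm, map)
    out$rlc_fit <- fit_rlc(build_rlc(fluor, cell, roi = "whole-cell"))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulation mode (the default config): for each species preset,
#' generates `n_specimens` synthetic specimens (hyperspectral scene +
#' fluorescence sequence), runs the spectral side (calibration, NDVI,
#' degradation index, per-chamber profiles, chamber-gradient ANOVA +
#' Tukey), the fluorescence side (Fv/Fm, RLC build + fit), the pigment
#' side (synthetic replicate table, per-cell contents, ratio indices,
#' Wilcoxon species comparison), and the between-species tests (Welch t on
#' NDVI; Welch t on arcsine-transformed Fv/Fm). All tables are written as
#' CSV under `config$out_dir` along with a JSON run manifest (config echo,
#' package version, output checksums, warnings). Deterministic given
#' config + seed.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character()
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))

  specimens <- withCallingHandlers(
    collect_specimens(config), warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    })

  profiles <- list(); summary_rows <- list(); rlc_rows <- list()
  for (sp in names(specimens)) {
    res <- specimens[[sp]]
    profiles[[sp]] <- lapply(res, `[[`, "ndvi_profile")
    for (i in seq_along(res)) {
      r <- res[[i]]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        species = sp, specimen = i, ndvi = r$ndvi_mean,
        dd507 = r$dd507_mean,
        fvfm = r$fvfm_mean %||% NA_real_)
      if (!is.null(r$rlc_fit))
        rlc_rows[[length(rlc_rows) + 1L]] <- data.frame(
          species = sp, specimen = i, roi = "whole-cell",
          t(coef(r$rlc_fit)), rss = r$rlc_fit$rss,
          converged = r$rlc_fit$converged)
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  rlc_df <- if (length(rlc_rows)) do.call(rbind, rlc_rows) else NULL

  gradient <- lapply(profiles, function(p)
    withCallingHandlers(gradient_test(p), warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }))

  species <- unique(summary_df$species)
  stats_rows <- list()
  if (length(species) == 2L) {
    g <- function(col, s) summary_df[summary_df$species == s, col]
    nd <- welch_t(g("ndvi", species[1]), g("ndvi", species[2]))
    stats_rows[[1]] <- data.frame(test = "NDVI Welch t",
                                  statistic = nd$statistic,
                                  df = nd$df, p.value = nd$p.value)
    if (!all(is.na(summary_df$fvfm))) {
      fv <- welch_t(arcsine_transform(g("fvfm", species[1])),
                    arcsine_transform(g("fvfm", species[2])))
      stats_rows[[2]] <- data.frame(test = "Fv/Fm Welch t (arcsine)",
                                    statistic = fv$statistic,
                                    df = fv$df, p.value = fv$p.value)
    }
  }
  for (sp in names(gradient)) {
    an <- gradient[[sp]]$anova
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      test = paste0("NDVI chamber ANOVA [", sp, "]"),
      statistic = an$statistic, df = paste(an$df, collapse = ","),
      p.value = an$p.value)
  }
  stats_df <- do.call(rbind, lapply(stats_rows, function(d) {
    d$df <- as.character(d$df); d
  }))

  # pigment side
  pig <- make_pigment_table(seed = config$seed)
  idx <- pigment_indices(per_cell(pig))
  pig_tests <- withCallingHandlers(
    compare_pigment_groups(idx, alpha = config$alpha_level),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })

  paths <- c(
    summary = write_out(summary_df, config, "specimen_summary.csv"),
    rlc = if (!is.null(rlc_df)) write_out(rlc_df, config, "rlc_fits.csv"),
    stats = write_out(stats_df, config, "stats.csv"),
    indices = write_out(idx, config, "pigment_indices.csv"),
    pig_tests = write_out(pig_tests, config, "pigment_tests.csv"))
  for (sp in names(profiles)) {
    stacked <- do.call(rbind, lapply(seq_along(profiles[[sp]]), function(i) {
      p <- as.data.frame(profiles[[sp]][[i]]); p$specimen <- i; p
    }))
    paths[[paste0("profile_", sp)]] <-
      write_out(stacked, config, sprintf("ndvi_profile_%s.csv", sp))
    lt <- gradient[[sp]]$tukey$letters
    paths[[paste0("tukey_", sp)]] <- write_out(
      data.frame(age_index = names(lt), letters = unname(lt)),
      config, sprintf("tukey_%s.csv", sp))
  }

  manifest <- list(
    package = "kleptophys",
    version = as.character(utils::packageVersion("kleptophys")),
    config = unclass(config),
    outputs = as.list(tools::md5sum(unlist(paths))),
    warnings = warn_log)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary_df, rlc = rlc_df, stats = stats_df,
                 gradient = gradient, pigment_indices = idx,
                 pigment_tests = pig_tests, manifest = manifest))
}

write_out <- function(df, config, name) {
  p <- file.path(config$out_dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}

# simulate (or load) the per-specimen inputs and process them
collect_specimens <- function(config) {
  out <- list()
  if (!is.null(config$inputs)) {
    for (spec in config$inputs) {
      sample <- read_cube(spec$sample); white <- read_cube(spec$white)
      dark <- read_cube(spec$dark); map <- read_chamber_map(spec$map)
      fluor <- if (!is.null(spec$fluorescence))
        read_fluor_sequence(spec$fluorescence)
      sp <- spec$species %||% "specimen"
      out[[sp]] <- c(out[[sp]], list(process_specimen(
        sample, white, dark, map, fluor, config)))
    }
    return(out)
  }
  sim <- config$simulate
  for (preset_name in sim$presets) {
    preset <- species_preset(preset_name)
    res <- lapply(seq_len(sim$n_specimens), function(i) {
      sseed <- sub_seed(config$seed, 100L * match(preset_name,
                                                  sim$presets) + i)
      scene <- make_scene(preset, shape = sim$shape,
                          noise_sd = sim$noise_sd, seed = sseed)
      fl <- make_fluorescence(preset, scene$map,
                              par_ladder = config$par_ladder,
                              noise_sd = sim$noise_sd, seed = sseed)
      process_specimen(scene$sample, scene$white, scene$dark, scene$map,
                       fl$seq, config)
    })
    out[[preset_name]] <- res
  }
  out
}
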