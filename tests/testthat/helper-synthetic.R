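# shared fixtures, all generated in code

tiny_grid <- function(step = 4) seq(400, 800, by = step)

# uniform-valued raw cube triple for calibration tests
flat_cubes <- function(nr = 4, nc = 5, wl = tiny_grid(80), s = 500,
                       w = 900, d = 100) {
  mk <- function(v) hyper_cube(array(v, dim = c(nr, nc, length(wl))), wl)
  list(sample = mk(s), white = mk(w), dark = mk(d))
}

# small synthetic scene used across test files
quick_scene <- function(preset = "hg", noise_sd = 0, jitter_d = 0,
                        seed = 1, shape = c(64L, 88L),
                        wavelengths = tiny_grid(2)) {
  make_scene(preset, shape = shape, wavelengths = wavelengths,
             noise_sd = noise_sd, jitter_d = jitter_d, seed = seed)
}

# reference per-cell pigment means as a per_cell pigment_profile with one
# pseudo-replicate per species (for ratio-of-means computations)
reference_mean_profile <- function() {
  ref <- foram_pigment_reference()
  rows <- do.call(rbind, lapply(names(ref), function(sp)
    data.frame(replicate = 1L, species = sp, n_specimens = 100L,
               pigment = names(ref[[sp]]$mean),
               mass_ng = unname(ref[[sp]]$mean))))
  pigment_profile(rows, basis = "per_cell")
}
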