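# Shared fixtures: all inputs are generated in code at test time.

# compact phantom for fast Monte Carlo tests (1 mm voxels)
small_phantom <- function(voxel_mm = 1, with_inclusion = TRUE) {
  ph <- build_spine_phantom(voxel_mm = voxel_mm, diameter_mm = 12,
                            length_mm = 20, disc_thickness_mm = 4,
                            cord_diameter_mm = 3, margin_mm = 4)
  if (with_inclusion) ph <- place_inclusion(ph, center_mm = c(3, 0, 0))
  ph
}

# detector grid that fits the small phantom's face
small_detgrid <- function() detector_grid(ny = 4, nz = 5, pitch_mm = 2.48)

# one consistent Green's-function set on the small phantom (shared by
# jacobian / inversion consistency tests); cached per session
.small_greens_env <- new.env(parent = emptyenv())
small_greens <- function(n_photons = 3e4, seed = 11, n_patterns = 4,
                         group = c(2, 3)) {
  key <- sprintf("g_%g_%d_%d_%d%d", n_photons, seed, n_patterns,
                 group[1], group[2])
  if (!is.null(.small_greens_env[[key]])) return(.small_greens_env[[key]])
  ph <- small_phantom()
  detg <- small_detgrid()
  sp <- superpatch_layout(detg, group[1], group[2])
  exc <- simulate_excitation(ph, n_photons, seed, detectors = detg,
                             n_patterns = n_patterns, pattern_width_mm = 6,
                             nt = 96)
  gm <- lapply(seq_len(sp$n_patches), function(s)
    adjoint_emission_greens(ph, sp$patches[[s]], n_photons,
                            derive_seed(seed, 7L, s), nt = 96))
  out <- list(ph = ph, detg = detg, sp = sp, exc = exc, gm = gm,
              u0 = cw_from_tpsf(exc$tpsf),
              eta = ph$eta[tissue_indices(ph)],
              n_patterns = n_patterns, nt = 96)
  .small_greens_env[[key]] <- out
  out
}

# full desk-scale study, run once and reused by the acceptance tests
.study_env <- new.env(parent = emptyenv())
cached_study <- function() {
  if (is.null(.study_env$report)) {
    .study_env$report <- run_study(study_config(seed = 1), verbose = FALSE)
  }
  .study_env$report
}
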