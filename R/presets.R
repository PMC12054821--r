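## Named acquisition presets.
##
## Each preset bundles a generator configuration and generator arguments
## emulating one of the study's acquisition conditions. The expansion-strain
## law (linear then saturating) is a package stand-in consistent with the
## observed temperature-dependent equilibrium, not a measured law; its
## preset constants are documented here and in the methods vignette.

preset_table <- function() list(
  ## gold-nanoparticle tracking in 300 nm holes: 0.7 e-/A^2/frame.
  ## 13 K: expansion strain 1e-3 per e-/A^2 saturating at 5 e-/A^2;
  ## 81 K: no expansion, jitter only.
  tracks_13K = function(seed) {
    cfg <- generator_config(seed = seed, n_frames = 20, fluence_per_frame = 0.7,
                            noise_level = 0, hole_diameter = 300,
                            model = list(sigma0_sq = 0.012))
    gen_expanding_tracks(cfg, n_particles = 25, strain_rate = 1e-3,
                         saturation_fluence = 5)
  },
  tracks_81K = function(seed) {
    cfg <- generator_config(seed = seed, n_frames = 20, fluence_per_frame = 0.7,
                            noise_level = 0, hole_diameter = 300,
                            model = list(sigma0_sq = 0.012))
    gen_expanding_tracks(cfg, n_particles = 25, strain_rate = 0,
                         saturation_fluence = 5)
  },
  ## 13 K diffraction series: 0.25 e-/A^2/frame, 50 frames; the water ring
  ## moves 3.7 -> 3.3 A over the first 5 e-/A^2 while broadening and
  ## weakening; gold (111) reference ring present.
  diffraction_13K = function(seed) {
    cfg <- generator_config(seed = seed, n_frames = 50,
                            fluence_per_frame = 0.25, noise_level = 0.02)
    s <- pmin(fluence_axis(cfg), 5) / 5
    gen_diffraction_profile(cfg,
                            peak_center_series = 3.7 - 0.4 * s,
                            peak_width_series = 0.012 + 0.008 * s,
                            amplitude_series = 40 - 15 * s,
                            gold = TRUE)
  },
  ## low-density amorphous water EELS: 0.1 eV dispersion, plasmon at
  ## 20.4 eV; returns 9 spectra (independent sub-seeds).
  eels_LDA = function(seed) {
    lapply(seq_len(9), function(i) {
      cfg <- generator_config(seed = seed + i, noise_level = 0.02)
      gen_eels_spectrum(cfg, plasmon_center = 20.4)
    })
  },
  ## per-frame FSC series, 0.63 e-/A^2/frame, first 30 frames, noiseless.
  ## 81 K decay rate 5 A^2/(e-/A^2); 13 K is 1.5x slower.
  fsc_81K = function(seed) {
    cfg <- generator_config(seed = seed, n_frames = 30,
                            fluence_per_frame = 0.63, noise_level = 0)
    gen_fsc_series(cfg, b_rate = 5)
  },
  fsc_13K = function(seed) {
    cfg <- generator_config(seed = seed, n_frames = 30,
                            fluence_per_frame = 0.63, noise_level = 0)
    gen_fsc_series(cfg, b_rate = 5 / 1.5)
  },
  ## frame-grouped power-spectrum peak intensities: 200 frames at
  ## 0.375 e-/A^2/frame, peak at 3.7 A (u = 0.27 A^-1).
  brownian = function(seed) {
    cfg <- generator_config(seed = seed, fluence_per_frame = 0.375,
                            noise_level = 0)
    gen_brownian_peak_series(cfg, sigma0_sq = 0.012, u = 0.27, M = 200)
  },
  ## gold-111 spot power versus defocus, -10..0 um in 1 um steps, 300 keV.
  defocus = function(seed) {
    cfg <- generator_config(seed = seed, noise_level = 0)
    gen_defocus_series(cfg, alpha = 5e-5)
  }
)

#' Generate data from a named acquisition preset
#'
#' Presets fix the generator parameters to the package's documented study
#' conditions; only the seed varies.
#'
#' @param name one of `"tracks_13K"`, `"tracks_81K"`, `"diffraction_13K"`,
#'   `"eels_LDA"`, `"fsc_81K"`, `"fsc_13K"`, `"brownian"`, `"defocus"`.
#' @param seed integer RNG seed.
#' @return the generated data object for that preset (a list of 9 spectra
#'   for `"eels_LDA"`).
#' @examples
#' fsc <- gen_preset("fsc_81K", seed = 1)
#' @export
gen_preset <- function(name, seed = 1L) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset; see ?gen_preset for the available names")
  tab[[name]](as.integer(seed))
}
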