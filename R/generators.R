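## Seeded synthetic-data generators.
##
## Every analysis stage in the package consumes either coordinate tracks,
## 1-D profiles/spectra, per-frame FSC curves, frame-grouped power-spectrum
## peak intensities, or defocus series.  The generators below produce all of
## these with the statistical structure the estimators assume, as pure
## functions of (seed, config), so the whole pipeline is testable without
## microscope data.

#' Generator configuration
#'
#' Shared configuration for all synthetic-data generators: the fluence axis,
#' the noise scale and the specimen geometry.
#'
#' Frame `f` carries the cumulative fluence at its midpoint,
#' `F_f = fluence_per_frame * (f - 1/2)`, which is unbiased for
#' linear-in-dose models.
#'
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   output.
#' @param n_frames number of movie frames, >= 1.
#' @param fluence_per_frame electron fluence per frame in e-/A^2, > 0.
#' @param noise_level dimensionless relative noise standard deviation;
#'   0 produces noiseless data.
#' @param hole_diameter support-foil hole diameter in nm.
#' @param tilt_angle stage tilt in degrees, in \[0, 90).
#' @param tilt_axis unit 2-vector of the tilt axis in the image plane.
#' @param model named list of model parameters specific to each generator
#'   (e.g. `sigma0_sq`, the pseudo-Brownian mean-squared displacement per
#'   unit fluence in A^2/(e-/A^2)).
#' @return object of class `"generator_config"`.
#' @examples
#' cfg <- generator_config(seed = 1, n_frames = 20, fluence_per_frame = 0.7)
#' fluence_axis(cfg)
#' @export
generator_config <- function(seed = 1L, n_frames = 50L, fluence_per_frame = 0.25,
                             noise_level = 0.02, hole_diameter = 300,
                             tilt_angle = 0, tilt_axis = c(1, 0),
                             model = list()) {
  stopifnot_scalar(fluence_per_frame, "fluence_per_frame", positive = TRUE)
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  if (noise_level < 0) stop("'noise_level' must be >= 0")
  if (tilt_angle < 0 || tilt_angle >= 90) stop("'tilt_angle' must be in [0, 90)")
  if (length(tilt_axis) != 2L || all(tilt_axis == 0))
    stop("'tilt_axis' must be a nonzero 2-vector")
  structure(list(
    seed = as.integer(seed), n_frames = as.integer(n_frames),
    fluence_per_frame = fluence_per_frame, noise_level = noise_level,
    hole_diameter = hole_diameter, tilt_angle = tilt_angle,
    tilt_axis = tilt_axis / sqrt(sum(tilt_axis^2)), model = model
  ), class = "generator_config")
}

#' @rdname generator_config
#' @param cfg a `generator_config`.
#' @export
fluence_axis <- function(cfg) {
  cfg$fluence_per_frame * (seq_len(cfg$n_frames) - 0.5)
}

## in-plane unit normal of the tilt axis (the direction along which projected
## out-of-plane motion appears)
tilt_normal <- function(tilt_axis) c(-tilt_axis[2], tilt_axis[1])

#' Simulate radially expanding particle tracks
#'
#' Places `n_particles` uniformly in a disc of the configured hole diameter
#' and displaces each radially from the hole centre by the cumulative strain
#' `eps(F) = strain_rate * min(F, saturation_fluence)`, emulating the
#' irradiation-driven expansion of low-temperature amorphous water. Isotropic
#' pseudo-Brownian jitter (a random walk with per-frame, per-axis variance
#' `sigma0_sq * fluence_per_frame`, with `sigma0_sq` from `cfg$model`,
#' default 0.01 A^2/(e-/A^2)) is superimposed, plus an optional out-of-plane
#' component projected into the image as `z * sin(tilt)` along the in-plane
#' normal of the tilt axis.
#'
#' `strain_rate = 0` emulates liquid-nitrogen temperature (no expansion) and
#' is accepted.
#'
#' @param cfg a [generator_config()].
#' @param n_particles number of particles, >= 2.
#' @param strain_rate dimensionless strain per e-/A^2.
#' @param saturation_fluence fluence (e-/A^2) beyond which the strain stops
#'   accumulating.
#' @param out_of_plane_fraction out-of-plane displacement as a fraction of
#'   the in-plane radial expansion at the hole rim.
#' @return object of class `"particle_tracks"`: per-frame x/y matrices in
#'   Angstroms (frames x particles), the fluence axis, tilt and hole geometry.
#' @examples
#' cfg <- generator_config(seed = 2, n_frames = 10, fluence_per_frame = 0.7,
#'                         noise_level = 0)
#' tr <- gen_expanding_tracks(cfg, n_particles = 10, strain_rate = 1e-3,
#'                            saturation_fluence = 5)
#' @export
gen_expanding_tracks <- function(cfg, n_particles = 25, strain_rate = 1e-3,
                                 saturation_fluence = 5,
                                 out_of_plane_fraction = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  if (n_particles < 2) stop("'n_particles' must be >= 2")
  if (strain_rate < 0) stop("'strain_rate' must be >= 0")
  R <- cfg$hole_diameter * 10 / 2                    # nm -> A, radius
  hole_center <- c(2 * R, 2 * R)                     # image corner origin
  d <- cfg$fluence_per_frame
  fl <- fluence_axis(cfg)
  eps <- strain_rate * pmin(fl, saturation_fluence)
  sigma0_sq <- cfg$model$sigma0_sq %||% 0.01
  nhat <- tilt_normal(cfg$tilt_axis)
  sin_t <- sin(cfg$tilt_angle * pi / 180)

  with_seed(cfg$seed, {
    r0 <- R * sqrt(runif(n_particles))
    phi <- 2 * pi * runif(n_particles)
    px <- r0 * cos(phi); py <- r0 * sin(phi)
    sdw <- sqrt(sigma0_sq * d)
    jx <- apply(matrix(rnorm(cfg$n_frames * n_particles, sd = sdw),
                       cfg$n_frames), 2, cumsum)
    jy <- apply(matrix(rnorm(cfg$n_frames * n_particles, sd = sdw),
                       cfg$n_frames), 2, cumsum)
    if (cfg$n_frames == 1L) { jx <- matrix(jx, 1); jy <- matrix(jy, 1) }
    z <- outer(eps * R * out_of_plane_fraction, rep(1, n_particles))
    x <- hole_center[1] + outer(1 + eps, px) + jx + z * sin_t * nhat[1]
    y <- hole_center[2] + outer(1 + eps, py) + jy + z * sin_t * nhat[2]
    particle_tracks(x, y, fluence_per_frame = d, tilt_angle = cfg$tilt_angle,
                    tilt_axis = cfg$tilt_axis, hole_center = hole_center,
                    hole_diameter = cfg$hole_diameter)
  })
}

#' Simulate a dose-dependent diffraction profile series
#'
#' Per-frame 1-D radial diffraction profiles on a spatial-frequency grid
#' `q = 1/spacing` (A^-1): a Voigt ring whose centre/width/amplitude follow
#' the supplied per-frame series, a linear background, an optional gold (111)
#' reference ring at 2.35 A, and Gaussian noise with variance proportional
#' to the signal (counting-statistics surrogate).
#'
#' @param cfg a [generator_config()].
#' @param peak_center_series per-frame ring position in A spacing (recycled
#'   to `n_frames`).
#' @param peak_width_series per-frame Voigt Gaussian width in A^-1 (the
#'   Lorentzian half-width is taken as half of it).
#' @param amplitude_series per-frame ring area (counts x A^-1).
#' @param background length-2 numeric `c(intercept, slope)` of the linear
#'   background in q.
#' @param q_grid ascending spatial-frequency grid in A^-1.
#' @param gold logical; add a fixed Voigt ring at 2.35 A spacing.
#' @param gold_amplitude area of the gold ring.
#' @return object of class `"radial_profile_series"`: the grid, an
#'   intensity matrix (frames x q) and the fluence axis.
#' @examples
#' cfg <- generator_config(seed = 1, n_frames = 4, noise_level = 0)
#' ps <- gen_diffraction_profile(cfg, peak_center_series = 3.7,
#'                               peak_width_series = 0.012,
#'                               amplitude_series = 40)
#' @export
gen_diffraction_profile <- function(cfg, peak_center_series,
                                    peak_width_series = 0.012,
                                    amplitude_series = 40,
                                    background = c(30, -20),
                                    q_grid = seq(0.16, 0.55, by = 0.002),
                                    gold = FALSE, gold_amplitude = 25) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_frames
  ctr <- rep_len(peak_center_series, n)
  wid <- rep_len(peak_width_series, n)
  amp <- rep_len(amplitude_series, n)
  if (any(1 / ctr < min(q_grid) | 1 / ctr > max(q_grid)))
    stop("peak centers fall outside the q grid")
  fl <- fluence_axis(cfg)
  with_seed(cfg$seed, {
    inten <- t(vapply(seq_len(n), function(f) {
      y <- amp[f] * voigt_profile(q_grid, 1 / ctr[f], wid[f], wid[f] / 2) +
        background[1] + background[2] * q_grid
      if (gold)
        y <- y + gold_amplitude * voigt_profile(q_grid, 1 / 2.35, 0.006, 0.003)
      if (cfg$noise_level > 0)
        y <- y + rnorm(length(q_grid),
                       sd = cfg$noise_level * sqrt(pmax(y, 0)))
      y
    }, numeric(length(q_grid))))
    structure(list(q = q_grid, intensity = inten, fluence = fl,
                   fluence_per_frame = cfg$fluence_per_frame,
                   calibration = 1),
              class = "radial_profile_series")
  })
}

#' Simulate an electron energy-loss spectrum
#'
#' A Voigt zero-loss peak (ZLP) at 0 eV plus a Voigt plasmon peak, on a
#' uniform energy grid (0.1 eV dispersion by default), with counting noise.
#'
#' @param cfg a [generator_config()]; only `seed` and `noise_level` are used.
#' @param plasmon_center plasmon energy in eV, > 0.
#' @param zlp_width Gaussian width (sd, eV) of the ZLP; its Lorentzian
#'   half-width is half of it.
#' @param plasmon_width Gaussian width (sd, eV) of the plasmon peak.
#' @param intensity_ratio plasmon area as a fraction of the ZLP area; 0
#'   produces a plasmon-free spectrum.
#' @param energy_grid uniform energy-loss grid in eV.
#' @param zlp_counts total ZLP area in counts.
#' @param temperature_label specimen temperature in K (metadata).
#' @return object of class `"eels_spectrum"` with `energy` and `counts`.
#' @examples
#' cfg <- generator_config(seed = 3, noise_level = 0)
#' sp <- gen_eels_spectrum(cfg, plasmon_center = 20.4)
#' @export
gen_eels_spectrum <- function(cfg, plasmon_center = 20.4, zlp_width = 0.4,
                              plasmon_width = 3, intensity_ratio = 0.05,
                              energy_grid = seq(-5, 50, by = 0.1),
                              zlp_counts = 1e5, temperature_label = 13) {
  stopifnot(inherits(cfg, "generator_config"))
  stopifnot_scalar(plasmon_center, "plasmon_center", positive = TRUE)
  if (zlp_width <= 0 || plasmon_width <= 0) stop("widths must be > 0")
  if (intensity_ratio < 0) stop("'intensity_ratio' must be >= 0")
  with_seed(cfg$seed, {
    counts <- zlp_counts * voigt_profile(energy_grid, 0, zlp_width,
                                         zlp_width / 2) +
      zlp_counts * intensity_ratio *
        voigt_profile(energy_grid, plasmon_center, plasmon_width,
                      plasmon_width / 2)
    if (cfg$noise_level > 0)
      counts <- counts + rnorm(length(counts),
                               sd = cfg$noise_level * sqrt(pmax(counts, 0)))
    eels_spectrum(energy_grid, counts, temperature_label)
  })
}

#' Simulate per-frame half-set FSC curves under linear-in-dose B-factor decay
#'
#' Frame `f`'s amplitude relative to frame 1 is
#' `tau_f/tau_1 = exp(-DeltaB_f q^2 / 4)` with
#' `DeltaB_f = b_const + b_rate * (F_f - F_1)` for `f >= 2` (frame 1 is the
#' reference, ratio identically 1) and `F_f` the cumulative fluence at the
#' frame midpoint. FSC curves are constructed by inverting the FSC/SNR
#' relation from the chosen amplitude ratios and the frame-1 FSC implied by
#' `snr1`. With `cfg$noise_level = 0` the construction is exact, so the
#' B-factor pipeline recovers `b_rate` to numerical precision.
#'
#' @param cfg a [generator_config()].
#' @param b_rate B-factor decay rate in A^2 per e-/A^2.
#' @param b_const frame-independent offset of the frame-relative B in A^2.
#' @param q_grid spatial-frequency grid in A^-1.
#' @param snr1 function of q giving the frame-1 spectral signal-to-noise
#'   ratio.
#' @return object of class `"fsc_series"`: `q`, an FSC matrix
#'   (frames x q), and the fluence axis.
#' @examples
#' cfg <- generator_config(seed = 1, n_frames = 10, fluence_per_frame = 0.63,
#'                         noise_level = 0)
#' fsc <- gen_fsc_series(cfg, b_rate = 5)
#' @export
gen_fsc_series <- function(cfg, b_rate, b_const = 0,
                           q_grid = seq(0.02, 0.30, by = 0.01),
                           snr1 = function(q) 100 * exp(-5 * q)) {
  stopifnot(inherits(cfg, "generator_config"))
  fl <- fluence_axis(cfg)
  s1 <- snr1(q_grid)
  if (any(s1 <= 0)) stop("'snr1' must be positive on the q grid")
  fsc1 <- s1 / (1 + s1)
  with_seed(cfg$seed, {
    fsc <- t(vapply(seq_len(cfg$n_frames), function(f) {
      db <- if (f == 1L) 0 else b_const + b_rate * (fl[f] - fl[1])
      ratio <- exp(-db * q_grid^2 / 4)
      snr_f <- ratio^2 * s1
      v <- snr_f / (1 + snr_f)
      if (cfg$noise_level > 0)
        v <- v + rnorm(length(v), sd = cfg$noise_level * (1 - v))
      v
    }, numeric(length(q_grid))))
    if (any(fsc <= -1 | fsc >= 1))
      stop("generated FSC values fall outside (-1, 1); reduce noise_level")
    fsc_series(q_grid, fsc, cfg$fluence_per_frame)
  })
}

#' Simulate frame-grouped power-spectrum peak intensities
#'
#' Peak intensities `W_{M,m}` for summed power spectra at frame groupings
#' `m`, following the pseudo-Brownian dephasing model
#' `W = scale * M * m * d^2 * g(x)` with `x = alpha_u * m * d`,
#' `g(x) = 2 (x + exp(-x) - 1) / x^2` and `alpha_u = 2 pi^2 sigma0_sq u^2`,
#' plus an optional additive linear-in-(m d) nuisance emulating imperfect
#' gain correction (which the estimator must remove) and multiplicative
#' noise.
#'
#' @param cfg a [generator_config()]; `fluence_per_frame` is the per-original-
#'   frame fluence `d`.
#' @param sigma0_sq mean-squared displacement per unit fluence per axis,
#'   A^2/(e-/A^2).
#' @param u spatial frequency of the monitored peak, A^-1.
#' @param M total number of frames; every `m` must divide `M`.
#' @param m_list frame-grouping counts.
#' @param nuisance_slope slope of the additive linear component per unit
#'   (m d).
#' @param scale overall proportionality constant (detector gain).
#' @return object of class `"spectral_peak_series"`.
#' @examples
#' cfg <- generator_config(seed = 1, fluence_per_frame = 0.375, noise_level = 0)
#' sp <- gen_brownian_peak_series(cfg, sigma0_sq = 0.012)
#' @export
gen_brownian_peak_series <- function(cfg, sigma0_sq, u = 0.27, M = 200,
                                     m_list = c(1, 2, 4, 5, 8, 10, 20, 25,
                                                50, 100, 200),
                                     nuisance_slope = 0, scale = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  if (sigma0_sq < 0) stop("'sigma0_sq' must be >= 0")
  if (any(M %% m_list != 0)) stop("every m in 'm_list' must divide M")
  d <- cfg$fluence_per_frame
  au <- alpha_u(sigma0_sq, u)
  with_seed(cfg$seed, {
    W <- brownian_peak_expected(m_list, M = M, d = d, alpha_u = au,
                                scale = scale) +
      nuisance_slope * m_list * d
    if (cfg$noise_level > 0)
      W <- W * (1 + rnorm(length(W), sd = cfg$noise_level))
    structure(list(m_list = m_list, W = W, M = M, d = d, u = u),
              class = "spectral_peak_series")
  })
}

#' Simulate a diffraction-spot power versus defocus series
#'
#' Spot powers follow the square of the spatial-coherence envelope
#' `Es(q) = exp[-(pi alpha / lambda)^2 (lambda dz q + Cs lambda^3 q^3)^2]`
#' at each defocus, with optional multiplicative noise.
#'
#' @param cfg a [generator_config()]; only `seed` and `noise_level` are used.
#' @param alpha source semiangle in rad (1/e definition).
#' @param lambda_e electron wavelength in A (default 300 keV).
#' @param Cs spherical aberration in mm.
#' @param defocus_list defocus values in micrometres (negative = underfocus).
#' @param q spatial frequency of the monitored reflection in A^-1
#'   (default the gold 111 ring at 2.35 A).
#' @param power_scale power at zero envelope attenuation.
#' @return object of class `"defocus_series"`.
#' @examples
#' cfg <- generator_config(seed = 1, noise_level = 0)
#' ds <- gen_defocus_series(cfg, alpha = 5e-5)
#' @export
gen_defocus_series <- function(cfg, alpha, lambda_e = 0.01969, Cs = 2.0,
                               defocus_list = seq(-10, 0, by = 1),
                               q = 1 / 2.35, power_scale = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  if (alpha < 0) stop("'alpha' must be >= 0")
  es <- coherence_envelope(q, alpha, lambda_e, Cs, defocus_list)
  with_seed(cfg$seed, {
    p <- power_scale * es^2
    if (cfg$noise_level > 0)
      p <- p * exp(rnorm(length(p), sd = cfg$noise_level))
    defocus_series(defocus_list, p, q = q, lambda_e = lambda_e, Cs = Cs)
  })
}
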