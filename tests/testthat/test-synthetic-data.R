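test_that("generators are pure functions of seed and config", {
  cfg <- generator_config(seed = 7, n_frames = 8, fluence_per_frame = 0.5,
                          noise_level = 0.05)
  a <- gen_expanding_tracks(cfg, n_particles = 6)
  b <- gen_expanding_tracks(cfg, n_particles = 6)
  expect_identical(a, b)
  expect_identical(gen_eels_spectrum(cfg), gen_eels_spectrum(cfg))
  expect_identical(gen_fsc_series(cfg, b_rate = 3), gen_fsc_series(cfg, b_rate = 3))
  cfg2 <- generator_config(seed = 8, n_frames = 8, fluence_per_frame = 0.5,
                           noise_level = 0.05)
  expect_false(identical(gen_eels_spectrum(cfg)$counts,
                         gen_eels_spectrum(cfg2)$counts))
})

test_that("config invariants are enforced", {
  expect_error(generator_config(fluence_per_frame = 0), "> 0")
  expect_error(generator_config(n_frames = 0), ">= 1")
  expect_error(generator_config(tilt_angle = 95), "tilt_angle")
})

test_that("zero strain and zero noise give rigid tracks; linear strain is exact", {
  cfg <- generator_config(seed = 1, n_frames = 10, fluence_per_frame = 0.5,
                          noise_level = 0, model = list(sigma0_sq = 0))
  tr <- gen_expanding_tracks(cfg, n_particles = 8, strain_rate = 0)
  pds <- pairwise_distance_series(tr)
  expect_equal(pds$rms_change, rep(0, 10), tolerance = 1e-12)

  # two particles 1000 A apart, strain accumulating to 0.005 at saturation
  tr2 <- particle_tracks(
    x = rbind(c(0, 1000), c(0, 1005)), y = rbind(c(0, 0), c(0, 0)),
    fluence_per_frame = 5)
  d <- pairwise_distance_series(tr2)
  expect_equal(d$rms_change[2], 5)

  # generated strain: final separation scales by (1 + eps)
  cfg3 <- generator_config(seed = 3, n_frames = 20, fluence_per_frame = 0.5,
                           noise_level = 0, model = list(sigma0_sq = 0))
  tr3 <- gen_expanding_tracks(cfg3, n_particles = 5, strain_rate = 1e-3,
                              saturation_fluence = 5)
  d1 <- dist(cbind(tr3$x[1, ], tr3$y[1, ]))
  dN <- dist(cbind(tr3$x[20, ], tr3$y[20, ]))
  eps1 <- 1e-3 * min(tr3$fluence[1], 5)
  epsN <- 1e-3 * 5
  expect_equal(as.vector(dN / d1), rep((1 + epsN) / (1 + eps1), length(d1)),
               tolerance = 1e-12)
})

test_that("13 K track preset reproduces the headline expansion bound", {
  tr <- gen_preset("tracks_13K", seed = 42)
  pds <- pairwise_distance_series(tr)
  i <- which(pds$fluence >= 5)[1]
  expect_gte(pds$rms_change[i], 5)
  # and the liquid-nitrogen preset shows no appreciable change
  tr81 <- gen_preset("tracks_81K", seed = 42)
  pds81 <- pairwise_distance_series(tr81)
  expect_lt(max(pds81$rms_change), 1)
})

test_that("diffraction generator places peaks where asked", {
  cfg <- generator_config(seed = 1, n_frames = 3, noise_level = 0)
  ps <- gen_diffraction_profile(cfg, peak_center_series = 3.7,
                                peak_width_series = 0.012,
                                amplitude_series = 40)
  # constant series, no noise -> identical frames
  expect_equal(ps$intensity[1, ], ps$intensity[2, ])
  expect_equal(ps$intensity[1, ], ps$intensity[3, ])
  # gold reference adds exactly one extra peak at 2.35 A
  psg <- gen_diffraction_profile(cfg, peak_center_series = 3.7,
                                 peak_width_series = 0.012,
                                 amplitude_series = 40, gold = TRUE)
  extra <- psg$intensity[1, ] - ps$intensity[1, ]
  expect_equal(psg$q[which.max(extra)], 1 / 2.35, tolerance = 2e-3)
  expect_error(gen_diffraction_profile(cfg, peak_center_series = 20),
               "outside")
})

test_that("EELS generator: ZLP dominates and degenerate plasmon is rejected downstream", {
  cfg <- generator_config(seed = 5, noise_level = 0)
  sp <- gen_eels_spectrum(cfg, plasmon_center = 20.4)
  expect_lt(abs(sp$energy[which.max(sp$counts)]), 0.2)
  expect_error(gen_eels_spectrum(cfg, plasmon_center = 20.4, zlp_width = -1),
               "widths")
  sp0 <- gen_eels_spectrum(cfg, plasmon_center = 20.4, intensity_ratio = 0)
  expect_error(plasmon_energy(list(sp0)), "plasmon")
})

test_that("FSC generator is exact in noiseless mode and degenerate at zero rate", {
  cfg <- generator_config(seed = 1, n_frames = 12, fluence_per_frame = 0.63,
                          noise_level = 0)
  fsc0 <- gen_fsc_series(cfg, b_rate = 0, b_const = 0)
  for (f in 2:12) expect_equal(fsc0$fsc[f, ], fsc0$fsc[1, ])
  # round trip at two rates with ratio 1.5
  r1 <- per_frame_bfactor(amplitude_decay(gen_fsc_series(cfg, b_rate = 6)))
  r2 <- per_frame_bfactor(amplitude_decay(gen_fsc_series(cfg, b_rate = 4)))
  expect_equal(r1$rate, 6, tolerance = 1e-9)
  expect_equal(decay_rate_ratio(r1, r2)$ratio, 1.5, tolerance = 1e-9)
})

test_that("brownian peak generator matches the dephasing-model limits", {
  m <- c(1, 2, 4, 5, 8, 10, 20, 25, 50, 100, 200)
  # fully correlated limit: W proportional to M m d^2
  w0 <- brownian_peak_expected(m, M = 200, d = 0.375, alpha_u = 0)
  expect_equal(w0 / (200 * m * 0.375^2), rep(1, length(m)))
  # small-x: W / (M m d^2) constant to <= 0.5%
  au <- 0.01 / (max(m) * 0.375)
  ws <- brownian_peak_expected(m, M = 200, d = 0.375, alpha_u = au)
  expect_lt(max(abs(ws / (200 * m * 0.375^2) - 1)), 0.005)
  # large-x: W -> 2 M d / alpha_u independent of m, to <= 0.5%
  wl <- brownian_peak_expected(c(1000, 2000), M = 2000, d = 1, alpha_u = 1)
  expect_lt(max(abs(wl / (2 * 2000 * 1 / 1) - 1)), 0.005)
  # default m list divides M
  cfg <- generator_config(seed = 1, fluence_per_frame = 0.375, noise_level = 0)
  sp <- gen_brownian_peak_series(cfg, sigma0_sq = 0.012)
  expect_true(all(sp$M %% sp$m_list == 0))
  expect_error(gen_brownian_peak_series(cfg, sigma0_sq = 0.01, m_list = c(3, 7)),
               "divide")
})

test_that("defocus generator: zero semiangle gives a flat series", {
  cfg <- generator_config(seed = 1, noise_level = 0)
  ds <- gen_defocus_series(cfg, alpha = 0)
  expect_equal(ds$power, rep(ds$power[1], length(ds$power)))
  expect_equal(ds$defocus, seq(-10, 0, 1))
})

test_that("estimator standard error shrinks roughly as 1/sqrt(n)", {
  spectra36 <- unlist(lapply(1:4, function(k) {
    lapply(seq_len(9), function(i) {
      cfg <- generator_config(seed = 1000 * k + i, noise_level = 0.05)
      gen_eels_spectrum(cfg, plasmon_center = 20.4)
    })
  }), recursive = FALSE)
  pe9 <- plasmon_energy(spectra36[1:9])
  pe36 <- plasmon_energy(spectra36)
  expect_gt(pe9$SE, 0)
  # 4x the spectra: SEM should drop by about half (allow a factor-2 band)
  expect_lt(pe36$SE / pe9$SE, 1)
  expect_gt(pe36$SE / pe9$SE, 0.25)
})
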