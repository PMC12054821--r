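test_that("radial profile of simple images behaves analytically", {
  # constant image -> flat profile at that constant for any percentile
  img <- matrix(7, 64, 64)
  for (p in c(0, 20, 50)) {
    rp <- radial_profile(img, c(32.5, 32.5), exclusion_percentile = p)
    expect_true(all(rp$intensity[!is.na(rp$intensity)] == 7))
  }
  # ring image: profile argmax within 1 px of the ring radius
  rp2 <- radial_profile(ring_image(r0 = 40), c(64.5, 64.5))
  expect_lt(abs(rp2$q[which.max(rp2$intensity)] - 40), 1)
  # radially symmetric image matches its analytic radial function within
  # binning error: oracle = annulus-weighted mean of f(r) over each 1 px bin
  sel <- which(rp2$q < 55)
  f <- function(r) 10 + 100 * exp(-(r - 40)^2 / (2 * 2^2))
  oracle <- vapply(sel, function(k) {
    r <- seq(k - 1, k, length.out = 200)
    sum(f(r) * r) / sum(r)
  }, numeric(1))
  # residual discreteness: integer pixels sample each annulus unevenly
  expect_lt(max(abs(rp2$intensity[sel] - oracle)), 5)
  expect_error(radial_profile(img, c(500, 500)), "inside")
})

test_that("percentile exclusion removes a beam-stop wedge", {
  rp_ref <- radial_profile(ring_image(wedge = FALSE), c(64.5, 64.5),
                           exclusion_percentile = 20)
  rp_wedge <- radial_profile(ring_image(wedge = TRUE), c(64.5, 64.5),
                             exclusion_percentile = 20)
  sel <- rp_ref$q < 55
  expect_lt(max(abs(rp_wedge$intensity[sel] - rp_ref$intensity[sel]),
                na.rm = TRUE), 3)
  # without exclusion the wedge drags the ring bin down
  rp_raw <- radial_profile(ring_image(wedge = TRUE), c(64.5, 64.5),
                           exclusion_percentile = 0)
  ring_bin <- which.min(abs(rp_ref$q - 40))
  expect_gt(rp_ref$intensity[ring_bin] - rp_raw$intensity[ring_bin], 2)
})

test_that("Voigt + linear fit is exact on noiseless peaks across a parameter sweep", {
  q <- seq(0.16, 0.55, by = 0.002)
  # peaks contained in the 2.8-4.5 A window; broader rings that spill past
  # the window edge are not an exact-recovery regime
  for (ctr in c(3.3, 3.6, 4.0)) {
    for (w in c(0.008, 0.012, 0.02)) {
      y <- voigt_trace(q, 1 / ctr, w, w / 2)
      pf <- fit_peak_voigt_linear(as_radial_profile(q, y),
                                  window = c(2.8, 4.5), init_center = 3.6)
      expect_true(pf$converged)
      expect_lt(abs(pf$center - ctr) / ctr, 1e-4)
    }
  }
})

test_that("fit flags degenerate and edge-pinned cases as non-converged", {
  q <- seq(0.16, 0.55, by = 0.002)
  # pure line, no peak
  pf <- fit_peak_voigt_linear(as_radial_profile(q, 20 - 10 * q),
                              window = c(2.8, 4.5), init_center = 3.7)
  expect_false(pf$converged)
  # peak far outside the window pins the centre to the edge
  y <- voigt_trace(q, 1 / 2.35, 0.01, 0.005)
  pf2 <- fit_peak_voigt_linear(as_radial_profile(q, y),
                               window = c(3.5, 4.5), init_center = 4)
  expect_false(pf2$converged)
  expect_error(fit_peak_voigt_linear(as_radial_profile(q[1:5], q[1:5]),
                                     window = c(2.8, 4.5), init_center = 3.7),
               "8 grid points")
})

test_that("camera-length calibration recovers a synthetic mis-scaling", {
  cfg <- generator_config(seed = 2, n_frames = 1, noise_level = 0)
  ps <- gen_diffraction_profile(cfg, peak_center_series = 3.7,
                                peak_width_series = 0.012,
                                amplitude_series = 40, gold = TRUE)
  prof <- as_radial_profile(ps$q, ps$intensity[1, ])
  cal0 <- calibrate_q(prof, 2.35)
  expect_equal(cal0$calibration, 1, tolerance = 1e-3)
  mis <- as_radial_profile(ps$q * 1.1, ps$intensity[1, ])
  # window in the mis-scaled axis units around the displaced gold peak
  cal <- calibrate_q(mis, 2.35, window = 1.1 * sort(1 / c(2.2, 2.5)),
                     init_center = 1.1 / 2.35)
  expect_equal(cal$calibration, 1 / 1.1, tolerance = 1e-3)
})

test_that("peak shift series tracks the 3.7 -> 3.3 A migration", {
  ps <- gen_preset("diffraction_13K", seed = 11)
  tab <- peak_shift_series(ps)
  expect_true(all(tab$converged))
  expect_equal(tab$center_A[1], 3.7, tolerance = 5e-3)
  n <- nrow(tab)
  expect_equal(tab$center_A[n], 3.3, tolerance = 5e-3)
  # monotone non-increasing within a small tolerance over the shift phase
  shift <- tab$center_A[tab$fluence <= 5]
  expect_true(all(diff(shift) < 0.02))
  # constant-centre series shows no shift
  cfg <- generator_config(seed = 1, n_frames = 5, noise_level = 0)
  flat <- gen_diffraction_profile(cfg, peak_center_series = 3.7,
                                  peak_width_series = 0.012,
                                  amplitude_series = 40)
  tf <- peak_shift_series(flat)
  expect_lt(max(abs(tf$center_A - 3.7)), 1e-4)
})

test_that("plasmon energy is recovered with SEM across spectra and shift invariance", {
  spectra <- gen_preset("eels_LDA", seed = 4)
  pe <- plasmon_energy(spectra)
  expect_equal(pe$n_spectra, 9)
  expect_equal(pe$E_p, 20.4, tolerance = 0.01)
  # a common energy-axis offset cancels in the plasmon - ZLP difference
  shifted <- lapply(spectra, function(sp)
    eels_spectrum(sp$energy + 0.3, sp$counts))
  pe2 <- plasmon_energy(shifted)
  expect_equal(pe2$E_p, pe$E_p, tolerance = 2e-3)
  # single spectrum: SE is undefined, not zero
  pe1 <- plasmon_energy(spectra[[1]])
  expect_true(is.na(pe1$SE))
  expect_equal(pe1$n_spectra, 1)
})

test_that("plasmon-density model matches the square-root scaling and composes", {
  expect_equal(plasmon_from_density(20.4, 0.93, 0.93), 20.4)
  expect_equal(round(plasmon_from_density(20.4, 0.93, 1.1), 1), 22.2)
  expect_equal(plasmon_from_density(20.4, 0.93, 1.00), 21.15, tolerance = 1e-3)
  # monotone in rho and composition f(f(E,a,b),b,c) = f(E,a,c)
  rhos <- seq(0.5, 1.5, 0.1)
  expect_true(all(diff(plasmon_from_density(20.4, 0.93, rhos)) > 0))
  expect_equal(plasmon_from_density(plasmon_from_density(20.4, 0.93, 1.1),
                                    1.1, 0.8),
               plasmon_from_density(20.4, 0.93, 0.8))
  expect_error(plasmon_from_density(20.4, 0.93, -1), "> 0")
})

test_that("density exclusion statistic is plain standardised distance", {
  meas <- list(E_p = 20.4, SE = 0.2)
  expect_equal(density_exclusion_z(meas, 20.4), 0)
  expect_equal(density_exclusion_z(meas, 22.2), 9.0)
  expect_gte(density_exclusion_z(meas, plasmon_from_density(20.4, 0.93, 1.1)), 5)
})
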