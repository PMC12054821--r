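test_that("link_tracks handles static, moving, and crossing detections", {
  # static detections: one track per particle, zero displacement
  det <- replicate(4, cbind(c(0, 100, 200), c(0, 0, 0)), simplify = FALSE)
  tr <- link_tracks(det, max_step = 5)
  expect_equal(tr$n_particles, 3)
  expect_true(all(!is.na(tr$x)))
  expect_equal(pairwise_distance_series(tr)$rms_change, rep(0, 4))

  # single particle moving 2 A/frame stays one continuous track
  det2 <- lapply(0:5, function(f) cbind(2 * f, 0))
  tr2 <- link_tracks(det2, max_step = 5)
  expect_equal(tr2$n_particles, 1)
  expect_equal(tr2$x[, 1], seq(0, 10, 2))

  # approaching particles: assignments enumerate to distance-then-id order
  # frame 1: A = (0,0), B = (10,0); frame 2 detections at (4,0), (6,0).
  # A->4 costs 4, B->6 costs 4; the alternative (A->6, B->4) costs 6 each.
  det3 <- list(cbind(c(0, 10), c(0, 0)), cbind(c(4, 6), c(0, 0)))
  tr3 <- link_tracks(det3, max_step = 5)
  expect_equal(tr3$n_particles, 2)
  expect_equal(tr3$x[2, ], c(4, 6))

  # a jump above max_step opens a gap and a new track, never a jump
  det4 <- list(cbind(0, 0), cbind(50, 0))
  tr4 <- link_tracks(det4, max_step = 5)
  expect_equal(tr4$n_particles, 2)
  expect_true(is.na(tr4$x[2, 1]) && is.na(tr4$x[1, 2]))
})

test_that("pairwise distances are invariant to rigid motion and exact under strain", {
  set.seed(11)
  n <- 12
  x0 <- runif(n, 0, 2000); y0 <- runif(n, 0, 2000)
  # rigid translation + rotation per frame
  th <- c(0, 0.1, 0.2)
  xs <- t(vapply(th, function(a) cos(a) * x0 - sin(a) * y0 + 100 * a, numeric(n)))
  ys <- t(vapply(th, function(a) sin(a) * x0 + cos(a) * y0 - 50 * a, numeric(n)))
  tr <- particle_tracks(xs, ys, fluence_per_frame = 1)
  expect_equal(pairwise_distance_series(tr)$rms_change, rep(0, 3),
               tolerance = 1e-10)

  # isotropic strain about an arbitrary centre: RMS change = eps * RMS(d0)
  eps <- 4e-3; ctr <- c(333, -77)
  xs2 <- rbind(x0, ctr[1] + (1 + eps) * (x0 - ctr[1]))
  ys2 <- rbind(y0, ctr[2] + (1 + eps) * (y0 - ctr[2]))
  tr2 <- particle_tracks(xs2, ys2, fluence_per_frame = 1)
  d0 <- dist(cbind(x0, y0))
  expected <- eps * sqrt(mean(d0^2))
  got <- pairwise_distance_series(tr2)$rms_change[2]
  expect_equal(got, expected, tolerance = 1e-9)

  # particle order must not matter
  perm <- sample(n)
  tr3 <- particle_tracks(xs2[, perm], ys2[, perm], fluence_per_frame = 1)
  expect_equal(pairwise_distance_series(tr3)$rms_change[2], got)
  expect_error(pairwise_distance_series(
    particle_tracks(cbind(1), cbind(1), fluence_per_frame = 1)), "2 tracks")
})

test_that("gapped tracks are excluded from pair statistics where missing", {
  x <- rbind(c(0, 1000, 500), c(0, 1010, NA))
  y <- rbind(c(0, 0, 800), c(0, 0, NA))
  tr <- particle_tracks(x, y, fluence_per_frame = 1)
  # only the (1,2) pair survives in frame 2
  expect_equal(pairwise_distance_series(tr)$rms_change[2], 10)
})

test_that("radial motion: rotation gives zero, strain gives eps * mean radius, jitter averages out", {
  set.seed(21)
  n <- 15
  ctr <- c(1000, 1000)
  r <- 500 * sqrt(runif(n)); ph <- 2 * pi * runif(n)
  x0 <- ctr[1] + r * cos(ph); y0 <- ctr[2] + r * sin(ph)
  # pure rotation about the hole centre
  a <- 0.05
  x1 <- ctr[1] + r * cos(ph + a); y1 <- ctr[2] + r * sin(ph + a)
  tr <- particle_tracks(rbind(x0, x1), rbind(y0, y1), fluence_per_frame = 1,
                        hole_center = ctr)
  # rotation is purely tangential: radial projection is r(cos a - 1), tiny
  expect_lt(abs(radial_motion(tr)$mean_radial[2]), mean(r) * a^2)

  eps <- 3e-3
  tr2 <- particle_tracks(rbind(x0, ctr[1] + (1 + eps) * (x0 - ctr[1])),
                         rbind(y0, ctr[2] + (1 + eps) * (y0 - ctr[2])),
                         fluence_per_frame = 1, hole_center = ctr)
  expect_equal(radial_motion(tr2)$mean_radial[2], eps * mean(r),
               tolerance = 1e-10)

  # uncorrelated jitter: mean radial displacement ~ 0 within sigma/sqrt(n)
  nbig <- 400; sig <- 2
  set.seed(22)
  xb <- ctr[1] + 500 * sqrt(runif(nbig)) * cos(2 * pi * runif(nbig))
  yb <- ctr[2] + 500 * sqrt(runif(nbig)) * sin(2 * pi * runif(nbig))
  trj <- particle_tracks(rbind(xb, xb + rnorm(nbig, sd = sig)),
                         rbind(yb, yb + rnorm(nbig, sd = sig)),
                         fluence_per_frame = 1, hole_center = ctr)
  expect_lt(abs(radial_motion(trj)$mean_radial[2]), 4 * sig / sqrt(nbig))
})

test_that("tilt-perpendicular displacement projects and accumulates", {
  # shifts parallel to the tilt axis contribute nothing
  sh <- cbind(rep(2, 10), rep(0, 10))
  expect_equal(tilt_perpendicular_displacement(sh, c(1, 0)), rep(0, 10))
  # constant 1 A/frame perpendicular shift accumulates to 10 A
  shp <- cbind(rep(0, 10), rep(1, 10))
  out <- tilt_perpendicular_displacement(shp, c(1, 0))
  expect_equal(out[10], 10)
  expect_equal(out, cumsum(rep(1, 10)))
})

test_that("tilt decomposition recovers out-of-plane motion", {
  expect_equal(decompose_tilt_motion(rep(0, 4), rep(0, 4), 30)$out_of_plane,
               rep(0, 4))
  # pure z motion of 10 A at 30 deg tilt appears as 5 A in projection
  dec <- decompose_tilt_motion(0, 5, theta = 30)
  expect_equal(dec$out_of_plane, 10, tolerance = 1e-12)
  expect_error(decompose_tilt_motion(0, 5, theta = 0), "unobservable")

  # round trip through the track generator with out-of-plane motion
  mk <- function(tilt) {
    cfg <- generator_config(seed = 9, n_frames = 15, fluence_per_frame = 0.7,
                            noise_level = 0, tilt_angle = tilt,
                            hole_diameter = 300, model = list(sigma0_sq = 0))
    gen_expanding_tracks(cfg, n_particles = 30, strain_rate = 1e-3,
                         saturation_fluence = 5, out_of_plane_fraction = 0.5)
  }
  tr0 <- mk(0); tr30 <- mk(30)
  mean_perp <- function(tr) {
    nhat <- c(-tr$tilt_axis[2], tr$tilt_axis[1])
    vapply(seq_len(tr$n_frames), function(f)
      mean((tr$x[f, ] - tr$x[1, ]) * nhat[1] +
           (tr$y[f, ] - tr$y[1, ]) * nhat[2]), numeric(1))
  }
  dec2 <- decompose_tilt_motion(mean_perp(tr0), mean_perp(tr30), 30)
  R <- 1500
  z_true <- 1e-3 * pmin(tr30$fluence, 5) * R * 0.5
  z_true <- z_true - z_true[1]   # frame-1 referenced
  expect_equal(dec2$out_of_plane, z_true, tolerance = 1e-6)
})

test_that("motion summary bundles the component metrics", {
  tr <- gen_preset("tracks_13K", seed = 3)
  ms <- motion_summary(tr)
  expect_equal(ms$rms_pairwise_change, pairwise_distance_series(tr)$rms_change)
  expect_equal(ms$mean_radial, radial_motion(tr)$mean_radial)
  expect_equal(dim(ms$net_displacement), c(tr$n_particles, 2))
  expect_output(print(ms), "motion summary")
})
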