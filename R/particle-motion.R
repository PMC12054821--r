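## Metrics of beam-induced specimen and foil motion from particle tracks.
##
## Coordinates are Angstroms in the image plane, origin at the image corner,
## y increasing downward (image convention); the hole centre is explicit.
## All "relative to first frame" quantities use frame 1 as the reference.

#' Particle track set
#'
#' Per-frame particle coordinates on a common fluence axis. Missing
#' detections are explicit `NA` gaps; every frame has the same particle ids.
#'
#' @param x,y frames x particles coordinate matrices in Angstroms (`NA` =
#'   gap).
#' @param fluence_per_frame fluence per frame in e-/A^2, > 0.
#' @param tilt_angle stage tilt in degrees, in \[0, 90).
#' @param tilt_axis unit 2-vector of the tilt axis in the image plane.
#' @param hole_center hole centre (x, y) in Angstroms.
#' @param hole_diameter hole diameter in nm.
#' @param temperature_label specimen temperature in K (metadata).
#' @return object of class `"particle_tracks"`.
#' @export
particle_tracks <- function(x, y, fluence_per_frame, tilt_angle = 0,
                            tilt_axis = c(1, 0), hole_center = c(0, 0),
                            hole_diameter = NA_real_,
                            temperature_label = NA_real_) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("'x' and 'y' must have the same shape")
  stopifnot_scalar(fluence_per_frame, "fluence_per_frame", positive = TRUE)
  if (tilt_angle < 0 || tilt_angle >= 90) stop("'tilt_angle' must be in [0, 90)")
  structure(list(
    x = x, y = y, n_frames = nrow(x), n_particles = ncol(x),
    fluence = fluence_per_frame * (seq_len(nrow(x)) - 0.5),
    fluence_per_frame = fluence_per_frame, tilt_angle = tilt_angle,
    tilt_axis = tilt_axis / sqrt(sum(tilt_axis^2)),
    hole_center = hole_center, hole_diameter = hole_diameter,
    temperature_label = temperature_label
  ), class = "particle_tracks")
}

#' @export
print.particle_tracks <- function(x, ...) {
  cat(sprintf(
    "Particle tracks: %d particles x %d frames (%.3g e-/A^2/frame, tilt %g deg)\n",
    x$n_particles, x$n_frames, x$fluence_per_frame, x$tilt_angle))
  cat(sprintf("  gaps: %d of %d detections missing\n",
              sum(is.na(x$x)), length(x$x)))
  invisible(x)
}

#' Link per-frame detections into tracks
#'
#' Greedy frame-to-frame nearest-neighbour assignment. Candidate pairs are
#' sorted by distance (ties broken by lowest track id, then lowest detection
#' index) and accepted while below `max_step`; unmatched detections open new
#' tracks and unmatched tracks carry an `NA` gap for the frame — an ambiguous
#' jump above `max_step` is never made.
#'
#' @param detections list with one element per frame, each a 2-column
#'   matrix (x, y) of detection coordinates in Angstroms.
#' @param max_step largest plausible per-frame displacement in Angstroms.
#' @param fluence_per_frame fluence per frame in e-/A^2 (metadata for the
#'   returned track set).
#' @param ... further metadata passed to [particle_tracks()].
#' @return a [particle_tracks()] object with one column per track.
#' @examples
#' det <- lapply(0:3, function(f) cbind(c(0, 100) + 2 * f, c(0, 0)))
#' tr <- link_tracks(det, max_step = 5)
#' @export
link_tracks <- function(detections, max_step, fluence_per_frame = 1, ...) {
  if (length(detections) < 1L) stop("need at least one frame of detections")
  stopifnot_scalar(max_step, "max_step", positive = TRUE)
  detections <- lapply(detections, function(d) {
    d <- as.matrix(d)
    if (ncol(d) != 2L) stop("each frame's detections must be a 2-column matrix")
    d
  })
  n_frames <- length(detections)
  ## track state: last known position and full history
  tx <- list(); ty <- list(); last <- list()
  open_track <- function(f, p) {
    id <- length(tx) + 1L
    tx[[id]] <<- rep(NA_real_, n_frames); ty[[id]] <<- rep(NA_real_, n_frames)
    tx[[id]][f] <<- p[1]; ty[[id]][f] <<- p[2]; last[[id]] <<- p
    id
  }
  for (p in seq_len(nrow(detections[[1]])))
    open_track(1L, detections[[1]][p, ])
  if (n_frames > 1L) for (f in 2:n_frames) {
    det <- detections[[f]]
    nd <- nrow(det); nt <- length(tx)
    if (nd > 0L && nt > 0L) {
      dm <- outer(seq_len(nt), seq_len(nd), function(i, j) {
        sqrt((vapply(last, `[`, 0, 1)[i] - det[j, 1])^2 +
             (vapply(last, `[`, 0, 2)[i] - det[j, 2])^2)
      })
      cand <- which(dm <= max_step, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(dm[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_t <- logical(nt); used_d <- logical(nd)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_t[i] && !used_d[j]) {
            used_t[i] <- TRUE; used_d[j] <- TRUE
            tx[[i]][f] <- det[j, 1]; ty[[i]][f] <- det[j, 2]
            last[[i]] <- det[j, ]
          }
        }
        for (j in which(!used_d)) open_track(f, det[j, ])
      } else {
        for (j in seq_len(nd)) open_track(f, det[j, ])
      }
    } else if (nd > 0L) {
      for (j in seq_len(nd)) open_track(f, det[j, ])
    }
  }
  particle_tracks(do.call(cbind, tx), do.call(cbind, ty),
                  fluence_per_frame = fluence_per_frame, ...)
}

#' RMS pairwise interparticle distance change versus fluence
#'
#' For every frame, the root-mean-square over all unordered particle pairs of
#' the change in pair distance relative to frame 1. Pairs with a gap in
#' either member (in frame 1 or the current frame) are excluded for that
#' frame. The metric is invariant to rigid translation and rotation; under a
#' uniform isotropic strain `eps` about any centre it equals
#' `eps * RMS(initial pair distances)` exactly.
#'
#' @param tracks a [particle_tracks()] object with >= 2 tracks.
#' @return data frame with columns `fluence` (e-/A^2) and `rms_change` (A).
#' @export
pairwise_distance_series <- function(tracks) {
  stopifnot(inherits(tracks, "particle_tracks"))
  if (tracks$n_particles < 2L) stop("need at least 2 tracks")
  np <- tracks$n_particles
  pairs <- which(upper.tri(matrix(TRUE, np, np)), arr.ind = TRUE)
  pair_dist <- function(f) {
    dx <- tracks$x[f, pairs[, 1]] - tracks$x[f, pairs[, 2]]
    dy <- tracks$y[f, pairs[, 1]] - tracks$y[f, pairs[, 2]]
    sqrt(dx^2 + dy^2)
  }
  d1 <- pair_dist(1L)
  rms <- vapply(seq_len(tracks$n_frames), function(f) {
    dd <- pair_dist(f) - d1
    dd <- dd[is.finite(dd)]
    if (!length(dd)) return(NA_real_)
    sqrt(mean(dd^2))
  }, numeric(1))
  data.frame(fluence = tracks$fluence, rms_change = rms)
}

#' Mean radial displacement versus fluence
#'
#' Per frame, the mean over particles of the displacement since frame 1
#' projected onto the unit vector from the hole centre to each particle's
#' first-frame position. Positive values mean outward motion. A pure
#' rotation about the hole centre gives zero to first order, and a uniform
#' outward strain `eps` gives exactly `eps * mean(initial radii)`.
#'
#' @param tracks a [particle_tracks()] object.
#' @return data frame with columns `fluence` and `mean_radial` (A).
#' @export
radial_motion <- function(tracks) {
  stopifnot(inherits(tracks, "particle_tracks"))
  rx <- tracks$x[1, ] - tracks$hole_center[1]
  ry <- tracks$y[1, ] - tracks$hole_center[2]
  r0 <- sqrt(rx^2 + ry^2)
  ok <- r0 > 0
  ux <- rx / r0; uy <- ry / r0
  mr <- vapply(seq_len(tracks$n_frames), function(f) {
    proj <- (tracks$x[f, ] - tracks$x[1, ]) * ux +
            (tracks$y[f, ] - tracks$y[1, ]) * uy
    mean(proj[ok], na.rm = TRUE)
  }, numeric(1))
  data.frame(fluence = tracks$fluence, mean_radial = mr)
}

#' Cumulative whole-frame displacement perpendicular to the tilt axis
#'
#' Projects each frame's whole-frame shift onto the in-plane normal of the
#' tilt axis and accumulates. Positive values point toward increasing
#' projected height.
#'
#' @param frame_shifts frames x 2 matrix of per-frame (x, y) shifts in
#'   Angstroms.
#' @param tilt_axis unit 2-vector of the tilt axis in the image plane.
#' @return numeric vector of cumulative perpendicular displacement in A.
#' @examples
#' sh <- cbind(rep(0, 10), rep(1, 10))   # 1 A/frame perpendicular
#' tilt_perpendicular_displacement(sh, c(1, 0))
#' @export
tilt_perpendicular_displacement <- function(frame_shifts, tilt_axis = c(1, 0)) {
  frame_shifts <- as.matrix(frame_shifts)
  if (ncol(frame_shifts) != 2L) stop("'frame_shifts' must have two columns")
  a <- tilt_axis / sqrt(sum(tilt_axis^2))
  nhat <- tilt_normal(a)
  cumsum(frame_shifts %*% nhat)
}

#' Decompose tilted-specimen motion into in-plane and out-of-plane parts
#'
#' With the in-plane component taken from an untilted acquisition, the
#' displacement perpendicular to the tilt axis observed at tilt `theta`
#' satisfies `disp_tilted = in_plane + z * sin(theta)`, so the out-of-plane
#' motion is `z = (disp_tilted - disp_untilted) / sin(theta)`.
#'
#' @param disp_untilted,disp_tilted displacement series (A) on a common
#'   fluence grid, both measured perpendicular to the tilt axis.
#' @param theta tilt angle in degrees, strictly between 0 and 90 (at 0 the
#'   out-of-plane component is unobservable).
#' @return list with components `in_plane` and `out_of_plane` (A).
#' @examples
#' decompose_tilt_motion(rep(0, 5), rep(5, 5), theta = 30)
#' @export
decompose_tilt_motion <- function(disp_untilted, disp_tilted, theta) {
  if (length(disp_untilted) != length(disp_tilted))
    stop("series must share a common fluence grid")
  if (theta <= 0 || theta >= 90)
    stop("out-of-plane motion is unobservable unless 0 < theta < 90")
  z <- (disp_tilted - disp_untilted) / sin(theta * pi / 180)
  list(in_plane = disp_untilted, out_of_plane = z)
}

#' Summarise beam-induced motion of a track set
#'
#' Bundles [pairwise_distance_series()], [radial_motion()] and per-particle
#' net displacement vectors on the shared fluence grid.
#'
#' @param tracks a [particle_tracks()] object.
#' @return object of class `"motion_summary"`.
#' @export
motion_summary <- function(tracks) {
  stopifnot(inherits(tracks, "particle_tracks"))
  pds <- pairwise_distance_series(tracks)
  rad <- radial_motion(tracks)
  nf <- tracks$n_frames
  net <- cbind(dx = tracks$x[nf, ] - tracks$x[1, ],
               dy = tracks$y[nf, ] - tracks$y[1, ])
  structure(list(
    fluence = tracks$fluence,
    rms_pairwise_change = pds$rms_change,
    mean_radial = rad$mean_radial,
    net_displacement = net,
    tilt_angle = tracks$tilt_angle
  ), class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  nf <- length(x$fluence)
  cat("Beam-induced motion summary\n")
  cat(sprintf("  fluence range: %.3g - %.3g e-/A^2 (%d frames)\n",
              x$fluence[1], x$fluence[nf], nf))
  cat(sprintf("  final RMS pairwise distance change: %.2f A\n",
              x$rms_pairwise_change[nf]))
  cat(sprintf("  final mean radial displacement:     %.2f A\n",
              x$mean_radial[nf]))
  invisible(x)
}

#' @export
as.data.frame.motion_summary <- function(x, ...) {
  data.frame(fluence = x$fluence,
             rms_pairwise_change = x$rms_pairwise_change,
             mean_radial = x$mean_radial)
}
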