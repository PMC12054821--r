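## The per-frame B-factor pipeline: half-set FSC curves -> relative
## amplitudes -> per-frame B-factors -> linear decay rate, plus the
## Rosenthal-Henderson regression and the per-frame blurring budget.
##
## Convention: Fourier amplitudes are damped as exp(-B q^2 / 4) with
## q = 1/spacing (A^-1), the crystallographic Debye-Waller convention.

#' Per-frame FSC series
#'
#' Half-set Fourier shell correlation curves for each movie frame on a
#' shared spatial-frequency grid.
#'
#' @param q ascending spatial-frequency grid in A^-1.
#' @param fsc frames x q matrix of FSC values in (-1, 1\]; frame 1 is the
#'   reference frame.
#' @param fluence_per_frame fluence per frame in e-/A^2.
#' @return object of class `"fsc_series"`.
#' @export
fsc_series <- function(q, fsc, fluence_per_frame) {
  fsc <- as.matrix(fsc)
  if (length(q) != ncol(fsc)) stop("q grid / FSC matrix mismatch")
  if (is.unsorted(q, strictly = TRUE)) stop("'q' must be strictly ascending")
  if (any(fsc <= -1 | fsc > 1)) stop("FSC values must lie in (-1, 1]")
  stopifnot_scalar(fluence_per_frame, "fluence_per_frame", positive = TRUE)
  structure(list(q = q, fsc = fsc, n_frames = nrow(fsc),
                 fluence_per_frame = fluence_per_frame,
                 fluence = fluence_per_frame * (seq_len(nrow(fsc)) - 0.5)),
            class = "fsc_series")
}

#' Relative amplitude from two half-set FSC values
#'
#' Converts half-set FSC values to the frame-f over frame-1 amplitude
#' ratio. Each FSC maps to a spectral signal-to-noise ratio
#' `SNR = FSC / (1 - FSC)`; the amplitude ratio is the square root of the
#' SNR ratio,
#' `tau_f/tau_1 = sqrt[ FSC_f (1 - FSC_1) / (FSC_1 (1 - FSC_f)) ]`.
#' With `scale = "snr"` the square root is omitted and the SNR ratio itself
#' is returned (the two conventions differ by exactly a factor of two in
#' the derived B-factors).
#'
#' Values are only defined for FSC in the open interval (0, 1); anything
#' outside is returned as `NA` (masked), never clamped.
#'
#' @param fsc_f FSC of frame f (vectorised).
#' @param fsc_1 FSC of the reference frame.
#' @param scale `"amplitude"` (default, square-root) or `"snr"`.
#' @return dimensionless ratio(s), `NA` where masked.
#' @examples
#' amplitude_ratio(0.2, 0.5)                  # 0.5
#' amplitude_ratio(0.2, 0.5, scale = "snr")   # 0.25
#' @export
amplitude_ratio <- function(fsc_f, fsc_1, scale = c("amplitude", "snr")) {
  scale <- match.arg(scale)
  n <- max(length(fsc_f), length(fsc_1))
  fsc_f <- rep_len(fsc_f, n); fsc_1 <- rep_len(fsc_1, n)
  ok <- fsc_f > 0 & fsc_f < 1 & fsc_1 > 0 & fsc_1 < 1
  r <- rep(NA_real_, n)
  snr <- (fsc_f[ok] / (1 - fsc_f[ok])) / (fsc_1[ok] / (1 - fsc_1[ok]))
  r[ok] <- if (scale == "amplitude") sqrt(snr) else snr
  r
}

#' Per-frame relative amplitudes from an FSC series
#'
#' Applies [amplitude_ratio()] to every frame against frame 1. Shells where
#' either FSC falls outside (0.01, 0.999) are masked to avoid divergence of
#' the FSC-to-SNR transform.
#'
#' @param fsc a [fsc_series()].
#' @param scale passed to [amplitude_ratio()].
#' @param fsc_limits validity interval for FSC values entering the
#'   transform.
#' @return object of class `"amplitude_decay"`: `q`, a frames x q `ratio`
#'   matrix (frame 1 identically 1), a validity `mask`, and the fluence
#'   axis.
#' @export
amplitude_decay <- function(fsc, scale = c("amplitude", "snr"),
                            fsc_limits = c(0.01, 0.999)) {
  stopifnot(inherits(fsc, "fsc_series"))
  scale <- match.arg(scale)
  valid <- fsc$fsc > fsc_limits[1] & fsc$fsc < fsc_limits[2]
  mask <- valid & matrix(valid[1, ], nrow(valid), ncol(valid), byrow = TRUE)
  ratio <- matrix(NA_real_, fsc$n_frames, length(fsc$q))
  for (f in seq_len(fsc$n_frames)) {
    r <- amplitude_ratio(fsc$fsc[f, ], fsc$fsc[1, ], scale = scale)
    r[!mask[f, ]] <- NA_real_
    ratio[f, ] <- r
  }
  ratio[1, mask[1, ]] <- 1
  structure(list(q = fsc$q, ratio = ratio, mask = mask,
                 fluence = fsc$fluence, scale = scale),
            class = "amplitude_decay")
}

#' Per-frame B-factors and their linear decay rate
#'
#' For each frame f >= 2, a weighted linear fit of `ln(tau_f/tau_1)` versus
#' `q^2` over `q_range` (weights proportional to `q^2`, the Fourier-shell
#' population) gives the per-frame B-factor change `DeltaB_f = -4 * slope`.
#' A second linear fit of `DeltaB_f` versus cumulative fluence gives the
#' decay rate. Frame 1 is the reference (`DeltaB_1 = 0` by construction)
#' and is excluded from the rate fit; frames with fewer than 4 valid shells
#' in range are skipped with a warning.
#'
#' @param decay an [amplitude_decay()] (an `fsc_series` is accepted and
#'   converted).
#' @param q_range spatial-frequency fit range in A^-1.
#' @return object of class `"bfactor_decay"`: per-frame `delta_b` (A^2),
#'   the fluence axis, the linear `rate` (A^2 per e-/A^2) with `rate_se`
#'   and `intercept`.
#' @export
per_frame_bfactor <- function(decay, q_range = range(decay$q)) {
  if (inherits(decay, "fsc_series")) decay <- amplitude_decay(decay)
  stopifnot(inherits(decay, "amplitude_decay"))
  q2 <- decay$q^2
  inr <- decay$q >= q_range[1] & decay$q <= q_range[2]
  nf <- nrow(decay$ratio)
  db <- rep(NA_real_, nf); db[1] <- 0
  for (f in seq_len(nf)[-1]) {
    r <- decay$ratio[f, ]
    ok <- inr & is.finite(r) & r > 0
    if (sum(ok) < 4L) {
      warning(sprintf("frame %d skipped: fewer than 4 valid shells in range", f))
      next
    }
    fit <- lm(log(r[ok]) ~ q2[ok], weights = q2[ok])
    db[f] <- -4 * coef(fit)[2]
  }
  use <- seq_len(nf)[-1]
  use <- use[is.finite(db[use])]
  if (length(use) < 2L) stop("need at least 2 fitted frames for the rate fit")
  rfit <- lm(db[use] ~ decay$fluence[use])
  rate_se <- suppressWarnings(unname(sqrt(diag(vcov(rfit)))[2]))
  structure(list(delta_b = db, fluence = decay$fluence,
                 rate = unname(coef(rfit)[2]),
                 rate_se = rate_se,
                 intercept = unname(coef(rfit)[1]),
                 q_range = q_range, scale = decay$scale),
            class = "bfactor_decay")
}

#' @export
print.bfactor_decay <- function(x, ...) {
  cat(sprintf(
    "Per-frame B-factor decay: rate %.4g +/- %.2g A^2/(e-/A^2), intercept %.4g A^2\n",
    x$rate, x$rate_se, x$intercept))
  cat(sprintf("  %d frames, q range %.3g-%.3g A^-1, %s-scale ratios\n",
              length(x$delta_b), x$q_range[1], x$q_range[2], x$scale))
  invisible(x)
}

#' @export
coef.bfactor_decay <- function(object, ...) {
  c(rate = object$rate, intercept = object$intercept)
}

#' @export
plot.bfactor_decay <- function(x, ...) {
  plot(x$fluence, x$delta_b, xlab = "cumulative fluence (e-/A^2)",
       ylab = expression(Delta * B ~ (ring(A)^2)), ...)
  abline(x$intercept, x$rate, lty = 2)
  invisible(x)
}

#' Ratio of two B-factor decay rates
#'
#' `rate_a / rate_b`, i.e. how many times slower series b decays than
#' series a, with a standard error by first-order error propagation.
#'
#' @param series_a,series_b [per_frame_bfactor()] results; conventionally
#'   `series_a` is the faster-decaying (liquid-nitrogen) series.
#' @return list with `ratio` and `se`.
#' @export
decay_rate_ratio <- function(series_a, series_b) {
  stopifnot(inherits(series_a, "bfactor_decay"),
            inherits(series_b, "bfactor_decay"))
  if (series_b$rate == 0) stop("series_b has zero decay rate")
  ratio <- series_a$rate / series_b$rate
  se <- abs(ratio) * sqrt((series_a$rate_se / series_a$rate)^2 +
                          (series_b$rate_se / series_b$rate)^2)
  list(ratio = ratio, se = se)
}

#' Rosenthal-Henderson regression
#'
#' Least-squares fit of `ln(n_particles)` versus `1/resolution^2`; the
#' overall data-quality B-factor is twice the slope.
#'
#' @param points data frame (or list) with numeric fields `n_particles` and
#'   `resolution` (A); at least 3 points with at least 2 distinct
#'   resolutions (2 points give the exact line through both).
#' @return list with `B` (A^2), `intercept`, and the fitted `lm` object.
#' @examples
#' pts <- data.frame(n_particles = exp(1 + 50 / c(4, 3, 2.5)^2),
#'                   resolution = c(4, 3, 2.5))
#' rosenthal_henderson(pts)$B   # 100
#' @export
rosenthal_henderson <- function(points) {
  n <- points$n_particles; res <- points$resolution
  if (length(n) < 2L || any(!is.finite(res)) || any(res <= 0) || any(n <= 0))
    stop("need >= 2 points with finite positive n_particles and resolution")
  x <- 1 / res^2
  if (length(unique(x)) < 2L) stop("need at least 2 distinct resolutions")
  fit <- lm(log(n) ~ x)
  list(B = 2 * unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fit = fit)
}

#' Assemble the per-frame image-blurring budget
#'
#' Sums the independent dose-dependent sources of image blurring, each
#' expressed as a per-frame B-factor: a dose-independent constant
#' (pseudo-Brownian motion + charge fluctuations), radiation damage growing
#' linearly with cumulative fluence, and a per-frame specimen-motion term
#' (a preset per hole-size scenario).
#'
#' @param constant dose-independent B contribution in A^2 per frame.
#' @param damage_rate radiation-damage B rate in A^2 per e-/A^2.
#' @param motion_per_frame per-frame specimen-motion B in A^2 (length sets
#'   the number of frames).
#' @param d fluence per frame in e-/A^2.
#' @return object of class `"blur_budget"` with the components and the
#'   per-frame total (their sum).
#' @export
assemble_budget <- function(constant, damage_rate, motion_per_frame, d) {
  if (constant < 0 || damage_rate < 0 || any(motion_per_frame < 0))
    stop("all budget components must be >= 0")
  stopifnot_scalar(d, "d", positive = TRUE)
  nf <- length(motion_per_frame)
  fl <- d * (seq_len(nf) - 0.5)
  damage <- damage_rate * fl
  total <- constant + damage + motion_per_frame
  structure(list(fluence = fl, constant = rep(constant, nf),
                 radiation_damage = damage, motion = motion_per_frame,
                 total = total, d = d),
            class = "blur_budget")
}

#' @export
print.blur_budget <- function(x, ...) {
  nf <- length(x$fluence)
  cat(sprintf("Blurring budget over %d frames (%.3g e-/A^2/frame)\n", nf, x$d))
  cat(sprintf("  constant %.3g A^2; damage %.3g A^2 at end; motion %.3g-%.3g A^2\n",
              x$constant[1], x$radiation_damage[nf],
              min(x$motion), max(x$motion)))
  cat(sprintf("  total at final frame: %.3g A^2\n", x$total[nf]))
  invisible(x)
}

#' @export
plot.blur_budget <- function(x, ...) {
  matplot(x$fluence, cbind(x$constant, x$radiation_damage, x$motion, x$total),
          type = "l", lty = c(3, 2, 4, 1), col = c("brown", "blue", "purple", 1),
          xlab = "cumulative fluence (e-/A^2)", ylab = expression(B ~ (ring(A)^2)),
          ...)
  legend("topleft", c("constant", "radiation damage", "motion", "total"),
         lty = c(3, 2, 4, 1), col = c("brown", "blue", "purple", 1), bty = "n")
  invisible(x)
}
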