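## Instrument calibrations: detector coincidence-loss correction,
## blank-beam intensity interpolation, intensity -> ice-thickness inversion,
## four-point-probe sheet/bulk resistance, and electron flux calibration.

#' Coincidence-loss parameters
#'
#' Detector model constants for the exponential coincidence-loss /
#' DQE-correction: `l = DQE * exp(-D s / F)`.
#'
#' @param dqe detective quantum efficiency, in (0, 1\] (default 0.8656).
#' @param s fitted coincidence parameter in px^2 (default 5.149).
#' @param frame_rate camera frame rate in frames/s (default 400).
#' @return object of class `"coincidence_params"`.
#' @export
coincidence_params <- function(dqe = 0.8656, s = 5.149, frame_rate = 400) {
  if (dqe <= 0 || dqe > 1) stop("'dqe' must be in (0, 1]")
  stopifnot_scalar(s, "s", positive = TRUE)
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  structure(list(dqe = dqe, s = s, frame_rate = frame_rate),
            class = "coincidence_params")
}

#' Fractional loss from coincidence and imperfect DQE
#'
#' `l = DQE * exp(-D s / F)` for flux density `D`; measured counts are
#' corrected by dividing by `l`. Monotone decreasing in `D`, with
#' `l -> DQE` as `D -> 0`.
#'
#' @param D flux density in e-/px/s, >= 0 (vectorised).
#' @param params a [coincidence_params()].
#' @return fractional loss in (0, DQE\].
#' @examples
#' coincidence_loss(0)    # 0.8656
#' coincidence_loss(10)   # 0.7611
#' @export
coincidence_loss <- function(D, params = coincidence_params()) {
  if (any(D < 0)) stop("'D' must be >= 0")
  params$dqe * exp(-D * params$s / params$frame_rate)
}

#' Correct counts for coincidence loss
#'
#' @param counts measured counts.
#' @inheritParams coincidence_loss
#' @return corrected counts, `counts / l`.
#' @export
correct_coincidence <- function(counts, D, params = coincidence_params()) {
  counts / coincidence_loss(D, params)
}

#' Interpolate blank-beam intensity at an image's acquisition time
#'
#' Piecewise-linear interpolation between periodically acquired blank
#' (empty-area) images. Queries outside the blank time range clamp to the
#' nearest blank with a warning rather than extrapolating.
#'
#' @param blank_times acquisition times of the blank images in s.
#' @param blank_values blank intensities (counts).
#' @param query_time time(s) at which to evaluate.
#' @return interpolated intensity (counts).
#' @export
interpolate_blank_intensity <- function(blank_times, blank_values, query_time) {
  if (length(blank_times) != length(blank_values) || length(blank_times) < 1L)
    stop("blank times/values mismatch")
  ord <- order(blank_times)
  if (any(query_time < min(blank_times) | query_time > max(blank_times)))
    warning("query outside blank time range; clamping to nearest blank")
  if (length(blank_times) == 1L) return(rep(blank_values, length(query_time)))
  approx(blank_times[ord], blank_values[ord], xout = query_time,
         rule = 2)$y
}

#' Intensity-to-thickness calibration table
#'
#' A monotone table mapping the transmitted intensity ratio `I/I0` to
#' frozen-water thickness. Any table may be supplied, including one exported
#' from a multislice-based calibration; [make_attenuation_calibration()]
#' builds an analytic exponential-attenuation table.
#'
#' @param ratio intensity ratios in (0, 1\], strictly decreasing with
#'   thickness.
#' @param thickness thicknesses in nm, ascending from 0.
#' @param aperture_cutoff objective-aperture cutoff resolution in A
#'   (metadata).
#' @return object of class `"thickness_calibration"`.
#' @export
thickness_calibration <- function(ratio, thickness, aperture_cutoff = 1.2) {
  if (length(ratio) != length(thickness) || length(ratio) < 2L)
    stop("ratio/thickness mismatch or too short")
  ord <- order(thickness)
  ratio <- ratio[ord]; thickness <- thickness[ord]
  if (any(diff(ratio) >= 0))
    stop("intensity ratio must be strictly decreasing with thickness")
  if (any(ratio <= 0 | ratio > 1)) stop("ratios must be in (0, 1]")
  if (aperture_cutoff <= 0) stop("'aperture_cutoff' must be > 0")
  structure(list(ratio = ratio, thickness = thickness,
                 aperture_cutoff = aperture_cutoff),
            class = "thickness_calibration")
}

#' @rdname thickness_calibration
#' @param attenuation_length 1/e attenuation thickness in nm.
#' @param max_thickness largest tabulated thickness in nm.
#' @param n number of table knots.
#' @export
make_attenuation_calibration <- function(attenuation_length = 300,
                                         max_thickness = 1000, n = 101) {
  t <- seq(0, max_thickness, length.out = n)
  thickness_calibration(exp(-t / attenuation_length), t)
}

#' Frozen-water thickness from an intensity ratio
#'
#' Monotone interpolation of the calibration table; exact at the table
#' knots. A ratio below the table minimum means the specimen is thicker
#' than the calibration covers and is an error.
#'
#' @param ratio transmitted intensity ratio(s) `I/I0`, in (0, 1\].
#' @param cal a [thickness_calibration()].
#' @return thickness in nm.
#' @examples
#' cal <- make_attenuation_calibration(300)
#' thickness_from_intensity(exp(-1), cal)   # 300 nm
#' @export
thickness_from_intensity <- function(ratio, cal) {
  stopifnot(inherits(cal, "thickness_calibration"))
  if (any(ratio <= 0 | ratio > 1)) stop("'ratio' must be in (0, 1]")
  if (any(ratio < min(cal$ratio)))
    stop("intensity ratio below calibration table: specimen too thick")
  ## table is decreasing in thickness; approx needs ascending x
  approx(rev(cal$ratio), rev(cal$thickness), xout = pmin(ratio, max(cal$ratio)),
         rule = 2)$y
}

## Otsu's two-class threshold: maximise between-class variance of a
## histogram split. Used to separate foil/nanoparticle pixels (dark) from
## ice (bright) in intensity-ratio maps.
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  ## the maximum is a plateau when the classes are separated by empty bins;
  ## take its middle so the threshold sits mid-gap
  idx <- which(bcv >= max(bcv) * (1 - 1e-12))
  mids[idx[ceiling(length(idx) / 2)]]
}

#' Mean frozen-water thickness of a hole from an intensity-ratio map
#'
#' Applies [thickness_from_intensity()] per pixel after removing foil and
#' nanoparticle pixels, which transmit far less than the ice: pixels with
#' ratio at or below the threshold (Otsu two-class split by default) are
#' discarded and the mean thickness of the remainder is returned.
#'
#' @param ratio_map matrix of per-pixel intensity ratios `I/I0`.
#' @param cal a [thickness_calibration()].
#' @param threshold `"otsu"` or a numeric ratio cutoff; pixels `<=`
#'   threshold are removed.
#' @return list with `mean_thickness` (nm), the `threshold` used and the
#'   number of pixels kept.
#' @export
thickness_map_mean <- function(ratio_map, cal, threshold = "otsu") {
  v <- as.vector(as.matrix(ratio_map))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(v)
         else as.numeric(threshold)
  keep <- v > thr & is.finite(v)
  if (!any(keep)) stop("no pixels above the foil threshold")
  list(mean_thickness = mean(thickness_from_intensity(v[keep], cal)),
       threshold = thr, n_pixels = sum(keep))
}

#' Current-voltage series for four-point-probe measurements
#'
#' @param current sourced currents in A, spanning zero, length >= 3.
#' @param voltage measured voltages in V.
#' @param c1,c2 geometric correction factors (gold-on-mica foil:
#'   C1 = 0.5192, C2 = 1).
#' @param thickness specimen thickness in m (for bulk resistivity).
#' @return object of class `"iv_series"`.
#' @export
iv_series <- function(current, voltage, c1 = 0.5192, c2 = 1,
                      thickness = NA_real_) {
  if (length(current) != length(voltage) || length(current) < 3L)
    stop("need matched current/voltage vectors of length >= 3")
  if (min(current) >= 0 || max(current) <= 0)
    stop("currents must span zero (symmetric sweep)")
  structure(list(current = current, voltage = voltage, c1 = c1, c2 = c2,
                 thickness = thickness),
            class = "iv_series")
}

#' Sheet and bulk resistance from a four-point-probe I-V sweep
#'
#' `R_s = (pi / ln 2) * (dV/dI) * C1 * C2`, with `dV/dI` the least-squares
#' slope of voltage versus current; bulk resistivity is the sheet
#' resistance times the specimen thickness. A slope standard error
#' exceeding the slope itself (non-ohmic contact, as for amorphous carbon
#' at 4 K) sets `reliable = FALSE`.
#'
#' @param iv an [iv_series()].
#' @return list with `R_s` (Ohm/sq), `bulk` (Ohm m, `NA` without a
#'   thickness), `slope`, `slope_se`, `r_squared` and `reliable`.
#' @examples
#' iv <- iv_series(current = seq(-0.02, 0.02, 0.002),
#'                 voltage = seq(-0.02, 0.02, 0.002) * 1)
#' sheet_resistance(iv)$R_s    # (pi/ln 2) * 0.5192 = 2.3533
#' @export
sheet_resistance <- function(iv) {
  stopifnot(inherits(iv, "iv_series"))
  fit <- lm(iv$voltage ~ iv$current)
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  rs <- (pi / log(2)) * slope * iv$c1 * iv$c2
  list(R_s = rs,
       bulk = if (is.na(iv$thickness)) NA_real_ else rs * iv$thickness,
       slope = slope, slope_se = unname(se), r_squared = r2,
       reliable = is.finite(se) && se < abs(slope))
}

#' Electron flux calibration from paired current readings
#'
#' Ordinary least squares of the true beam current (picoammeter) on the
#' fluorescent-screen reading; applied as
#' `true = gradient * screen + intercept`.
#'
#' @param screen screen current readings in nA.
#' @param true reference (picoammeter) currents in nA.
#' @return object of class `"flux_calibration"` with `gradient`,
#'   `intercept` (nA) and the underlying `lm` fit.
#' @export
flux_calibration <- function(screen, true) {
  if (length(screen) != length(true) || length(screen) < 2L)
    stop("need matched readings of length >= 2")
  fit <- lm(true ~ screen)
  structure(list(gradient = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), fit = fit),
            class = "flux_calibration")
}

#' @export
print.flux_calibration <- function(x, ...) {
  cat(sprintf("Flux calibration: true = %.4f * screen + %.4f nA\n",
              x$gradient, x$intercept))
  invisible(x)
}

#' @rdname flux_calibration
#' @param cal a `flux_calibration`.
#' @export
apply_flux_calibration <- function(cal, screen) {
  cal$gradient * screen + cal$intercept
}
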