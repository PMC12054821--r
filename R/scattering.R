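## Radial profile extraction, Voigt + linear peak fitting for diffraction
## rings and EELS peaks, camera-length calibration against the gold (111)
## ring, and the plasmon-energy / density model.
##
## Spatial-frequency convention: q = 1/spacing (A^-1); all diffraction peak
## positions are reported as spacings in A.

#' EELS spectrum
#'
#' @param energy ascending, uniformly spaced energy-loss grid in eV
#'   (0.1 eV dispersion by default in the generator).
#' @param counts detector counts per channel.
#' @param temperature_label specimen temperature in K (metadata).
#' @return object of class `"eels_spectrum"`.
#' @export
eels_spectrum <- function(energy, counts, temperature_label = NA_real_) {
  if (length(energy) != length(counts)) stop("grid/counts length mismatch")
  de <- diff(energy)
  if (any(de <= 0) || max(de) - min(de) > 1e-8 * max(de))
    stop("'energy' must be ascending and uniformly spaced")
  structure(list(energy = energy, counts = counts,
                 temperature_label = temperature_label),
            class = "eels_spectrum")
}

#' Radial profile of a 2-D diffraction image
#'
#' Bins pixels by integer radius from the supplied pattern centre (bin width
#' 1 px) and, within each bin, discards pixels below the given percentile
#' before averaging — this removes the beam stop and other low outliers.
#' The radius axis is uncalibrated (pixel units) until [calibrate_q()].
#'
#' @param image numeric matrix of counts (rows = y, columns = x).
#' @param center pattern centre `c(x, y)` in pixels; must lie inside the
#'   image.
#' @param exclusion_percentile percentile (0-100) of pixels to discard
#'   within each radial bin before averaging; 20 removes a typical beam-stop
#'   shadow.
#' @param frame,fluence provenance metadata.
#' @return object of class `"radial_profile"` with fields `q` (bin-centre
#'   radius), `intensity` (mean counts, `NA` for empty bins), `calibration`.
#' @export
radial_profile <- function(image, center, exclusion_percentile = 20,
                           frame = NA_integer_, fluence = NA_real_) {
  image <- as.matrix(image)
  if (exclusion_percentile < 0 || exclusion_percentile >= 100)
    stop("'exclusion_percentile' must be in [0, 100)")
  if (center[1] < 1 || center[1] > ncol(image) ||
      center[2] < 1 || center[2] > nrow(image))
    stop("'center' must lie inside the image")
  xs <- col(image) - center[1]
  ys <- row(image) - center[2]
  r <- sqrt(xs^2 + ys^2)
  bin <- floor(r)
  nb <- max(bin) + 1L
  inten <- rep(NA_real_, nb)
  sp <- split(as.vector(image), bin)
  for (nm in names(sp)) {
    v <- sp[[nm]]
    if (exclusion_percentile > 0) {
      thr <- quantile(v, exclusion_percentile / 100, names = FALSE, type = 7)
      v <- v[v >= thr]
    }
    if (length(v)) inten[as.integer(nm) + 1L] <- mean(v)
  }
  structure(list(q = seq_len(nb) - 0.5, intensity = inten,
                 calibration = NA_real_, frame = frame, fluence = fluence,
                 units = "px"),
            class = "radial_profile")
}

#' Construct a radial profile from a precomputed 1-D trace
#'
#' @param q ascending abscissa (A^-1 if calibrated, else px).
#' @param intensity intensities.
#' @param calibration scale factor already applied to `q` (`NA` =
#'   uncalibrated).
#' @param units `"A^-1"` or `"px"`.
#' @inheritParams radial_profile
#' @return object of class `"radial_profile"`.
#' @export
as_radial_profile <- function(q, intensity, calibration = 1,
                              frame = NA_integer_, fluence = NA_real_,
                              units = "A^-1") {
  if (is.unsorted(q, strictly = TRUE)) stop("'q' must be strictly ascending")
  if (length(q) != length(intensity)) stop("grid/intensity length mismatch")
  structure(list(q = q, intensity = intensity, calibration = calibration,
                 frame = frame, fluence = fluence, units = units),
            class = "radial_profile")
}

## pull one frame of a profile series as a radial_profile
profile_frame <- function(series, f) {
  stopifnot(inherits(series, "radial_profile_series"))
  as_radial_profile(series$q, series$intensity[f, ],
                    calibration = series$calibration, frame = f,
                    fluence = series$fluence[f])
}

## ---- Voigt + linear core fit -------------------------------------------

## Nonlinear least squares of amplitude * Voigt(center, sigma, gamma) +
## linear background over a window.  Initialisation: centre as supplied,
## amplitude from local max above an endpoint-line background, widths from
## the local FWHM.  Non-convergence, an amplitude indistinguishable from
## zero, or a centre pinned to the window edge set converged = FALSE.
fit_voigt_core <- function(x, y, window, init_center) {
  sel <- x >= window[1] & x <= window[2] & is.finite(y)
  if (sum(sel) < 8L) stop("fit window must contain at least 8 grid points")
  if (init_center < window[1] || init_center > window[2])
    stop("'init_center' must lie inside the window")
  xs <- x[sel]; ys <- y[sel]
  step <- median(diff(xs))
  ## endpoint-line background
  b1 <- (ys[length(ys)] - ys[1]) / (xs[length(xs)] - xs[1])
  b0 <- ys[1] - b1 * xs[1]
  resid <- ys - (b0 + b1 * xs)
  h <- max(resid)
  fwhm <- sum(resid > h / 2) * step
  if (!is.finite(fwhm) || fwhm <= 0) fwhm <- 2 * step
  sigma0 <- max(fwhm / 2.355, step / 4)
  empty <- list(center = NA_real_, center_se = NA_real_, sigma = NA_real_,
                gamma = NA_real_, amplitude = NA_real_,
                bg_intercept = NA_real_, bg_slope = NA_real_,
                window = window, converged = FALSE)
  attempt <- function(ctr0) {
    start <- list(A = max(h, 0) * fwhm * 1.06, ctr = ctr0,
                  sg = sigma0, gm = sigma0 / 2, b0 = b0, b1 = b1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ys ~ A * voigt_profile(xs, ctr, sg, gm) + b0 + b1 * xs,
        start = start,
        lower = c(A = 0, ctr = window[1], sg = step / 20, gm = 0,
                  b0 = -Inf, b1 = -Inf),
        upper = c(A = Inf, ctr = window[2], sg = Inf, gm = Inf,
                  b0 = Inf, b1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    out <- empty
    if (is.null(fit)) return(out)
    out$rss <- sum(residuals(fit)^2)
    cf <- coef(fit)
    se <- tryCatch(suppressWarnings(sqrt(diag(vcov(fit)))),
                   error = function(e) rep(NA_real_, 6))
    out$center <- unname(cf["ctr"]); out$center_se <- unname(se[2])
    out$sigma <- unname(cf["sg"]); out$gamma <- unname(cf["gm"])
    out$amplitude <- unname(cf["A"])
    out$bg_intercept <- unname(cf["b0"]); out$bg_slope <- unname(cf["b1"])
    edge <- out$center <= window[1] + step | out$center >= window[2] - step
    amp_ok <- is.finite(se[1]) && out$amplitude > 2 * se[1]
    out$converged <- !edge && amp_ok && is.finite(out$center_se)
    out
  }
  ## two starts - the supplied centre and the tallest point above the
  ## endpoint background - guard against local minima when the guess is far
  ## from the peak; keep the converged fit with the smaller residual
  out <- attempt(init_center)
  alt <- xs[which.max(resid)]
  if (abs(alt - init_center) > 2 * step) {
    out2 <- attempt(alt)
    better <- out2$converged &&
      (!out$converged || (out2$rss %||% Inf) < (out$rss %||% Inf))
    if (better) out <- out2
  }
  out$rss <- NULL
  out
}

new_peak_fit <- function(core, units) {
  structure(c(core, list(units = units)), class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Voigt + linear peak fit: NOT converged (do not use the centre)\n")
  } else {
    cat(sprintf("Voigt + linear peak fit: center %.4f +/- %.4f %s\n",
                x$center, x$center_se, x$units))
    cat(sprintf("  widths (gaussian sd, lorentzian hwhm): %.4g, %.4g\n",
                x$sigma, x$gamma))
    cat(sprintf("  amplitude (area): %.4g; background %.4g + %.4g x\n",
                x$amplitude, x$bg_intercept, x$bg_slope))
  }
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) {
  c(center = object$center, sigma = object$sigma, gamma = object$gamma,
    amplitude = object$amplitude, bg_intercept = object$bg_intercept,
    bg_slope = object$bg_slope)
}

#' Fit a Voigt + linear model to a peak
#'
#' Nonlinear least squares of a Voigt profile plus a linear background over
#' a window. For diffraction profiles the window and centre are given as
#' spacings in A (fitted internally in q = 1/spacing, with the centre and
#' its standard error transformed back by the delta method); for EELS
#' spectra they are in eV. Convergence is reported and a fit whose centre
#' pins to the window edge, or whose amplitude is indistinguishable from
#' zero (e.g. a pure line with no peak), is flagged `converged = FALSE`.
#'
#' @param x a `radial_profile` or `eels_spectrum`.
#' @param window numeric length-2 fit window (A spacings for diffraction,
#'   eV for EELS), containing at least 8 grid points.
#' @param init_center initial centre, inside the window.
#' @param ... unused.
#' @return object of class `"peak_fit"` with the centre, Gaussian and
#'   Lorentzian widths, amplitude, background, centre standard error and a
#'   convergence flag.
#' @export
fit_peak_voigt_linear <- function(x, window, init_center, ...) {
  UseMethod("fit_peak_voigt_linear")
}

#' @rdname fit_peak_voigt_linear
#' @export
fit_peak_voigt_linear.radial_profile <- function(x, window = c(2.8, 4.5),
                                                 init_center = 3.7, ...) {
  qwin <- sort(1 / window)
  core <- fit_voigt_core(x$q, x$intensity, qwin, 1 / init_center)
  if (is.finite(core$center)) {
    cq <- core$center
    core$center <- 1 / cq
    core$center_se <- core$center_se / cq^2   # delta method for 1/q
  }
  core$window <- sort(window)
  new_peak_fit(core, units = "A")
}

#' @rdname fit_peak_voigt_linear
#' @export
fit_peak_voigt_linear.eels_spectrum <- function(x, window, init_center, ...) {
  core <- fit_voigt_core(x$energy, x$counts, sort(window), init_center)
  new_peak_fit(core, units = "eV")
}

#' Calibrate the spatial-frequency axis against a reference ring
#'
#' Fits the gold (111) reference peak and rescales the q axis so that its
#' centre sits at `1/reference_spacing`. The applied scale factor is
#' recorded in the profile's `calibration` field.
#'
#' @param profile a `radial_profile`.
#' @param reference_spacing reference lattice spacing in A (gold 111 =
#'   2.35 A).
#' @param window fit window in current axis units; defaults to spacings
#'   2.2-2.5 A assuming a roughly calibrated axis.
#' @param init_center initial peak position in current axis units.
#' @return the recalibrated `radial_profile`.
#' @export
calibrate_q <- function(profile, reference_spacing = 2.35,
                        window = sort(1 / c(2.2, 2.5)),
                        init_center = 1 / reference_spacing) {
  stopifnot(inherits(profile, "radial_profile"))
  core <- fit_voigt_core(profile$q, profile$intensity, sort(window),
                         init_center)
  if (!core$converged)
    stop("reference peak fit did not converge; cannot calibrate")
  scale <- (1 / reference_spacing) / core$center
  profile$q <- profile$q * scale
  profile$calibration <- if (is.na(profile$calibration)) scale
                         else profile$calibration * scale
  profile$units <- "A^-1"
  profile
}

#' Track a diffraction ring centre across a dose series
#'
#' Applies [fit_peak_voigt_linear()] frame by frame, carrying the previous
#' frame's fitted centre forward as the next initial guess. Non-converged
#' frames are flagged and do not update the running centre.
#'
#' @param profiles a `radial_profile_series` (e.g. from
#'   [gen_diffraction_profile()]) or a list of `radial_profile` objects.
#' @param window fit window in A spacing.
#' @param init_center initial ring position in A for the first frame.
#' @return data frame with columns `frame`, `fluence`, `center_A`, `se_A`,
#'   `converged`.
#' @export
peak_shift_series <- function(profiles, window = c(2.8, 4.5),
                              init_center = 3.7) {
  if (inherits(profiles, "radial_profile_series"))
    profiles <- lapply(seq_along(profiles$fluence),
                       function(f) profile_frame(profiles, f))
  n <- length(profiles)
  out <- data.frame(frame = seq_len(n), fluence = NA_real_,
                    center_A = NA_real_, se_A = NA_real_, converged = FALSE)
  cur <- init_center
  for (f in seq_len(n)) {
    fit <- fit_peak_voigt_linear(profiles[[f]], window = window,
                                 init_center = cur)
    out$fluence[f] <- profiles[[f]]$fluence
    out$center_A[f] <- fit$center
    out$se_A[f] <- fit$center_se
    out$converged[f] <- fit$converged
    if (fit$converged) cur <- fit$center
  }
  out
}

#' Plasmon energy from EELS spectra
#'
#' Per spectrum, fits a Voigt + linear model to the zero-loss peak (window
#' centred on the spectrum maximum) and to the plasmon peak (initialised at
#' 21 eV), and reports the mean of the per-spectrum differences
#' `plasmon - ZLP` with its standard error of the mean across spectra.
#' Taking the difference makes the result invariant to a common energy-axis
#' offset.
#'
#' @param spectra a list of `eels_spectrum` objects (a single spectrum is
#'   accepted; its SE is then reported as `NA`).
#' @param plasmon_window fit window for the plasmon peak in eV.
#' @param plasmon_init initial plasmon position in eV.
#' @param zlp_halfwindow half-width of the ZLP fit window around the
#'   spectrum maximum, eV.
#' @return object of class `"plasmon_result"` with fields `E_p` (eV), `SE`
#'   (eV, SEM across spectra), `n_spectra`, and the per-spectrum energies.
#' @export
plasmon_energy <- function(spectra, plasmon_window = c(13, 30),
                           plasmon_init = 21, zlp_halfwindow = 2) {
  if (inherits(spectra, "eels_spectrum")) spectra <- list(spectra)
  ep <- vapply(spectra, function(sp) {
    stopifnot(inherits(sp, "eels_spectrum"))
    e0 <- sp$energy[which.max(sp$counts)]
    zlp <- fit_peak_voigt_linear(sp, window = e0 + c(-1, 1) * zlp_halfwindow,
                                 init_center = e0)
    pl <- fit_peak_voigt_linear(sp, window = plasmon_window,
                                init_center = plasmon_init)
    if (!zlp$converged)
      stop("zero-loss peak fit did not converge")
    if (!pl$converged)
      stop("plasmon peak absent or fit did not converge")
    pl$center - zlp$center
  }, numeric(1))
  n <- length(ep)
  structure(list(E_p = mean(ep), SE = if (n > 1) sd(ep) / sqrt(n) else NA_real_,
                 n_spectra = n, per_spectrum = ep),
            class = "plasmon_result")
}

#' @export
print.plasmon_result <- function(x, ...) {
  cat(sprintf("Plasmon energy: %.2f +/- %s eV (SEM over %d spectra)\n",
              x$E_p, ifelse(is.na(x$SE), "NA", sprintf("%.2f", x$SE)),
              x$n_spectra))
  invisible(x)
}

#' Plasmon energy predicted from a density change
#'
#' The plasmon energy scales with the square root of the valence electron
#' density, which for water is proportional to the mass density:
#' `E = E_ref * sqrt(rho / rho_ref)`.
#'
#' @param E_ref reference plasmon energy in eV (low-density amorphous water:
#'   20.4 eV).
#' @param rho_ref reference mass density in g/cm^3 (LDA: 0.93).
#' @param rho queried mass density in g/cm^3 (HDA: 1.1).
#' @return predicted plasmon energy in eV.
#' @examples
#' plasmon_from_density(20.4, 0.93, 1.1)   # 22.2 eV
#' @export
plasmon_from_density <- function(E_ref, rho_ref, rho) {
  stopifnot_scalar(E_ref, "E_ref", positive = TRUE)
  stopifnot_scalar(rho_ref, "rho_ref", positive = TRUE)
  if (any(rho <= 0)) stop("'rho' must be > 0")
  E_ref * sqrt(rho / rho_ref)
}

#' Exclusion statistic for a density-change hypothesis
#'
#' Number of standard errors separating the predicted plasmon energy of a
#' hypothesised phase from the measured one:
#' `z = |predicted - E_p| / SE`.
#'
#' @param measured a [plasmon_energy()] result, or any list with fields
#'   `E_p` and `SE`.
#' @param predicted predicted plasmon energy in eV (e.g. from
#'   [plasmon_from_density()]).
#' @return dimensionless z value.
#' @export
density_exclusion_z <- function(measured, predicted) {
  if (!is.finite(measured$SE) || measured$SE <= 0)
    stop("'measured' must carry a positive standard error")
  abs(predicted - measured$E_p) / measured$SE
}
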