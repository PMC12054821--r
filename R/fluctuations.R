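## Dose-independent blurring sources: pseudo-Brownian motion estimated from
## frame-grouped power-spectrum peak intensities, and microscopic charge
## fluctuations via the spatial-coherence envelope.

#' Dephasing parameter of pseudo-Brownian motion
#'
#' `alpha_u = 2 pi^2 sigma0_sq u^2`, the exponential rate (per e-/A^2) at
#' which Fourier components at spatial frequency `u` decorrelate under a
#' random walk with per-axis mean-squared displacement `sigma0_sq` per unit
#' fluence.
#'
#' @param sigma0_sq mean-squared displacement per unit fluence per axis,
#'   A^2/(e-/A^2).
#' @param u spatial frequency in A^-1.
#' @return rate per e-/A^2.
#' @examples
#' alpha_u(0.01, 0.25)   # 0.012337
#' @export
alpha_u <- function(sigma0_sq, u) {
  if (any(sigma0_sq < 0)) stop("'sigma0_sq' must be >= 0")
  2 * pi^2 * sigma0_sq * u^2
}

#' Expected frame-grouped power-spectrum peak intensity
#'
#' The pseudo-Brownian model for the peak intensity of the sum of `M/m`
#' power spectra taken from frames grouped in batches of `m`:
#' `W = scale * M * m * d^2 * g(x)` with `x = alpha_u * m * d` and
#' `g(x) = 2 (x + exp(-x) - 1) / x^2` (equivalently
#' `W \propto (2 M d / alpha_u) * (x + exp(-x) - 1) / x`). `g` interpolates
#' the fully correlated limit `g -> 1` (W proportional to `M m d^2`) and
#' the decorrelated limit `g -> 2/x` (W proportional to `2 M d / alpha_u`,
#' independent of m).
#'
#' @param m frame-grouping count(s).
#' @param M total number of frames.
#' @param d fluence per original frame, e-/A^2.
#' @param alpha_u dephasing rate per e-/A^2 (see [alpha_u()]).
#' @param scale proportionality constant.
#' @return expected peak intensities (same length as `m`).
#' @export
brownian_peak_expected <- function(m, M, d, alpha_u, scale = 1) {
  x <- alpha_u * m * d
  g <- ifelse(x < 1e-6, 1 - x / 3 + x^2 / 12, 2 * (x + expm1(-x)) / x^2)
  scale * M * m * d^2 * g
}

#' Estimate pseudo-Brownian motion from grouped peak intensities
#'
#' Estimates `sigma0_sq`, the mean-squared displacement per unit fluence,
#' from peak intensities `W` versus frame grouping `m`. A straight line is
#' first fitted to the largest `tail_fraction` of `m*d` values and its slope
#' removed (frame-to-frame correlation such as imperfect gain correction
#' enters as a component linear in `m*d`); the residual is then fitted to
#' the dephasing model with free scale and `alpha_u`, followed by a joint
#' least-squares refinement of (scale, alpha_u, nuisance slope). Finally
#' `sigma0_sq = alpha_u / (2 pi^2 u^2)`.
#'
#' @param series a `spectral_peak_series` (see
#'   [gen_brownian_peak_series()]), with at least 4 groupings spanning
#'   small and large `m`.
#' @param tail_fraction fraction of the largest `m*d` values used for the
#'   initial linear-nuisance fit.
#' @return object of class `"brownian_fit"` with `sigma0_sq` (A^2 per
#'   e-/A^2), `se`, `alpha_u`, the removed `background_slope` (per unit
#'   m*d), and a convergence flag. A fitted `alpha_u <= 0` is reported as
#'   `sigma0_sq = 0` with `converged = FALSE`.
#' @export
brownian_sigma0 <- function(series, tail_fraction = 0.3) {
  stopifnot(inherits(series, "spectral_peak_series"))
  m <- series$m_list; W <- series$W
  M <- series$M; d <- series$d; u <- series$u
  if (length(m) < 4L) stop("need at least 4 frame groupings")
  md <- m * d
  ord <- order(md)
  m <- m[ord]; W <- W[ord]; md <- md[ord]
  ## (i) linear fit to the large-(m d) tail
  ntail <- max(2L, ceiling(tail_fraction * length(md)))
  tail <- seq.int(length(md) - ntail + 1L, length(md))
  lf <- lm(W[tail] ~ md[tail])
  slope0 <- unname(coef(lf)[2])
  ## (ii) subtract the linear-growth component
  Wres <- W - slope0 * md
  fail <- structure(list(sigma0_sq = 0, se = NA_real_, alpha_u = 0,
                         background_slope = slope0, converged = FALSE),
                    class = "brownian_fit")
  ## fully correlated limit: W is linear in m d and nothing remains
  if (max(abs(Wres)) < 1e-8 * max(abs(W))) return(fail)
  ## (iii) dephasing-model fit on the residual
  A0 <- max(Wres)
  small <- which.min(md)
  a0 <- max(2 * Wres[small] / (A0 * md[small]), 1e-6)
  shape <- function(au, mm) {
    x <- au * mm * d
    ifelse(x < 1e-6, (mm * d / 2) * (1 - x / 3), (x + expm1(-x)) / x)
  }
  fit1 <- tryCatch(
    minpack.lm::nlsLM(Wres ~ A * shape(au, m), start = list(A = A0, au = a0),
                      lower = c(A = 0, au = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit1)) return(fail)
  ## (iv) joint refinement: model + linear nuisance
  st <- as.list(coef(fit1)); st$cc <- slope0
  fit2 <- tryCatch(
    minpack.lm::nlsLM(W ~ A * shape(au, m) + cc * md, start = st,
                      lower = c(A = 0, au = 1e-12, cc = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  fit <- if (is.null(fit2)) fit1 else fit2
  au_hat <- unname(coef(fit)["au"])
  if (!is.finite(au_hat) || au_hat <= 1e-10) return(fail)
  se_au <- tryCatch(sqrt(diag(vcov(fit)))[["au"]], error = function(e) NA_real_)
  k <- 2 * pi^2 * u^2
  structure(list(sigma0_sq = au_hat / k, se = se_au / k, alpha_u = au_hat,
                 background_slope = if (is.null(fit2)) slope0
                                    else unname(coef(fit2)["cc"]),
                 converged = TRUE),
            class = "brownian_fit")
}

#' @export
print.brownian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Pseudo-Brownian fit: not converged (sigma0^2 reported as 0)\n")
  } else {
    cat(sprintf("Pseudo-Brownian motion: sigma0^2 = %.4g +/- %.2g A^2/(e-/A^2)\n",
                x$sigma0_sq, x$se))
    cat(sprintf("  alpha_u = %.4g per e-/A^2; background slope removed: %.3g\n",
                x$alpha_u, x$background_slope))
  }
  invisible(x)
}

#' @export
coef.brownian_fit <- function(object, ...) {
  c(sigma0_sq = object$sigma0_sq, alpha_u = object$alpha_u)
}

#' B-factor contributed by pseudo-Brownian motion
#'
#' `B = 8 pi^2 sigma0_sq * fluence`, consistent with the dephasing envelope
#' `exp(-alpha_u F) = exp(-B q^2 / 4)` at `q = u` (since
#' `8 pi^2 sigma0_sq = 4 * (2 pi^2 sigma0_sq)`). Linear in fluence.
#'
#' @param sigma0_sq mean-squared displacement per unit fluence, A^2/(e-/A^2).
#' @param fluence accumulated fluence in e-/A^2.
#' @return B-factor in A^2.
#' @examples
#' brownian_to_bfactor(0.01, 1)   # 0.7896
#' @export
brownian_to_bfactor <- function(sigma0_sq, fluence) {
  8 * pi^2 * sigma0_sq * fluence
}

#' Defocus series of diffraction-spot powers
#'
#' @param defocus defocus values in micrometres (negative = underfocus); at
#'   least 4.
#' @param power spot power at each defocus, >= 0.
#' @param q spatial frequency of the reflection in A^-1.
#' @param lambda_e electron wavelength in A.
#' @param Cs spherical aberration in mm.
#' @return object of class `"defocus_series"`.
#' @export
defocus_series <- function(defocus, power, q = 1 / 2.35, lambda_e = 0.01969,
                           Cs = 2.0) {
  if (length(defocus) != length(power)) stop("defocus/power length mismatch")
  if (length(defocus) < 4L) stop("need at least 4 defocus values")
  if (any(power < 0)) stop("powers must be >= 0")
  structure(list(defocus = defocus, power = power, q = q,
                 lambda_e = lambda_e, Cs = Cs),
            class = "defocus_series")
}

#' Spatial coherence envelope
#'
#' `Es(q) = exp[-(pi alpha / lambda)^2 (lambda dz q + Cs lambda^3 q^3)^2]`,
#' the fractional amplitude retained at spatial frequency `q` for a source
#' of semiangle `alpha` (1/e definition), defocus `dz` and spherical
#' aberration `Cs`.
#'
#' @param q spatial frequency, A^-1.
#' @param alpha source semiangle in rad.
#' @param lambda_e electron wavelength in A.
#' @param Cs spherical aberration in mm (converted internally to A).
#' @param defocus_um defocus in micrometres (converted internally to A).
#' @return fractional amplitude(s) in (0, 1].
#' @export
coherence_envelope <- function(q, alpha, lambda_e, Cs, defocus_um) {
  dz <- defocus_um * 1e4          # um -> A
  cs <- Cs * 1e7                  # mm -> A
  g <- lambda_e * dz * q + cs * lambda_e^3 * q^3
  exp(-(pi * alpha / lambda_e)^2 * g^2)
}

#' Source semiangle from a spot-power defocus series
#'
#' Fits measured diffraction-spot powers versus defocus to the squared
#' spatial-coherence envelope with free amplitude. Because
#' `ln(power) = ln A - 2 (pi alpha / lambda)^2 g(dz)^2` is linear in
#' `alpha^2`, the fit is an ordinary least-squares regression of log power
#' on the squared phase-gradient term `g(dz)^2` — exact in the noiseless
#' case, with the standard error of `alpha` propagated from the slope. The
#' result is invariant to overall power normalisation.
#'
#' A positive fitted slope (power increasing with defocus magnitude) is
#' non-physical and is flagged `converged = FALSE` with `alpha = 0`.
#'
#' @param series a [defocus_series()].
#' @return object of class `"coherence_fit"` with `alpha` (rad), `se`,
#'   `residual_norm` (of log powers) and a convergence flag.
#' @export
coherence_alpha <- function(series) {
  stopifnot(inherits(series, "defocus_series"))
  ok <- series$power > 0
  if (sum(ok) < 4L) stop("need at least 4 positive powers")
  dz <- series$defocus[ok] * 1e4
  cs <- series$Cs * 1e7
  lam <- series$lambda_e
  g2 <- (lam * dz * series$q + cs * lam^3 * series$q^3)^2
  fit <- lm(log(series$power[ok]) ~ g2)
  slope <- unname(coef(fit)[2])
  slope_se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  rn <- sqrt(sum(fit$residuals^2))
  if (slope > 0) {
    ## flat data gives slope 0 (alpha = 0, fine); a significantly positive
    ## slope means power grows with defocus magnitude - non-physical
    nonphys <- slope > 2 * slope_se || !is.finite(slope_se)
    return(structure(list(alpha = 0, se = NA_real_, residual_norm = rn,
                          converged = !nonphys),
                     class = "coherence_fit"))
  }
  alpha <- (lam / pi) * sqrt(-slope / 2)
  se <- (lam / pi) * slope_se / (4 * sqrt(-slope / 2))
  structure(list(alpha = alpha, se = unname(se), residual_norm = rn,
                 converged = TRUE),
            class = "coherence_fit")
}

#' @export
print.coherence_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Coherence-envelope fit: non-physical (power grows with defocus)\n")
  } else {
    cat(sprintf("Source semiangle: alpha = %.4g +/- %.2g rad\n", x$alpha, x$se))
  }
  invisible(x)
}

#' @export
coef.coherence_fit <- function(object, ...) c(alpha = object$alpha)
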