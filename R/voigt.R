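## Voigt profile via the complex error function.
##
## The Voigt profile is the convolution of a Gaussian (sd sigma) and a
## Lorentzian (HWHM gamma), evaluated through the Faddeeva function
## w(z) = exp(-z^2) erfc(-iz) at z = (x - center + i*gamma) / (sigma*sqrt(2)).

## Faddeeva function for Im(z) >= 0.  The direct formula through
## pracma::erfz suffers catastrophic cancellation for |z| beyond ~5, where the
## Laplace continued fraction is accurate, so the evaluation is split at
## |z| = 4 (both branches agree to <1e-6 relative there).
faddeeva_w <- function(z) {
  w <- complex(length(z))
  big <- Mod(z) >= 4
  if (any(!big)) {
    zs <- z[!big]
    w[!big] <- exp(-zs^2) * (1 - pracma::erfz(-1i * zs))
  }
  if (any(big)) {
    zb <- z[big]
    f <- zb
    for (a in rev(seq(0.5, 5.5, by = 0.5))) f <- zb - a / f
    w[big] <- 1i / sqrt(pi) / f
  }
  w
}

#' Unit-area Voigt profile
#'
#' Convolution of a Gaussian of standard deviation `sigma` with a Lorentzian
#' of half-width `gamma`, normalised to unit area. For `gamma = 0` this
#' reduces to the Gaussian density; for `sigma -> 0` to the Lorentzian.
#'
#' @param x numeric vector of abscissae (same units as `center`).
#' @param center peak position.
#' @param sigma Gaussian standard deviation, > 0.
#' @param gamma Lorentzian half-width at half-maximum, >= 0.
#' @return numeric vector of densities.
#' @examples
#' q <- seq(-5, 5, 0.1)
#' v <- voigt_profile(q, 0, 1, 0.5)
#' @export
voigt_profile <- function(x, center, sigma, gamma) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (gamma < 0) stop("'gamma' must be >= 0")
  z <- (x - center + 1i * gamma) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}
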