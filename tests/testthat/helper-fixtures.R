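# Shared fixture builders; everything is generated in code.

# Synthetic diffraction image: constant background plus a circular ring of
# given radius (px) and Gaussian radial width, optionally with a zeroed
# beam-stop wedge.
ring_image <- function(n = 128, center = c(64.5, 64.5), r0 = 40,
                       width = 2, height = 100, background = 10,
                       wedge = FALSE) {
  img <- matrix(background, n, n)
  r <- sqrt((col(img) - center[1])^2 + (row(img) - center[2])^2)
  img <- img + height * exp(-(r - r0)^2 / (2 * width^2))
  if (wedge) {
    ang <- atan2(row(img) - center[2], col(img) - center[1])
    img[ang > 0 & ang < pi / 12] <- 0
  }
  img
}

# Noiseless single-peak profile with linear background, for fit oracles.
voigt_trace <- function(q, center_q, sigma, gamma, area = 50,
                        b0 = 20, b1 = -10) {
  area * voigt_profile(q, center_q, sigma, gamma) + b0 + b1 * q
}
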