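#' Analytic time-domain reflectance from a homogeneous semi-infinite medium
#'
#' Standard extrapolated-boundary dipole solution of the time-domain
#' diffusion equation for a pencil source at the surface: an isotropic
#' source at depth \eqn{z_0 = 1/\mu_s'} and its negative image mirrored
#' about the extrapolated boundary at \eqn{z_b = 2AD} give the reflectance
#'
#' \deqn{R(\rho, t) = \frac{1}{2}(4\pi D c)^{-3/2} t^{-5/2}
#'   e^{-\mu_a c t - \rho^2/(4 D c t)}
#'   \left[z_0 e^{-z_0^2/(4Dct)} + (z_0 + 2 z_b) e^{-(z_0+2z_b)^2/(4Dct)}
#'   \right]}
#'
#' with \eqn{D = 1/(3\mu_s')}. The absolute scale is irrelevant after
#' self-normalization; the shape is what the homogeneous fit matches.
#'
#' @param rho source-detector separation, mm
#' @param t times, ps (values <= 0 return 0)
#' @param mua absorption, mm^-1
#' @param musp reduced scattering, mm^-1
#' @param n refractive index (sets A and the speed of light)
#' @return reflectance rate at each t (arbitrary amplitude units)
#' @export
semi_infinite_reflectance <- function(rho, t, mua, musp, n = 1.4) {
  D <- 1 / (3 * musp)
  cc <- light_speed(n)
  A <- robin_coefficient(n)
  z0 <- 1 / musp
  zb <- 2 * A * D
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  pref <- 0.5 * (4 * pi * D * cc)^(-1.5) * tp^(-2.5) *
    exp(-mua * cc * tp - rho^2 / (4 * D * cc * tp))
  out[pos] <- pref * (z0 * exp(-z0^2 / (4 * D * cc * tp)) +
                        (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / (4 * D * cc * tp)))
  out
}
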