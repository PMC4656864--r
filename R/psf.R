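#' Gaussian point-spread-function model
#'
#' The instrument blur is modelled as a spherically symmetric Gaussian of
#' radius `sigma` in the object frame: a point source of intensity \eqn{I} at
#' distance \eqn{\rho} from the geometric image centre contributes
#' \deqn{h(\rho) = \frac{I}{2\pi\sigma^2} e^{-\rho^2 / 2\sigma^2}.}
#' Because the Gaussian is spherically symmetric in three dimensions, a
#' fluorophore a height \eqn{z} out of the focal plane contributes a 2D
#' Gaussian attenuated by \eqn{e^{-z^2/2\sigma^2}}.
#'
#' `sigma_known` is the calibrated PSF radius of the instrument; the
#' quality-control rule accepts a fit only when the fitted sigma is positive
#' and at most `2 * sigma_known`.
#'
#' @param sigma PSF radius in object-frame nanometres.
#' @param sigma_known calibrated instrument PSF radius (nm) used by quality
#'   control; defaults to `sigma`.
#' @return an object of class `psf_model`.
#' @examples
#' psf <- psf_model(sigma = 130)
#' point_source_image(0, psf, intensity = 2 * pi * 130^2)
#' @export
psf_model <- function(sigma, sigma_known = sigma) {
  stop_if_not_positive(sigma, "sigma")
  stop_if_not_positive(sigma_known, "sigma_known")
  structure(list(sigma = sigma, sigma_known = sigma_known), class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("Gaussian PSF: sigma = %.1f nm (calibrated sigma = %.1f nm)\n",
              x$sigma, x$sigma_known))
  invisible(x)
}

#' Image of a point source
#'
#' Radial intensity profile \eqn{h(\rho) = (I/2\pi\sigma^2)\,
#' e^{-\rho^2/2\sigma^2}} of a point emitter of intensity `intensity` under a
#' Gaussian PSF. The profile integrates to `intensity` over the image plane.
#'
#' @param rho distance from the geometric image centre (nm); vectorised.
#' @param psf a [psf_model()].
#' @param intensity total intensity \eqn{I} of the point source.
#' @return intensity per unit area at distance `rho`.
#' @export
point_source_image <- function(rho, psf, intensity = 1) {
  stopifnot(inherits(psf, "psf_model"))
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("`rho` must be finite and non-negative")
  s2 <- psf$sigma^2
  intensity / (2 * pi * s2) * exp(-rho^2 / (2 * s2))
}

#' Defocus-dependent PSF radius
#'
#' Lateral Gaussian PSF radius of a widefield microscope as a function of the
#' emitter's height `z` above the focal plane, in the Gaussian-beam
#' approximation:
#' \deqn{\sigma(z) = \sigma_0 \sqrt{1 + (z/z_R)^2},}
#' with in-focus radius \eqn{\sigma_0 = 0.21\,\lambda/\mathrm{NA}} and axial
#' scale \eqn{z_R = n_{imm}\lambda/\mathrm{NA}^2}. The width is symmetric in
#' `z` and increases monotonically with `|z|`.
#'
#' @param z height above the focal plane (nm); vectorised.
#' @param wavelength emission wavelength (nm).
#' @param na numerical aperture of the objective.
#' @param n_imm immersion refractive index (oil, 1.515).
#' @return PSF radius (nm) at each `z`.
#' @examples
#' defocus_psf_sigma(0, wavelength = 500, na = 1.3)   # ~80.8 nm
#' @export
defocus_psf_sigma <- function(z, wavelength = 500, na = 1.3, n_imm = 1.515) {
  stop_if_not_positive(wavelength, "wavelength")
  stop_if_not_positive(na, "na")
  s0 <- 0.21 * wavelength / na
  zr <- n_imm * wavelength / na^2
  s0 * sqrt(1 + (z / zr)^2)
}
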