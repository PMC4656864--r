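# shared fixture builders: all synthetic inputs are generated in code

PW <- 74
CROP_CENTER <- 13.5 * PW   # centre of a 27 x 27 region, local nm

# wrap a 27 x 27 intensity matrix as a candidate fitting region
make_region <- function(img, center_pixel = c(14L, 14L), zero_level = 0,
                        index = 1L, frame_id = "test", radius_px = NULL) {
  structure(list(index = index, center_pixel = center_pixel, crop = img,
                 zero_level = zero_level, pixel_width = PW,
                 frame_id = frame_id, radius_px = radius_px),
            class = "candidate_region")
}

# noise-free rendered spherical-shell region with known truth
sphere_region <- function(a = 500, sigma = 130, I0 = 1) {
  grid <- pixel_grid(27, 27, PW)
  sh <- spherical_shell(CROP_CENTER, CROP_CENTER, a, I0)
  make_region(render_shell_image(sh, psf_model(sigma), grid))
}

# noise-free rendered Monte Carlo ellipsoid region
mc_region <- function(model, a, b, phi = 0, q = 0, sigma = 130,
                      n = 10000, seed = 1, brightness = 1000) {
  grid <- pixel_grid(27, 27, PW)
  sh <- ellipsoid_shell(x0 = CROP_CENTER, y0 = CROP_CENTER, a = a, b = b,
                        phi = phi, q = q)
  cloud <- switch(model,
                  stretched = stretched_sphere_points(sh, n, seed),
                  uniform = uniform_ellipsoid_points(sh, n, seed),
                  polarized = polarized_ellipsoid_points(sh, n, seed))
  make_region(render_point_cloud_image(cloud, brightness / n, psf_model(sigma), grid))
}

# stub fit result, for quality-control and summary tests
stub_fit <- function(sigma_fit, a = 500, b = NA_real_, q = NA_real_,
                     accepted = NA, epsilon = 0.01, frame_id = "test") {
  structure(list(model_kind = "sphere_algebraic", frame_id = frame_id,
                 candidate = 1L, epsilon = epsilon, accepted = accepted,
                 reject_reason = NA_character_, x0 = 999, y0 = 999, a = a,
                 b = b, phi = NA_real_, q = q, brightness = 1,
                 sigma_fit = sigma_fit),
            class = "fit_result")
}

# surface area of the ellipsoid band x in [x0, x1] (independent quadrature)
ellipsoid_band_area <- function(a, b, x0, x1) {
  rho <- function(x) a * sqrt(pmax(1 - x^2 / b^2, 0))
  drho <- function(x) -a * x / (b^2 * sqrt(pmax(1 - x^2 / b^2, 1e-12)))
  integrate(function(x) 2 * pi * rho(x) * sqrt(1 + drho(x)^2), x0, x1,
            rel.tol = 1e-8)$value
}
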