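test_that("normalized residual matches hand-computed values", {
  d <- matrix(c(1, 2), 1)
  expect_equal(residual_error(d, d), 0)
  expect_equal(residual_error(d, d * 0), 1)
  expect_equal(residual_error(c(1, 2), c(1, 1)), 0.2)
  expect_error(residual_error(c(0, 0), c(1, 1)), "all-zero")
  expect_error(residual_error(c(1, 2, 3), c(1, 2)), "shape")
})

test_that("quality control accepts sigma up to exactly twice the calibrated PSF", {
  psf <- psf_model(100)
  expect_true(quality_control(stub_fit(100), psf)$accepted)
  expect_true(quality_control(stub_fit(200), psf)$accepted)       # boundary
  expect_false(quality_control(stub_fit(200.0001), psf)$accepted) # just past it
  expect_false(quality_control(stub_fit(210), psf)$accepted)
  expect_false(quality_control(stub_fit(0), psf)$accepted)
  expect_false(quality_control(stub_fit(-5), psf)$accepted)
  expect_false(quality_control(stub_fit(NA_real_), psf)$accepted)
  r <- quality_control(stub_fit(210), psf)
  expect_equal(r$reject_reason, "sigma_out_of_range")
})

test_that("equal-volume radius interpolates between the axes", {
  expect_equal(equal_volume_radius(420, 420), 420)
  expect_equal(equal_volume_radius(500, 800), (500^2 * 800)^(1 / 3))
  expect_lt(abs(equal_volume_radius(500, 800) - 584.8), 0.05)
  a <- seq(300, 500, by = 50)
  expect_true(all(diff(equal_volume_radius(a, 800)) > 0))
  expect_true(all(diff(equal_volume_radius(300, a + 300)) > 0))
  r <- equal_volume_radius(400, 700)
  expect_true(r > 400 && r < 700)
  expect_error(equal_volume_radius(500, 400), "a <= b")
})

test_that("surface-tension anisotropy has the spherical, moderate and extreme values", {
  expect_equal(anisotropy_ratio(1), 1)
  expect_equal(anisotropy_ratio(sqrt(3)), 1.2)
  expect_lt(anisotropy_ratio(1e4), 4 / 3)
  expect_equal(anisotropy_ratio(1e4), 4 / 3, tolerance = 1e-6)
  expect_true(all(diff(anisotropy_ratio(c(1, 1.2, 1.5, 2, 3))) > 0))
  expect_error(anisotropy_ratio(0.9), "aspect")
})

test_that("algebraic sphere fit recovers noise-free truth to sub-nanometre accuracy", {
  reg <- sphere_region(a = 500, sigma = 130)
  fit <- fit_sphere_algebraic(reg, psf_model(130))
  expect_true(fit$accepted)
  expect_lt(abs(fit$a - 500), 1)
  expect_lt(abs(fit$sigma_fit - 130), 1)
  expect_lt(abs(fit$x0 - CROP_CENTER), 1)
  expect_lt(abs(fit$y0 - CROP_CENTER), 1)
  expect_lt(fit$epsilon, 1e-6)
})

test_that("pure-noise regions are rejected by sigma-based quality control", {
  psf <- psf_model(100)
  rejected <- vapply(1:10, function(s) {
    set.seed(s)
    fit <- fit_sphere_algebraic(make_region(matrix(runif(729, 0, 100), 27)), psf)
    !isTRUE(fit$accepted)
  }, TRUE)
  expect_gte(mean(rejected), 0.9)
  ## an all-zero region is rejected with a recorded reason, not an error
  f0 <- fit_sphere_algebraic(make_region(matrix(0, 27, 27)), psf)
  expect_false(f0$accepted)
  expect_equal(f0$reject_reason, "empty_region")
})

test_that("random-search fitter recovers a noise-free uniform ellipsoid", {
  ## the objective's fixed 2500-fluorophore sample carries ~2% shape noise,
  ## so recovery is assessed on the mean of a few independent fits
  fits <- lapply(1:3, function(s) {
    reg <- mc_region("uniform", a = 450, b = 750, phi = 0.5, n = 10000,
                     seed = 40 + s)
    fit_ellipsoid_mc(reg, psf_model(130), "ellipsoid_uniform", seed = 45 + s)
  })
  expect_true(all(vapply(fits, function(f) f$accepted, TRUE)))
  expect_lt(abs(mean(vapply(fits, function(f) f$a, 0)) - 450) / 450, 0.02)
  expect_lt(abs(mean(vapply(fits, function(f) f$b, 0)) - 750) / 750, 0.02)
  expect_lt(abs(mean(vapply(fits, function(f) f$phi, 0)) - 0.5), 0.05)
  expect_true(all(vapply(fits, function(f) f$phi_reliable, TRUE)))
})

test_that("sphere data fitted with the ellipsoid model stays near aspect one", {
  reg <- sphere_region(a = 500, sigma = 130)
  fit <- fit_ellipsoid_mc(reg, psf_model(130), "ellipsoid_uniform", seed = 5)
  expect_gte(fit$b / fit$a, 1)
  expect_lte(fit$b / fit$a, 1.05)
  expect_false(fit$phi_reliable)
})

test_that("model capacity is monotone when each search starts from the simpler optimum", {
  reg <- mc_region("polarized", a = 450, b = 700, phi = 0.3, q = 0.4,
                   n = 10000, seed = 51)
  psf <- psf_model(130)
  f_sph <- fit_ellipsoid_mc(reg, psf, "sphere_mc", seed = 52)
  f_uni <- fit_ellipsoid_mc(reg, psf, "ellipsoid_uniform", seed = 52, init = f_sph)
  f_pol <- fit_ellipsoid_mc(reg, psf, "ellipsoid_polarized", seed = 52, init = f_uni)
  ## small slack: the nested searches share parameters but not the exact
  ## fluorophore sample, so the objective carries Monte Carlo jitter
  expect_lte(f_uni$epsilon, f_sph$epsilon + 0.002)
  expect_lte(f_pol$epsilon, f_uni$epsilon + 0.002)
  expect_lt(f_pol$epsilon, f_sph$epsilon)
})

test_that("frame and experiment summaries are unweighted and across-field", {
  one <- stub_fit(100, a = 480, accepted = TRUE)
  s1 <- summarize_frame(list(one))
  expect_equal(s1$n_accepted, 1)
  expect_equal(s1$mean_radius, 480)
  ## ellipsoid results are summarised by equal-volume radius and aspect
  e1 <- stub_fit(100, a = 400, b = 800, q = 0.3, accepted = TRUE)
  e2 <- stub_fit(100, a = 500, b = 700, q = 0.1, accepted = TRUE)
  rej <- stub_fit(300, a = 999, accepted = FALSE)
  s2 <- summarize_frame(list(e1, e2, rej))
  expect_equal(s2$n_accepted, 2)
  expect_equal(s2$mean_radius,
               mean(equal_volume_radius(c(400, 500), c(800, 700))))
  expect_equal(s2$mean_aspect, mean(c(2, 1.4)))
  expect_equal(s2$mean_polarity, 0.2)
  ## permutation invariance
  s2p <- summarize_frame(list(rej, e2, e1))
  expect_equal(s2p$mean_radius, s2$mean_radius)
  ## zero accepted -> empty summary
  s0 <- summarize_frame(list(rej))
  expect_true(s0$empty)
  expect_true(is.na(s0$mean_radius))
  ## across-field statistics are over fields, not spores
  f1 <- summarize_frame(list(stub_fit(90, a = 490, accepted = TRUE),
                             stub_fit(90, a = 510, accepted = TRUE)))
  f2 <- summarize_frame(list(stub_fit(90, a = 520, accepted = TRUE)))
  f3 <- summarize_frame(list(stub_fit(90, a = 505, accepted = TRUE)))
  ex <- summarize_experiment(list(f1, f2, f3))
  expect_equal(unname(ex$radius["mean"]), mean(c(500, 520, 505)))
  expect_equal(unname(ex$radius["sd"]), sd(c(500, 520, 505)))
  expect_warning(summarize_experiment(list(f1, f2)), "fewer than 3")
})
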