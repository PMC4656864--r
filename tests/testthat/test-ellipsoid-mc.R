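test_that("trig-method sphere sampling is uniform and deterministic", {
  cl <- sample_unit_sphere(1e5, seed = 7)
  expect_lt(max(abs(sqrt(rowSums(cl^2)) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(cl))), 3 / sqrt(1e5))
  ## octant occupancy: chi-square with 7 df, alpha = 0.001, several seeds
  for (s in 1:5) {
    p <- sample_unit_sphere(2e4, seed = s)
    oct <- tabulate(1 + (p[, 1] > 0) + 2 * (p[, 2] > 0) + 4 * (p[, 3] > 0), 8)
    chi <- sum((oct - 2e4 / 8)^2 / (2e4 / 8))
    expect_gt(pchisq(chi, df = 7, lower.tail = FALSE), 0.001)
  }
  expect_identical(sample_unit_sphere(100, seed = 3), sample_unit_sphere(100, seed = 3))
})

test_that("stretched-sphere points lie on the ellipsoid and crowd the poles", {
  sh <- ellipsoid_shell(x0 = 50, y0 = -20, a = 400, b = 800, phi = 0.7)
  p <- stretched_sphere_points(sh, 1e5, seed = 2)
  ## undo rotation and recentre, then check the implicit surface equation
  cp <- cos(sh$phi); sp <- sin(sh$phi)
  x <- cp * (p[, 1] - sh$x0) + sp * (p[, 2] - sh$y0)
  y <- -sp * (p[, 1] - sh$x0) + cp * (p[, 2] - sh$y0)
  fval <- x^2 / sh$b^2 + y^2 / sh$a^2 + p[, 3]^2 / sh$a^2
  expect_lt(max(abs(fval - 1)), 1e-9)
  ## degenerate stretch b = a reproduces the scaled sphere sample exactly
  shs <- ellipsoid_shell(a = 300, b = 300, phi = 0)
  expect_equal(unclass(stretched_sphere_points(shs, 1000, seed = 9))[, 1:3],
               unclass(300 * sample_unit_sphere(1000, seed = 9))[, 1:3],
               ignore_attr = TRUE)
  ## per-area density near the poles exceeds the equator by about b/a
  sh2 <- ellipsoid_shell(a = 400, b = 800, phi = 0)
  p2 <- stretched_sphere_points(sh2, 2e5, seed = 4)
  pole_cut <- 0.9 * sh2$b
  eq_cut <- 0.1 * sh2$b
  area_pole <- 2 * ellipsoid_band_area(sh2$a, sh2$b, pole_cut, sh2$b)
  area_eq <- 2 * ellipsoid_band_area(sh2$a, sh2$b, 0, eq_cut)
  x2 <- p2[, 1] - sh2$x0
  dens_pole <- sum(abs(x2) > pole_cut) / area_pole
  dens_eq <- sum(abs(x2) < eq_cut) / area_eq
  expect_gt(dens_pole, dens_eq)
  expect_lt(abs(dens_pole / dens_eq - sh2$b / sh2$a), 0.25)
})

test_that("uniform-ellipsoid retention probabilities follow the area scale factor", {
  sh <- ellipsoid_shell(a = 400, b = 800)
  ## poles, equator, and sphere special cases of the retention probability
  expect_equal(ellipsoid_retention_prob(c(sh$b, 0, 0), sh), sh$a / sh$b,
               ignore_attr = TRUE)
  expect_equal(ellipsoid_retention_prob(c(0, sh$a, 0), sh), 1, ignore_attr = TRUE)
  shs <- ellipsoid_shell(a = 300, b = 300)
  u <- 300 * sample_unit_sphere(500, seed = 1)
  expect_equal(max(abs(ellipsoid_retention_prob(unclass(u), shs) - 1)), 0,
               tolerance = 1e-12)
  ## retained points are uniform per unit area: chi-square over bands of
  ## equal area computed by independent quadrature
  p <- uniform_ellipsoid_points(sh, 5e4, seed = 6)
  x <- p[, 1] - sh$x0
  cuts <- seq(0, sh$b, length.out = 9)
  areas <- vapply(seq_len(8), function(k)
    2 * ellipsoid_band_area(sh$a, sh$b, cuts[k], cuts[k + 1]), 0)
  counts <- vapply(seq_len(8), function(k)
    sum(abs(x) >= cuts[k] & abs(x) < cuts[k + 1]), 0)
  expected <- 5e4 * areas / sum(areas)
  chi <- sum((counts - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 7, lower.tail = FALSE), 0.001)
  ## points satisfy the surface equation
  fval <- x^2 / sh$b^2 + (p[, 2] - sh$y0)^2 / sh$a^2 + p[, 3]^2 / sh$a^2
  expect_lt(max(abs(fval - 1)), 1e-9)
})

test_that("polarity bias reduces correctly at q = 0, 1 and -1", {
  sh <- ellipsoid_shell(a = 400, b = 800)
  pts <- rbind(c(800, 0, 0), c(0, 400, 0), c(0, 0, 400), c(500, 200, 150))
  ## q = 0 reduces to the uniform retention probability everywhere
  expect_equal(polarized_retention_prob(pts, sh, q = 0),
               ellipsoid_retention_prob(pts, sh))
  ## q = 1 kills the equator
  expect_equal(polarized_retention_prob(c(0, 400, 0), sh, q = 1), 0,
               ignore_attr = TRUE)
  ## q = -1 on a sphere: C = 1/2, so equator keeps 1 and poles keep 1/2
  shs <- ellipsoid_shell(a = 300, b = 300)
  expect_equal(polarized_retention_prob(c(0, 300, 0), shs, q = -1), 1,
               ignore_attr = TRUE)
  expect_equal(polarized_retention_prob(c(300, 0, 0), shs, q = -1), 0.5,
               ignore_attr = TRUE)
  ## probabilities stay in [0, 1] across q
  for (q in c(-1, -0.3, 0.5, 1)) {
    p <- polarized_retention_prob(unclass(stretched_sphere_points(sh, 1000, seed = 2)) -
                                    cbind(rep(sh$x0, 1000), sh$y0, 0), sh, q = q)
    expect_true(all(p >= 0 & p <= 1 + 1e-12))
  }
  expect_error(ellipsoid_shell(a = 300, b = 400, q = 1.2), "q")
  ## q = 0 sampling is identical to the uniform sampler under the same seed
  expect_identical(polarized_ellipsoid_points(sh, 500, seed = 11),
                   uniform_ellipsoid_points(sh, 500, seed = 11))
})

test_that("point-cloud rendering conserves flux and reproduces the point-source profile", {
  grid <- pixel_grid(27, 27, PW)
  psf <- psf_model(130)
  ## single in-focus point: pixel values match the discretised Gaussian
  cen <- CROP_CENTER
  img1 <- render_point_cloud_image(matrix(c(cen, cen, 0), 1), 5, psf, grid)
  expect_equal(sum(img1) * PW^2, 5, tolerance = 1e-6)
  ## profile decreases with distance from the source like the Gaussian
  expect_equal(img1[14, 14], max(img1))
  expect_gt(img1[14, 15], img1[14, 20])
  ## flux of a well-contained shell: n I attenuated by the 3D-Gaussian
  ## out-of-plane factor
  a <- 400
  cl <- sample_unit_sphere(2e4, seed = 5)
  cloud <- cbind(a * cl[, 1] + cen, a * cl[, 2] + cen, a * cl[, 3])
  img <- render_point_cloud_image(cloud, 2, psf, grid)
  expect_equal(sum(img) * PW^2, sum(2 * exp(-cloud[, 3]^2 / (2 * 130^2))),
               tolerance = 1e-6)
  ## determinism: same seed gives bit-identical clouds and images
  sh <- ellipsoid_shell(x0 = cen, y0 = cen, a = 350, b = 600, q = 0.4)
  c1 <- polarized_ellipsoid_points(sh, 2000, seed = 8)
  c2 <- polarized_ellipsoid_points(sh, 2000, seed = 8)
  expect_identical(c1, c2)
  expect_identical(render_point_cloud_image(c1, 1, psf, grid),
                   render_point_cloud_image(c2, 1, psf, grid))
})

test_that("Monte Carlo sphere image converges to the closed-form rendering", {
  grid <- pixel_grid(27, 27, PW)
  psf <- psf_model(130)
  a <- 500; I0 <- 2
  alg <- render_shell_image(spherical_shell(CROP_CENTER, CROP_CENTER, a, I0), psf, grid)
  cl <- sample_unit_sphere(1e5, seed = 12)
  cloud <- cbind(a * cl[, 1] + CROP_CENTER, a * cl[, 2] + CROP_CENTER, a * cl[, 3])
  mc <- render_point_cloud_image(cloud, 4 * pi * a^2 * I0 / 1e5, psf, grid)
  expect_lt(sqrt(mean((mc - alg)^2)) / sqrt(mean(alg^2)), 0.02)
})

test_that("stretched model shows brighter poles than the uniform model", {
  grid <- pixel_grid(27, 27, PW)
  psf <- psf_model(130)
  sh <- ellipsoid_shell(x0 = CROP_CENTER, y0 = CROP_CENTER, a = 420,
                        b = 420 * 1.7, phi = 0)
  st <- render_point_cloud_image(stretched_sphere_points(sh, 1e5, seed = 3),
                                 1e-2, psf, grid)
  un <- render_point_cloud_image(uniform_ellipsoid_points(sh, 1e5, seed = 3),
                                 1e-2, psf, grid)
  ## polar-to-equatorial brightness ratio along the image axes
  pole_px <- round((CROP_CENTER + sh$b) / PW)
  eq_px <- round((CROP_CENTER + sh$a) / PW)
  ratio <- function(img) img[14, pole_px] / img[eq_px, 14]
  expect_gt(ratio(st), ratio(un))
})
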