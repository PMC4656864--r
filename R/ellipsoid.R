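#' Ellipsoidal fluorescent shell
#'
#' A prolate ellipsoid of revolution with its long axis lying flat in the
#' object plane: semimajor axis `b` along the (rotated) x direction and two
#' equal semiminor axes `a`. In the unrotated frame the surface satisfies
#' \deqn{x^2/b^2 + y^2/a^2 + z^2/a^2 = 1.}
#' The in-plane orientation of the long axis is `phi` (radians, taken modulo
#' \eqn{\pi}), and `q` is the polarity: `q > 0` enriches fluorophores at the
#' poles, `q < 0` at the equator, `q = 0` is unbiased. `q` must not exceed 1
#' or the biased retention probability would become negative at the equator.
#'
#' @param x0,y0 centre position in the object frame (nm).
#' @param a semiminor axis (nm).
#' @param b semimajor axis (nm), `b >= a`.
#' @param phi orientation of the major axis in the object plane (radians).
#' @param q polarity, `<= 1`.
#' @param I intensity per fluorophore.
#' @param n_fluorophores number of fluorophores rendered for this shell.
#' @return an object of class `ellipsoid_shell`.
#' @export
ellipsoid_shell <- function(x0 = 0, y0 = 0, a, b = a, phi = 0, q = 0, I = 1,
                            n_fluorophores = 2500) {
  stop_if_not_positive(a, "a")
  stop_if_not_positive(b, "b")
  if (b < a) stop("`b` must be at least `a` (prolate convention)")
  if (!is.numeric(q) || q > 1) stop("`q` must be <= 1")
  if (n_fluorophores < 1) stop("`n_fluorophores` must be at least 1")
  structure(list(x0 = x0, y0 = y0, a = a, b = b, phi = phi %% pi, q = q,
                 I = I, n_fluorophores = as.integer(n_fluorophores)),
            class = "ellipsoid_shell")
}

#' @export
print.ellipsoid_shell <- function(x, ...) {
  cat(sprintf(paste0("ellipsoid shell: a = %.0f nm, b = %.0f nm (b/a = %.2f), ",
                     "phi = %.2f rad, q = %.2f, %d fluorophores\n"),
              x$a, x$b, x$b / x$a, x$phi, x$q, x$n_fluorophores))
  invisible(x)
}

new_point_cloud <- function(xyz, shell = NULL) {
  colnames(xyz) <- c("x", "y", "z")
  structure(xyz, class = c("point_cloud", "matrix", "array"), shell = shell)
}

#' Uniform random points on the unit sphere
#'
#' The "trig method": the azimuth is uniform on \eqn{[0, 2\pi)} and the
#' cosine of the polar angle uniform on \eqn{[-1, 1]}, which makes the
#' probability of landing in any surface patch proportional to its area.
#'
#' @param n number of points.
#' @param seed optional integer; when given, sampling is deterministic and the
#'   caller's RNG state is left untouched.
#' @return an `n x 3` matrix of class `point_cloud` with unit-norm rows.
#' @export
sample_unit_sphere <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    u <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    st <- sqrt(1 - u^2)
    new_point_cloud(cbind(st * cos(phi), st * sin(phi), u))
  })
}

## rotate points about z by angle phi (active rotation) and recentre
place_points <- function(xyz, shell) {
  cp <- cos(shell$phi); sp <- sin(shell$phi)
  out <- cbind(cp * xyz[, 1] - sp * xyz[, 2] + shell$x0,
               sp * xyz[, 1] + cp * xyz[, 2] + shell$y0,
               xyz[, 3])
  new_point_cloud(out, shell)
}

#' Fluorophore positions for a stretched-sphere shell
#'
#' Samples the unit sphere uniformly, stretches linearly onto the ellipsoid
#' (`x = b x'`, `y = a y'`, `z = a z'`), then rotates about the z axis by
#' `phi` and recentres. The anisotropic stretch concentrates points near the
#' poles (per unit ellipsoid surface area), which makes the rendered poles
#' relatively bright — the signature of a layer formed as a uniform sphere
#' and subsequently deformed.
#'
#' @param shell an [ellipsoid_shell()].
#' @param n number of fluorophores (default `shell$n_fluorophores`).
#' @inheritParams sample_unit_sphere
#' @return a `point_cloud` on the ellipsoid surface.
#' @export
stretched_sphere_points <- function(shell, n = shell$n_fluorophores, seed = NULL) {
  stopifnot(inherits(shell, "ellipsoid_shell"))
  u <- sample_unit_sphere(n, seed)
  place_points(cbind(shell$b * u[, 1], shell$a * u[, 2], shell$a * u[, 3]), shell)
}

#' Retention probability for uniform-density ellipsoid sampling
#'
#' For a point `(x, y, z)` on the ellipsoid surface (unrotated, centred
#' frame), the ratio of the local area scale factor of the sphere-to-ellipsoid
#' stretch to its maximum:
#' \deqn{p = a \left(x^2/b^4 + y^2/a^4 + z^2/a^4\right)^{1/2}.}
#' `p` equals `a/b` at the poles, 1 on the equator, and 1 everywhere on a
#' sphere. Thinning stretched-sphere points with retention probability `p`
#' yields points uniform per unit surface area.
#'
#' @param xyz an `n x 3` matrix of surface points in the unrotated, centred
#'   ellipsoid frame.
#' @param shell an [ellipsoid_shell()].
#' @return retention probabilities in `(0, 1]`.
#' @export
ellipsoid_retention_prob <- function(xyz, shell) {
  stopifnot(inherits(shell, "ellipsoid_shell"))
  xyz <- rbind(xyz)
  shell$a * sqrt(xyz[, 1]^2 / shell$b^4 +
                   (xyz[, 2]^2 + xyz[, 3]^2) / shell$a^4)
}

#' Polarity-biased retention probability
#'
#' Multiplies the uniform-ellipsoid retention probability by a polarity bias
#' \eqn{1 - q \sin(t)}, where \eqn{\sin(t) = \sqrt{y^2+z^2}/\sqrt{x^2+y^2+z^2}}
#' is 0 at the poles and 1 on the equator; the normalisation `C` is 1 for
#' `q >= 0` and `1/(1-q)` for `q < 0`, keeping the probability within
#' `[0, 1]` for all `q <= 1`.
#'
#' @inheritParams ellipsoid_retention_prob
#' @param q polarity, `<= 1`; defaults to `shell$q`.
#' @return biased retention probabilities in `[0, 1]`.
#' @export
polarized_retention_prob <- function(xyz, shell, q = shell$q) {
  if (q > 1) stop("`q` must be <= 1")
  xyz <- rbind(xyz)
  p <- ellipsoid_retention_prob(xyz, shell)
  sint <- sqrt(xyz[, 2]^2 + xyz[, 3]^2) /
    sqrt(xyz[, 1]^2 + xyz[, 2]^2 + xyz[, 3]^2)
  C <- if (q < 0) 1 / (1 - q) else 1
  C * p * (1 - q * sint)
}

## rejection sampler shared by the uniform and polarized models; resamples
## until exactly n points are retained so that total image brightness (n * I)
## does not depend on b/a or q
rejection_sample <- function(shell, n, seed, prob_fun) {
  with_seed(seed, {
    kept <- matrix(0, 0, 3)
    while (nrow(kept) < n) {
      m <- max(2L * (n - nrow(kept)), 64L)
      u <- sample_unit_sphere(m)   # uses the (already seeded) local stream
      xyz <- cbind(shell$b * u[, 1], shell$a * u[, 2], shell$a * u[, 3])
      keep <- runif(m) < prob_fun(xyz)
      kept <- rbind(kept, xyz[keep, , drop = FALSE])
    }
    place_points(kept[seq_len(n), , drop = FALSE], shell)
  })
}

#' Fluorophore positions uniform per unit ellipsoid surface area
#'
#' Stretched-sphere points thinned by the retention probability
#' [ellipsoid_retention_prob()] (rejection sampling), resampling until exactly
#' `n` points are retained.
#'
#' @inheritParams stretched_sphere_points
#' @return a `point_cloud` uniform on the ellipsoid surface.
#' @export
uniform_ellipsoid_points <- function(shell, n = shell$n_fluorophores, seed = NULL) {
  stopifnot(inherits(shell, "ellipsoid_shell"))
  rejection_sample(shell, n, seed, function(xyz) ellipsoid_retention_prob(xyz, shell))
}

#' Fluorophore positions with polar or equatorial localization bias
#'
#' Uniform-ellipsoid sampling with the additional polarity bias
#' [polarized_retention_prob()]. `q = 0` reduces exactly to
#' [uniform_ellipsoid_points()]; `q > 0` enriches the poles and `q < 0` the
#' equator.
#'
#' @inheritParams stretched_sphere_points
#' @return a `point_cloud` on the ellipsoid surface.
#' @export
polarized_ellipsoid_points <- function(shell, n = shell$n_fluorophores, seed = NULL) {
  stopifnot(inherits(shell, "ellipsoid_shell"))
  rejection_sample(shell, n, seed,
                   function(xyz) polarized_retention_prob(xyz, shell))
}

#' Render a fluorophore point cloud as a widefield image
#'
#' Sums the Gaussian point-source image of every fluorophore on the detector
#' grid. The PSF is the spherically symmetric 3D Gaussian of the shell image
#' model, so a fluorophore at height `z` contributes a 2D Gaussian of weight
#' \eqn{I e^{-z^2/2\sigma^2}}. Pixel values are the exact mean of the model
#' intensity over each pixel footprint (separable Gaussian integrals). With
#' enough fluorophores the rendering of a spherical cloud converges to the
#' closed-form [render_shell_image()].
#'
#' @param cloud a `point_cloud` (absolute object-frame nm).
#' @param I intensity per fluorophore.
#' @param psf a [psf_model()].
#' @param grid a [pixel_grid()].
#' @return a `n_rows x n_cols` matrix of mean pixel intensities.
#' @export
render_point_cloud_image <- function(cloud, I, psf, grid) {
  stopifnot(inherits(psf, "psf_model"), inherits(grid, "pixel_grid"))
  if (is.null(dim(cloud)) || nrow(cloud) == 0) stop("`cloud` must be a non-empty point matrix")
  s <- psf$sigma
  amp <- I * exp(-cloud[, 3]^2 / (2 * s^2))
  img <- render_gauss_points(cloud[, 1], cloud[, 2], amp,
                             rep(s, nrow(cloud)),
                             grid$n_rows, grid$n_cols, grid$pixel_width,
                             window = -1)
  img / grid$pixel_width^2
}
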