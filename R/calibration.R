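#' Specification of a calibration simulation
#'
#' Describes a synthetic widefield frame of fluorophore-decorated shells of
#' exactly known geometry, used to validate the inference pipeline. Defaults
#' reproduce the reference calibration conditions: spherical shells of radius
#' exactly 500 nm decorated with 10,000 fluorophores, imaged through a 1.3 NA
#' oil objective at 500 nm emission onto 74 nm pixels with 100% fill factor,
#' with shell centres in the focal plane.
#'
#' The simulated PSF is the spherically symmetric 3D Gaussian of the analysis
#' model augmented with defocus: a fluorophore at height `z` is rendered as a
#' 2D Gaussian of width [defocus_psf_sigma()]`(z)` carrying detected flux
#' attenuated by \eqn{e^{-z^2/2\sigma_0^2}}. Camera noise is Poisson shot
#' noise on the photon counts plus Gaussian read noise, quantised to the
#' camera bit depth.
#'
#' @param radius true shell radius (nm); for `aspect > 1` this is the
#'   semiminor axis `a`.
#' @param aspect axes ratio `b/a` of the simulated shells (1 = spheres).
#' @param polarity polarity `q` of the fluorophore distribution.
#' @param model fluorophore placement model for aspherical shells: one of
#'   `"sphere"`, `"stretched"`, `"uniform"`, `"polarized"`.
#' @param n_fluorophores fluorophores per shell.
#' @param wavelength emission wavelength (nm).
#' @param na objective numerical aperture.
#' @param n_imm immersion refractive index.
#' @param pixel_width object-frame pixel width (nm).
#' @param n_rows,n_cols frame size in pixels.
#' @param n_shells shells per frame (placed at least `min_separation_px`
#'   pixels apart on a jittered grid).
#' @param min_separation_px minimum centre-to-centre distance (pixels).
#' @param photons_per_fluorophore expected detected photons from an in-focus
#'   fluorophore.
#' @param read_noise Gaussian read noise (counts RMS).
#' @param bit_depth camera quantisation depth; pixel values are clipped to
#'   `2^bit_depth - 1`.
#' @param noise simulate shot/read noise and quantisation (disable for
#'   noise-free oracle comparisons).
#' @param seed integer seed; one frame is fully determined by its spec.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(radius = 500, aspect = 1, polarity = 0,
                            model = c("sphere", "stretched", "uniform", "polarized"),
                            n_fluorophores = 10000, wavelength = 500, na = 1.3,
                            n_imm = 1.515, pixel_width = 74,
                            n_rows = 400, n_cols = 480, n_shells = 50,
                            min_separation_px = 27,
                            photons_per_fluorophore = 30, read_noise = 2,
                            bit_depth = 12, noise = TRUE, seed = 1L) {
  model <- match.arg(model)
  stop_if_not_positive(radius, "radius")
  if (aspect < 1) stop("`aspect` must be >= 1")
  if (polarity > 1) stop("`polarity` must be <= 1")
  stopifnot(n_fluorophores >= 1, n_shells >= 1, bit_depth >= 1)
  structure(list(radius = radius, aspect = aspect, polarity = polarity,
                 model = model, n_fluorophores = as.integer(n_fluorophores),
                 wavelength = wavelength, na = na, n_imm = n_imm,
                 pixel_width = pixel_width, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), n_shells = as.integer(n_shells),
                 min_separation_px = min_separation_px,
                 photons_per_fluorophore = photons_per_fluorophore,
                 read_noise = read_noise, bit_depth = as.integer(bit_depth),
                 noise = isTRUE(noise), seed = as.integer(seed)),
            class = "simulation_spec")
}

## jittered-grid shell centres at least min_separation_px apart
place_shells <- function(spec) {
  pw <- spec$pixel_width
  margin <- REGION_HALF + 7
  jitter_px <- 4
  pitch <- ceiling(spec$min_separation_px + 2 * jitter_px + 1)
  nr <- floor((spec$n_rows - 2 * margin) / pitch)
  nc <- floor((spec$n_cols - 2 * margin) / pitch)
  if (nr * nc < spec$n_shells)
    stop(sprintf("frame too small for %d shells at %d px separation",
                 spec$n_shells, spec$min_separation_px))
  slots <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  pick <- slots[sample.int(nrow(slots), spec$n_shells), ]
  row_px <- margin + (pick$i - 0.5) * pitch + runif(spec$n_shells, -jitter_px, jitter_px)
  col_px <- margin + (pick$j - 0.5) * pitch + runif(spec$n_shells, -jitter_px, jitter_px)
  cbind(x = col_px * pw, y = row_px * pw)
}

shell_cloud <- function(spec, x0, y0) {
  a <- spec$radius
  if (spec$model == "sphere" && spec$aspect == 1) {
    u <- sample_unit_sphere(spec$n_fluorophores)
    new_point_cloud(cbind(a * u[, 1] + x0, a * u[, 2] + y0, a * u[, 3]))
  } else {
    sh <- ellipsoid_shell(x0 = x0, y0 = y0, a = a, b = a * spec$aspect,
                          phi = runif(1, 0, pi), q = spec$polarity)
    switch(spec$model,
           sphere = ,
           stretched = stretched_sphere_points(sh, spec$n_fluorophores),
           uniform = uniform_ellipsoid_points(sh, spec$n_fluorophores),
           polarized = polarized_ellipsoid_points(sh, spec$n_fluorophores))
  }
}

#' Simulate one calibration frame with ground truth
#'
#' Places `n_shells` shells on a jittered grid (at least
#' `min_separation_px` pixels apart, margins clear of the frame edge),
#' decorates each with fluorophores, renders every fluorophore with the
#' defocus-dependent PSF, applies Poisson shot noise, Gaussian read noise and
#' quantisation, and returns the frame together with a ground-truth manifest
#' (one row per shell).
#'
#' @param spec a [simulation_spec()].
#' @return a list with elements `frame` (an [as_frame()] object) and `truth`
#'   (a data frame: shell, x0, y0, a, b, phi, q, n_fluorophores, seed).
#' @export
simulate_calibration_frame <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    centers <- place_shells(spec)
    s0 <- defocus_psf_sigma(0, spec$wavelength, spec$na, spec$n_imm)
    img <- matrix(0, spec$n_rows, spec$n_cols)
    truth <- vector("list", spec$n_shells)
    for (k in seq_len(spec$n_shells)) {
      cloud <- shell_cloud(spec, centers[k, "x"], centers[k, "y"])
      sh <- attr(cloud, "shell")
      z <- cloud[, 3]
      amp <- spec$photons_per_fluorophore * exp(-z^2 / (2 * s0^2))
      sig <- defocus_psf_sigma(z, spec$wavelength, spec$na, spec$n_imm)
      img <- img + render_gauss_points(cloud[, 1], cloud[, 2], amp, sig,
                                       spec$n_rows, spec$n_cols,
                                       spec$pixel_width, window = 6)
      truth[[k]] <- data.frame(
        shell = k, x0 = centers[k, "x"], y0 = centers[k, "y"],
        a = spec$radius, b = spec$radius * spec$aspect,
        phi = if (is.null(sh)) NA_real_ else sh$phi,
        q = spec$polarity, n_fluorophores = spec$n_fluorophores,
        seed = spec$seed)
    }
    if (spec$noise) {
      cap <- 2^spec$bit_depth - 1
      img[] <- rpois(length(img), pmax(img, 0)) +
        rnorm(length(img), 0, spec$read_noise)
      img[] <- pmin(pmax(round(img), 0), cap)
    }
    list(frame = as_frame(img, spec$pixel_width,
                          id = sprintf("sim-seed%d", spec$seed),
                          source = "calibration_sim"),
         truth = do.call(rbind, truth))
  })
}

#' Write a small set of simulated test fixtures
#'
#' Emits one simulated frame (TIFF) plus its ground-truth manifest (CSV) for
#' each fluorophore placement model: a sphere, a stretched sphere, a uniform
#' ellipsoid and polarized ellipsoids at two polarities. Frames are small
#' (a handful of shells) and fully determined by `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, a data frame of fixture file paths and kinds.
#' @export
generate_test_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- list(
    sphere    = list(model = "sphere",    aspect = 1,   polarity = 0),
    stretched = list(model = "stretched", aspect = 1.7, polarity = 0),
    uniform   = list(model = "uniform",   aspect = 1.7, polarity = 0),
    polarized_q0.8  = list(model = "polarized", aspect = 1.7, polarity = 0.8),
    polarized_qm0.5 = list(model = "polarized", aspect = 1.7, polarity = -0.5))
  out <- vector("list", length(kinds))
  for (k in seq_along(kinds)) {
    kk <- kinds[[k]]
    spec <- simulation_spec(model = kk$model, aspect = kk$aspect,
                            polarity = kk$polarity, n_fluorophores = 2500,
                            n_rows = 120, n_cols = 120, n_shells = 4,
                            seed = seed + k)
    sim <- simulate_calibration_frame(spec)
    tif <- file.path(dir, paste0(names(kinds)[k], ".tif"))
    csv <- file.path(dir, paste0(names(kinds)[k], "_truth.csv"))
    write_frame(sim$frame, tif)
    write.csv(sim$truth, csv, row.names = FALSE)
    out[[k]] <- data.frame(kind = names(kinds)[k], frame = tif, truth = csv)
  }
  invisible(do.call(rbind, out))
}
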