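#' Normalized residual of a fit
#'
#' Ratio of the sum of squared residuals to the sum of squared data values:
#' \deqn{\varepsilon = \frac{\sum_j (I^{data}_j - I^{fit}_j)^2}
#'                          {\sum_j (I^{data}_j)^2}.}
#' Computed on the background-subtracted pixel values that were fitted.
#'
#' @param data observed pixel values (any shape).
#' @param fit fitted model values, same shape.
#' @return the dimensionless residual error.
#' @export
residual_error <- function(data, fit) {
  if (length(data) != length(fit)) stop("`data` and `fit` must have the same shape")
  ss <- sum(data^2)
  if (ss == 0) stop("residual error undefined for all-zero data")
  sum((data - fit)^2) / ss
}

#' Sigma-based quality control
#'
#' A fitted candidate is accepted when the fitting process yielded a
#' plausible PSF radius: any positive value up to twice the calibrated
#' instrument PSF radius. Overlapping spores, fragments and empty regions
#' inflate or destabilise the fitted sigma and are rejected by this single
#' rule. The decision changes exactly at `sigma_fit = 2 * sigma_known`
#' (accepted at the boundary).
#'
#' @param result a `fit_result`.
#' @param psf a [psf_model()] carrying `sigma_known`.
#' @return the `fit_result` with `accepted` and `reject_reason` set.
#' @export
quality_control <- function(result, psf) {
  stopifnot(inherits(result, "fit_result"), inherits(psf, "psf_model"))
  if (!is.null(result$reject_reason) && !is.na(result$reject_reason)) {
    result$accepted <- FALSE
    return(result)
  }
  s <- result$sigma_fit
  if (!is.finite(s) || s <= 0 || s > 2 * psf$sigma_known) {
    result$accepted <- FALSE
    result$reject_reason <- "sigma_out_of_range"
  } else {
    result$accepted <- TRUE
    result$reject_reason <- NA_character_
  }
  result
}

#' Equal-volume sphere radius of a prolate ellipsoid
#'
#' The radius of the sphere with the same volume as an ellipsoid with
#' semiminor axis `a` (twice) and semimajor axis `b`: \eqn{(a^2 b)^{1/3}}.
#' Lies between `a` and `b`.
#'
#' @param a semiminor axis (nm), positive; vectorised.
#' @param b semimajor axis (nm), `>= a`.
#' @return equal-volume radius (nm).
#' @export
equal_volume_radius <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b < a))
    stop("axes must satisfy 0 < a <= b")
  (a^2 * b)^(1 / 3)
}

#' Surface-tension anisotropy of a thin-walled ellipsoidal pressure vessel
#'
#' For a pressurised prolate shell of aspect ratio `b/a`, the ratio of the
#' circumferential surface tension around the equator to the axial tension at
#' the equator is
#' \deqn{\frac{\gamma_y}{\gamma_x} = \frac{4 (b/a)^2}{3 (b/a)^2 + 1}.}
#' The ratio is 1 for a sphere and approaches 4/3 for very elongated shells,
#' so an intact elongated spore coat must be anisotropically reinforced: the
#' larger equatorial tension would otherwise crack it along its long axis.
#'
#' @param aspect aspect ratio `b/a`, `>= 1`; vectorised.
#' @return the tension ratio \eqn{\gamma_y/\gamma_x} at the equator.
#' @examples
#' anisotropy_ratio(sqrt(3))  # 1.2
#' @export
anisotropy_ratio <- function(aspect) {
  if (any(!is.finite(aspect)) || any(aspect < 1))
    stop("`aspect` must be >= 1")
  4 * aspect^2 / (3 * aspect^2 + 1)
}

new_fit_result <- function(model_kind, region, pars, epsilon,
                           reject_reason = NA_character_) {
  structure(c(list(model_kind = model_kind,
                   frame_id = region$frame_id,
                   candidate = region$index,
                   epsilon = epsilon,
                   accepted = NA,
                   reject_reason = reject_reason),
              pars),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: a = %.1f nm", x$model_kind, x$a))
  if (!is.na(x$b)) cat(sprintf(", b = %.1f nm (b/a = %.2f)", x$b, x$b / x$a))
  if (!is.na(x$q)) cat(sprintf(", q = %.2f", x$q))
  cat(sprintf(", sigma = %.1f nm, epsilon = %.3f, %s\n", x$sigma_fit, x$epsilon,
              if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

## local pixel-centre coordinates of a crop, plus the offset to frame-absolute nm
crop_geometry <- function(region) {
  pw <- region$pixel_width
  n <- nrow(region$crop)
  list(x = (seq_len(n) - 0.5) * pw, y = (seq_len(n) - 0.5) * pw, pw = pw,
       x_off = (region$center_pixel[2] - REGION_HALF - 1) * pw,
       y_off = (region$center_pixel[1] - REGION_HALF - 1) * pw)
}

#' Fit the algebraic spherical-shell model to a fitting region
#'
#' Least-squares fit of the five parameters of the closed-form shell image
#' (centre `x0, y0`, radius `a`, brightness per unit area `I0`, PSF radius
#' `sigma`) to a background-corrected 27 x 27 region. `I0` enters the model
#' linearly and is profiled out analytically; the remaining four parameters
#' are optimised by bounded quasi-Newton descent, initialised from the Hough
#' detection (centre and radius) and the calibrated PSF radius. Pixel values
#' are modelled as the mean of the profile over the pixel footprint (3 x 3
#' sub-pixel samples). The result passes through [quality_control()].
#'
#' @param region a `candidate_region` from [extract_region()].
#' @param psf a [psf_model()]; `sigma_known` sets the QC bound and the sigma
#'   search range.
#' @param n_sub sub-pixel samples per axis used by the renderer.
#' @return a `fit_result` with fields `x0`, `y0` (frame-absolute nm), `a`,
#'   `brightness` (`I0`), `sigma_fit`, `epsilon`, `accepted`.
#' @export
fit_sphere_algebraic <- function(region, psf, n_sub = 3) {
  stopifnot(inherits(region, "candidate_region"), inherits(psf, "psf_model"))
  crop <- region$crop
  geo <- crop_geometry(region)
  d <- as.vector(crop)
  empty_pars <- list(x0 = NA_real_, y0 = NA_real_, a = NA_real_, b = NA_real_,
                     phi = NA_real_, q = NA_real_, brightness = NA_real_,
                     sigma_fit = NA_real_)
  if (sum(d^2) == 0) {
    res <- new_fit_result("sphere_algebraic", region, empty_pars, NA_real_,
                          reject_reason = "empty_region")
    return(quality_control(res, psf))
  }
  offs <- sub_pixel_offsets(geo$pw, n_sub)
  basis <- function(p) {
    g <- 0
    for (dx in offs) {
      dx2 <- (geo$x + dx - p[1])^2
      for (dy in offs)
        g <- g + f_shell(sqrt(outer((geo$y + dy - p[2])^2, dx2, "+")), p[3], 1, p[4])
    }
    as.vector(g) / length(offs)^2
  }
  obj <- function(p) {
    g <- basis(p)
    I0 <- max(0, sum(g * d) / sum(g * g))
    sum((d - I0 * g)^2)
  }
  cen <- (REGION_HALF + 0.5) * geo$pw
  a0 <- if (!is.null(region$radius_px) && is.finite(region$radius_px))
    region$radius_px * geo$pw else 8 * geo$pw
  p0 <- c(cen, cen, a0, psf$sigma_known)
  lim <- 5 * geo$pw
  fit <- tryCatch(
    nlminb(p0, obj,
           lower = c(cen - lim, cen - lim, 100, 15),
           upper = c(cen + lim, cen + lim, 1300, 4 * psf$sigma_known)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$objective)) {
    res <- new_fit_result("sphere_algebraic", region, empty_pars, NA_real_,
                          reject_reason = "nonconvergence")
    return(quality_control(res, psf))
  }
  p <- fit$par
  g <- basis(p)
  I0 <- max(0, sum(g * d) / sum(g * g))
  eps <- residual_error(d, I0 * g)
  res <- new_fit_result("sphere_algebraic", region,
                        list(x0 = p[1] + geo$x_off, y0 = p[2] + geo$y_off,
                             a = p[3], b = NA_real_, phi = NA_real_,
                             q = NA_real_, brightness = I0,
                             sigma_fit = p[4]),
                        eps)
  quality_control(res, psf)
}

## principal axes of the intensity distribution: orientation and a rough
## aspect-ratio estimate used to warm-start the ellipsoid search
moment_axes <- function(crop, geo) {
  w <- pmax(as.vector(crop), 0)
  if (sum(w) == 0) return(list(phi = 0, ratio = 1))
  X <- outer(rep(1, length(geo$y)), geo$x)
  Y <- outer(geo$y, rep(1, length(geo$x)))
  mx <- sum(w * X) / sum(w); my <- sum(w * Y) / sum(w)
  cxx <- sum(w * (X - mx)^2) / sum(w)
  cyy <- sum(w * (Y - my)^2) / sum(w)
  cxy <- sum(w * (X - mx) * (Y - my)) / sum(w)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
  list(phi = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi,
       ratio = sqrt(max(ev$values[1], 1e-12) / max(ev$values[2], 1e-12)))
}

#' Fit a Monte Carlo shell model by iterative random search
#'
#' Fits one of the point-cloud image models to a background-corrected region
#' by least squares. The objective renders the candidate parameter vector
#' with a fixed fluorophore sample (common random numbers: the same `seed`
#' is reused at every evaluation, so the objective is deterministic and the
#' search can converge). The search starts from the algebraic sphere fit
#' (centre, radius, sigma), with the orientation warm-started from the image
#' second moments, and performs `n_iter` hill-descent iterations: every
#' parameter is perturbed by a Gaussian step whose size decays geometrically,
#' and a move is accepted only if it lowers the sum of squares. Brightness is
#' profiled out analytically. Axes are canonicalised to `b >= a` (swapping
#' and rotating `phi` by pi/2 when needed); when the fitted aspect ratio is
#' below 1.05 the orientation is reported but flagged unreliable
#' (`phi_reliable = FALSE`).
#'
#' @param region a `candidate_region`.
#' @param psf a [psf_model()].
#' @param model_kind one of `"sphere_mc"`, `"ellipsoid_stretched"`,
#'   `"ellipsoid_uniform"`, `"ellipsoid_polarized"`.
#' @param seed integer seed for the fluorophore sample and the search.
#' @param n_fluorophores fluorophores in the fixed sample (default 2500).
#' @param n_iter random-search iterations (default 600).
#' @param step_decay per-iteration multiplier of the step sizes.
#' @param init optional `fit_result` (e.g. a simpler model's optimum) used as
#'   the starting point instead of the internal sphere fit.
#' @return a `fit_result` with fields `x0`, `y0`, `a`, `b`, `phi`, `q`,
#'   `brightness` (total, `n * I`), `sigma_fit`, `epsilon`, `accepted`,
#'   `phi_reliable`.
#' @export
fit_ellipsoid_mc <- function(region, psf, model_kind = "ellipsoid_uniform",
                             seed = 1L, n_fluorophores = 2500, n_iter = 600,
                             step_decay = 0.9925, init = NULL) {
  stopifnot(inherits(region, "candidate_region"), inherits(psf, "psf_model"))
  model_kind <- match.arg(model_kind, c("sphere_mc", "ellipsoid_stretched",
                                        "ellipsoid_uniform", "ellipsoid_polarized"))
  crop <- region$crop
  geo <- crop_geometry(region)
  d <- as.vector(crop)
  if (sum(d^2) == 0) {
    res <- new_fit_result(model_kind, region,
                          list(x0 = NA_real_, y0 = NA_real_, a = NA_real_,
                               b = NA_real_, phi = NA_real_, q = NA_real_,
                               brightness = NA_real_, sigma_fit = NA_real_),
                          NA_real_, reject_reason = "empty_region")
    return(quality_control(res, psf))
  }
  n27 <- nrow(crop)
  grid <- pixel_grid(n27, n27, geo$pw)
  cloud_seed <- as.integer(seed)
  has_q <- model_kind == "ellipsoid_polarized"
  is_sphere <- model_kind == "sphere_mc"

  cloud_for <- function(p) {
    ## p = (x0, y0, a, b, phi, sigma, q)
    sh <- ellipsoid_shell(x0 = p[1], y0 = p[2], a = p[3],
                          b = if (is_sphere) p[3] else p[4],
                          phi = p[5], q = if (has_q) p[7] else 0)
    switch(model_kind,
           sphere_mc = ,
           ellipsoid_stretched = stretched_sphere_points(sh, n_fluorophores, cloud_seed),
           ellipsoid_uniform = uniform_ellipsoid_points(sh, n_fluorophores, cloud_seed),
           ellipsoid_polarized = polarized_ellipsoid_points(sh, n_fluorophores, cloud_seed))
  }
  sse <- function(p) {
    g <- as.vector(render_point_cloud_image(cloud_for(p), 1 / n_fluorophores,
                                            psf, grid))
    B <- max(0, sum(g * d) / sum(g * g))
    list(sse = sum((d - B * g)^2), B = B)
  }

  if (is.null(init)) init <- fit_sphere_algebraic(region, psf)
  cen <- (REGION_HALF + 0.5) * geo$pw
  a0 <- if (is.finite(init$a)) init$a else 8 * geo$pw
  s0 <- if (is.finite(init$sigma_fit)) init$sigma_fit else psf$sigma_known
  x0 <- if (is.finite(init$x0)) init$x0 - geo$x_off else cen
  y0 <- if (is.finite(init$y0)) init$y0 - geo$y_off else cen
  mom <- moment_axes(crop, geo)
  b0 <- if (!is.null(init$b) && is.finite(init$b)) init$b
        else min(a0 * max(mom$ratio, 1), 1300)
  phi0 <- if (!is.null(init$phi) && is.finite(init$phi)) init$phi else mom$phi
  q0 <- if (!is.null(init$q) && is.finite(init$q)) init$q else 0
  p <- c(x0, y0, a0, max(a0, b0), phi0, s0, q0)

  lim <- 5 * geo$pw
  clamp <- function(p) {
    p[1] <- min(max(p[1], cen - lim), cen + lim)
    p[2] <- min(max(p[2], cen - lim), cen + lim)
    p[3] <- min(max(p[3], 100), 1300)
    p[4] <- min(max(p[4], 100), 1300)
    if (p[4] < p[3]) { p[3:4] <- p[4:3]; p[5] <- p[5] + pi / 2 }
    p[5] <- p[5] %% pi
    p[6] <- min(max(p[6], 15), 4 * psf$sigma_known)
    p[7] <- min(max(p[7], -1), 1)
    p
  }
  p <- clamp(p)
  cur <- sse(p)
  steps0 <- c(5, 5, 20, 20, 0.1, 5, 0.1)  # nm, nm, nm, nm, rad, nm, q
  active <- c(TRUE, TRUE, TRUE, !is_sphere, !is_sphere, TRUE, has_q)
  with_seed(as.integer(seed) + 1L, {
    for (it in seq_len(n_iter)) {
      stp <- steps0 * step_decay^it
      prop <- p
      prop[active] <- prop[active] + rnorm(sum(active)) * stp[active]
      prop <- clamp(prop)
      cand <- sse(prop)
      if (cand$sse < cur$sse) { p <- prop; cur <- cand }
    }
  })
  g <- as.vector(render_point_cloud_image(cloud_for(p), 1 / n_fluorophores, psf, grid))
  eps <- residual_error(d, cur$B * g)
  pars <- list(x0 = p[1] + geo$x_off, y0 = p[2] + geo$y_off,
               a = p[3], b = if (is_sphere) NA_real_ else p[4],
               phi = if (is_sphere) NA_real_ else p[5],
               q = if (has_q) p[7] else NA_real_,
               brightness = cur$B, sigma_fit = p[6])
  res <- new_fit_result(model_kind, region, pars, eps)
  res$phi_reliable <- !is_sphere && p[4] / p[3] >= 1.05
  quality_control(res, psf)
}

#' Tabulate fit results
#'
#' Binds a list of `fit_result` objects into a data frame with a stable
#' column order: frame, candidate, model, x0, y0, a, b, phi, q, brightness,
#' sigma_fit, epsilon, accepted, reject_reason.
#'
#' @param results a list of `fit_result` objects.
#' @return a data frame, one row per candidate.
#' @export
results_table <- function(results) {
  cols <- c("frame_id", "candidate", "model_kind", "x0", "y0", "a", "b",
            "phi", "q", "brightness", "sigma_fit", "epsilon", "accepted",
            "reject_reason")
  rows <- lapply(results, function(r) {
    v <- r[cols]
    names(v) <- cols
    as.data.frame(v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  names(out) <- c("frame", "candidate", "model", "x0", "y0", "a", "b", "phi",
                  "q", "brightness", "sigma_fit", "epsilon", "accepted",
                  "reject_reason")
  out
}

radius_of <- function(r) {
  if (!is.null(r$b) && is.finite(r$b)) equal_volume_radius(r$a, max(r$a, r$b)) else r$a
}

#' Per-frame summary of accepted fits
#'
#' Unweighted means over the accepted candidates of one frame: the shell
#' radius (for ellipsoid models, the equal-volume radius \eqn{(a^2 b)^{1/3}}),
#' the aspect ratio `b/a`, the polarity `q`, the fitted sigma and the
#' residual.
#'
#' @param results list of `fit_result` objects from one frame.
#' @return an object of class `frame_summary`.
#' @export
summarize_frame <- function(results) {
  acc <- Filter(function(r) isTRUE(r$accepted), results)
  s <- list(frame_id = if (length(results)) results[[1]]$frame_id else NA_character_,
            n_candidates = length(results), n_accepted = length(acc))
  if (length(acc) == 0) {
    s <- c(s, list(mean_radius = NA_real_, mean_aspect = NA_real_,
                   mean_polarity = NA_real_, mean_sigma = NA_real_,
                   mean_epsilon = NA_real_, empty = TRUE))
  } else {
    mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    s <- c(s, list(
      mean_radius = mean(vapply(acc, radius_of, 0)),
      mean_aspect = mean_or_na(vapply(acc, function(r)
        if (!is.null(r$b) && is.finite(r$b)) max(r$a, r$b) / r$a else NA_real_, 0)),
      mean_polarity = mean_or_na(vapply(acc, function(r)
        if (is.null(r$q)) NA_real_ else r$q, 0)),
      mean_sigma = mean(vapply(acc, function(r) r$sigma_fit, 0)),
      mean_epsilon = mean(vapply(acc, function(r) r$epsilon, 0)),
      empty = FALSE))
  }
  structure(s, class = "frame_summary")
}

#' Across-field experiment summary
#'
#' Means and standard deviations of the per-frame summary quantities across
#' independent fields of view. The standard deviation is computed over
#' fields, not over individual spores: repeating the whole-field average on
#' independent fields measures the random error of the method.
#'
#' @param frames list of `frame_summary` objects (three or more fields are
#'   recommended; fewer give an unstable standard deviation).
#' @return an object of class `experiment_summary`.
#' @export
summarize_experiment <- function(frames) {
  stopifnot(length(frames) >= 1)
  if (length(frames) < 3)
    warning("fewer than 3 fields; across-field standard deviations are unstable")
  grab <- function(f) vapply(frames, function(s) s[[f]], 0)
  nonempty <- !vapply(frames, function(s) isTRUE(s$empty), TRUE)
  stat <- function(f) {
    v <- grab(f)[nonempty]
    v <- v[is.finite(v)]
    if (!length(v)) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)
  }
  structure(list(n_fields = length(frames),
                 n_accepted = sum(grab("n_accepted")),
                 radius = stat("mean_radius"),
                 aspect = stat("mean_aspect"),
                 polarity = stat("mean_polarity"),
                 sigma = stat("mean_sigma"),
                 epsilon = stat("mean_epsilon"),
                 fields = frames),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("experiment summary over %d fields (%d accepted spores)\n",
              x$n_fields, x$n_accepted))
  cat(sprintf("  radius : %.1f +/- %.1f nm (across-field sd)\n",
              x$radius["mean"], x$radius["sd"]))
  if (is.finite(x$aspect["mean"]))
    cat(sprintf("  aspect : %.3f +/- %.3f\n", x$aspect["mean"], x$aspect["sd"]))
  if (is.finite(x$polarity["mean"]))
    cat(sprintf("  polarity: %.3f +/- %.3f\n", x$polarity["mean"], x$polarity["sd"]))
  invisible(x)
}
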