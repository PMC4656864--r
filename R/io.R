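#' Read a grayscale TIFF micrograph
#'
#' Reads an 8/12/16-bit grayscale TIFF as integer counts (12-bit data stored
#' in a 16-bit container reads back with values at most 4095). RGB or
#' multi-channel files are refused.
#'
#' @param path TIFF file path.
#' @param pixel_width object-frame pixel width (nm).
#' @param id frame identifier; defaults to the file name.
#' @return an [as_frame()] object.
#' @export
read_frame <- function(path, pixel_width = 74, id = basename(path)) {
  if (!file.exists(path)) stop(sprintf("frame file not found: %s", path))
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read '%s' as TIFF: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) != 2)
    stop(sprintf("'%s' is not single-channel grayscale (dimensions: %s)",
                 path, paste(dim(img), collapse = " x ")))
  as_frame(img, pixel_width = pixel_width, id = id, source = path)
}

#' Write a frame as a 16-bit grayscale TIFF
#'
#' Integer counts are stored losslessly in a 16-bit container; a written
#' frame reads back pixel-identical through [read_frame()].
#'
#' @param frame an [as_frame()] object (integer counts up to 65535).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "elm_frame"))
  img <- frame$image
  if (any(img > 65535)) stop("pixel values exceed the 16-bit container")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Write per-candidate fit results to CSV
#'
#' Column order is stable: frame, candidate, model, x0, y0, a, b, phi, q,
#' brightness, sigma_fit, epsilon, accepted, reject_reason.
#'
#' @param results a list of `fit_result` objects or a [results_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment summary to JSON
#'
#' @param summary an `experiment_summary` (or `frame_summary`).
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(summary_as_list(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

summary_as_list <- function(s) {
  if (inherits(s, "experiment_summary")) {
    list(n_fields = s$n_fields, n_accepted = s$n_accepted,
         radius = as.list(s$radius), aspect = as.list(s$aspect),
         polarity = as.list(s$polarity), sigma = as.list(s$sigma),
         epsilon = as.list(s$epsilon),
         fields = lapply(s$fields, function(f) unclass(f)))
  } else unclass(s)
}

#' Pipeline configuration
#'
#' Flat key-value configuration of the segmentation/fitting pipeline. Every
#' key can be overridden; the defaults are the package's declared defaults
#' (74 nm pixels, 27 x 27 fitting regions, Hough radii 4-12 px with a 0.5
#' relative accumulator threshold, 13 px collision distance, 600
#' random-search iterations with 0.9925 step decay, 2500 fluorophores per
#' Monte Carlo render). Configurations round-trip losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param sigma_known calibrated instrument PSF radius (nm).
#' @param model fitted model: `"sphere_algebraic"`, `"sphere_mc"`,
#'   `"ellipsoid_stretched"`, `"ellipsoid_uniform"` or
#'   `"ellipsoid_polarized"`.
#' @param pixel_width object-frame pixel width (nm).
#' @param hough_radii_px Hough radius search range (pixels).
#' @param hough_threshold relative accumulator threshold.
#' @param smooth_sigma edge-map presmoothing (pixels).
#' @param nms_radius detection peak separation (pixels).
#' @param collision_px anticollision distance (pixels).
#' @param n_fluorophores fluorophores per Monte Carlo objective render.
#' @param n_iter random-search iterations.
#' @param step_decay random-search step decay per iteration.
#' @param seed integer seed for all pipeline randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sigma_known = 81, model = "sphere_algebraic",
                            pixel_width = 74, hough_radii_px = 4:12,
                            hough_threshold = 0.5, smooth_sigma = 1,
                            nms_radius = 4, collision_px = 13,
                            n_fluorophores = 2500, n_iter = 600,
                            step_decay = 0.9925, seed = 1L) {
  model <- match.arg(model, c("sphere_algebraic", "sphere_mc",
                              "ellipsoid_stretched", "ellipsoid_uniform",
                              "ellipsoid_polarized"))
  stop_if_not_positive(sigma_known, "sigma_known")
  structure(list(sigma_known = sigma_known, model = model,
                 pixel_width = pixel_width,
                 hough_radii_px = as.integer(hough_radii_px),
                 hough_threshold = hough_threshold,
                 smooth_sigma = smooth_sigma, nms_radius = nms_radius,
                 collision_px = collision_px,
                 n_fluorophores = as.integer(n_fluorophores),
                 n_iter = as.integer(n_iter), step_decay = step_decay,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
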