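#' Micrograph frame
#'
#' Wraps a matrix of pixel intensities with its object-frame pixel width and
#' provenance metadata. Frames must be at least 27 x 27 pixels, the size of
#' one fitting region.
#'
#' @param image numeric matrix of non-negative intensities (rows x columns).
#' @param pixel_width object-frame pixel width (nm).
#' @param id frame identifier used in result tables.
#' @param source origin of the data (file path or simulation tag).
#' @return an object of class `elm_frame`.
#' @export
as_frame <- function(image, pixel_width = 74, id = "frame", source = NA_character_) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 27 || ncol(image) < 27)
    stop("frame must be at least 27 x 27 pixels")
  if (any(image < 0, na.rm = TRUE)) stop("frame intensities must be non-negative")
  stop_if_not_positive(pixel_width, "pixel_width")
  structure(list(image = image, pixel_width = pixel_width,
                 id = as.character(id), source = source),
            class = "elm_frame")
}

#' @export
print.elm_frame <- function(x, ...) {
  cat(sprintf("frame '%s': %d x %d pixels, %.0f nm/pixel\n",
              x$id, nrow(x$image), ncol(x$image), x$pixel_width))
  invisible(x)
}

## half-width of the square fitting region (27 x 27 pixels)
REGION_HALF <- 13L

#' Locate candidate spore images in a frame
#'
#' Runs a circular Hough transform on the gradient-magnitude edge map of the
#' lightly smoothed frame and returns one background-corrected 27 x 27
#' fitting region per accumulator peak. Detection favours recall: elongated
#' spores and some false positives are returned, and downstream
#' quality control is relied upon to reject the latter. Candidates whose
#' fitting region would leave the frame are dropped.
#'
#' @param frame an [as_frame()] object.
#' @param radii_px circle radii searched, in pixels (default 4:12, about
#'   300-900 nm at 74 nm/pixel, spanning typical spore coat radii).
#' @param threshold accumulator peaks above `threshold * max` become
#'   candidates.
#' @param smooth_sigma Gaussian presmoothing radius in pixels.
#' @param nms_radius minimum peak separation in pixels during detection (the
#'   coarser anticollision filter is applied separately).
#' @return a list of `candidate_region` objects, strongest response first.
#' @export
detect_candidates <- function(frame, radii_px = 4:12, threshold = 0.5,
                              smooth_sigma = 1, nms_radius = 4) {
  stopifnot(inherits(frame, "elm_frame"))
  img <- frame$image
  if (diff(range(img)) == 0) {
    warning("frame is flat (blank or saturated); no candidates")
    return(list())
  }
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  gx <- sm; gy <- sm
  gx[] <- 0; gy[] <- 0
  gx[, 2:(ncol(sm) - 1)] <- (sm[, 3:ncol(sm)] - sm[, 1:(ncol(sm) - 2)]) / 2
  gy[2:(nrow(sm) - 1), ] <- (sm[3:nrow(sm), ] - sm[1:(nrow(sm) - 2), ]) / 2
  edge <- sqrt(gx^2 + gy^2)

  acc <- matrix(-Inf, nrow(img), ncol(img))
  racc <- matrix(NA_real_, nrow(img), ncol(img))
  for (r in radii_px) {
    a <- EBImage::filter2(edge, ring_kernel(r), boundary = 0)
    upd <- a > acc
    acc[upd] <- a[upd]
    racc[upd] <- r
  }

  peaks <- local_maxima(acc)
  keep <- peaks[acc[peaks] >= threshold * max(acc)]
  ord <- keep[order(acc[keep], decreasing = TRUE)]
  rows <- (ord - 1) %% nrow(img) + 1
  cols <- (ord - 1) %/% nrow(img) + 1
  ## greedy non-maximum suppression at the detection scale
  sel <- integer(0)
  for (k in seq_along(ord)) {
    if (length(sel) == 0 ||
        all(sqrt((rows[sel] - rows[k])^2 + (cols[sel] - cols[k])^2) > nms_radius))
      sel <- c(sel, k)
  }
  rows <- rows[sel]; cols <- cols[sel]; vals <- acc[ord][sel]; rs <- racc[ord][sel]

  out <- list()
  for (k in seq_along(rows)) {
    reg <- extract_region(frame, c(rows[k], cols[k]), index = length(out) + 1L)
    if (is.null(reg)) next
    reg$response <- vals[k]
    reg$radius_px <- rs[k]
    out[[length(out) + 1L]] <- reg
  }
  out
}

## annulus of radius r (pixels), unit mass, used as Hough voting kernel
ring_kernel <- function(r) {
  h <- ceiling(r) + 1
  d <- sqrt(outer((-h:h)^2, (-h:h)^2, "+"))
  k <- (abs(d - r) <= 0.6) * 1
  k / sum(k)
}

## linear indices of strict local maxima (8-neighbourhood)
local_maxima <- function(a) {
  nr <- nrow(a); nc <- ncol(a)
  best <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src_r <- max(1, 1 + di):min(nr, nr + di)
    dst_r <- max(1, 1 - di):min(nr, nr - di)
    src_c <- max(1, 1 + dj):min(nc, nc + dj)
    dst_c <- max(1, 1 - dj):min(nc, nc - dj)
    best[dst_r, dst_c] <- pmax(best[dst_r, dst_c], a[src_r, src_c])
  }
  which(a > best)
}

#' Suppress double detections of elongated spores
#'
#' Elongated spores sometimes register as two nearby circles in the Hough
#' transform. Candidates are visited in order of decreasing Hough response
#' and any candidate closer than `min_dist_px` pixels to an already-accepted
#' one is dropped, so the stronger response survives. The default distance is
#' half the fitting-region width. The filter is idempotent.
#'
#' @param candidates a list of `candidate_region` objects from one frame.
#' @param min_dist_px collision distance in pixels.
#' @return the filtered list.
#' @export
anticollision_filter <- function(candidates, min_dist_px = 13) {
  if (length(candidates) == 0) return(candidates)
  resp <- vapply(candidates, function(cand)
    if (is.null(cand$response)) 0 else cand$response, 0)
  ord <- order(resp, decreasing = TRUE)
  kept <- list()
  for (k in ord) {
    cand <- candidates[[k]]
    ok <- TRUE
    for (other in kept) {
      d <- sqrt(sum((cand$center_pixel - other$center_pixel)^2))
      if (d < min_dist_px) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- cand
  }
  ## restore original (response-sorted) candidate indices
  kept[order(vapply(kept, function(cand) cand$index, 0L))]
}

#' Extract a background-corrected fitting region
#'
#' Crops the 27 x 27 pixel region centred on `center` and removes the dark
#' background by setting a zero signal level at the median value of all
#' pixels darker than the mean of the region; corrected values are clipped at
#' zero. If no pixel lies below the mean (an exactly constant crop) the
#' minimum of the crop is used — such regions carry no signal and are
#' rejected downstream anyway. Candidates nearer than 13 pixels to a frame
#' edge are rejected (returning `NULL`) rather than zero-padded, since
#' padding would bias the fitted PSF radius.
#'
#' @param frame an [as_frame()] object.
#' @param center integer `(row, col)` of the candidate centre.
#' @param index candidate index within the frame.
#' @return a `candidate_region` (list with `index`, `center_pixel`, `crop`,
#'   `zero_level`, `pixel_width`), or `NULL` if the region leaves the frame.
#' @export
extract_region <- function(frame, center, index = 1L) {
  stopifnot(inherits(frame, "elm_frame"), length(center) == 2)
  img <- frame$image
  r <- as.integer(round(center[1])); c <- as.integer(round(center[2]))
  h <- REGION_HALF
  if (r - h < 1 || r + h > nrow(img) || c - h < 1 || c + h > ncol(img))
    return(NULL)
  crop <- img[(r - h):(r + h), (c - h):(c + h)]
  dark <- crop[crop < mean(crop)]
  zero <- if (length(dark)) median(dark) else min(crop)
  structure(list(index = as.integer(index), center_pixel = c(r, c),
                 crop = pmax(crop - zero, 0), zero_level = zero,
                 pixel_width = frame$pixel_width, frame_id = frame$id),
            class = "candidate_region")
}
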