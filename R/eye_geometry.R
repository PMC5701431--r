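# Phases 2-3: pupil and eye-center localization, iris radius estimation,
# and construction of the inferior-iris region of interest.
#
# Coordinates are 1-based (row, col) with the origin at the top-left; rows
# increase downward, so "above the eye center" means a smaller row index.

#' Locate the darkest window of a frame
#'
#' Scans every `window x window` position, computes its mean brightness via
#' an integral image, and returns the center of the darkest window — a point
#' inside the pupil under the acquisition conditions. Ties are broken toward
#' the smallest row, then the smallest column.
#'
#' @param x frame, RGB array or brightness matrix (see [flood_fill()]).
#' @param window odd window side in pixels (default 21).
#' @return integer `c(row, col)` of the darkest-window center.
#' @export
find_darkest_seed <- function(x, window = 21L) {
  b <- as_brightness(x)
  h <- nrow(b); w <- ncol(b)
  window <- as.integer(window)
  if (h < window || w < window)
    tf_error("frame smaller than the search window", "tf_bad_input")
  # integral image with a zero first row/col
  ii <- t(apply(apply(b, 2, cumsum), 1, cumsum))  # t() undoes apply's flip
  ii <- rbind(0, cbind(0, ii))
  nh <- h - window + 1L; nw <- w - window + 1L
  r0 <- seq_len(nh); c0 <- seq_len(nw)
  sums <- ii[r0 + window, c0 + window, drop = FALSE] -
    ii[r0, c0 + window, drop = FALSE] -
    ii[r0 + window, c0, drop = FALSE] + ii[r0, c0, drop = FALSE]
  hits <- which(sums == min(sums), arr.ind = TRUE)
  best <- hits[order(hits[, 1], hits[, 2])[1], ]
  half <- (window - 1L) %/% 2L
  structure(c(row = unname(best[1]) + half, col = unname(best[2]) + half),
            window_mean = min(sums) / window^2)
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) tf_error("empty mask has no centroid", "tf_bad_input")
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Refine a coarse pupil mask by blurring and re-filling
#'
#' The coarse flood-filled pupil may have a ragged boundary, pinholes from
#' camera noise, and bleed into the iris. The coarse region is hole-filled
#' and painted to maximum brightness, the image is Gaussian-blurred, and the
#' flood fill is re-run from the same seed with a lower threshold, capturing
#' the pupil with a smooth boundary. Falls back to the coarse mask if the
#' refined region is degenerate.
#'
#' @param x frame, RGB array or brightness matrix.
#' @param coarse_mask logical mask from the first flood fill.
#' @param seed the seed used for the coarse fill, `c(row, col)`.
#' @param blur_sigma Gaussian sigma in pixels (default 5).
#' @param refine_threshold flood-fill threshold for the second pass
#'   (default 3 of 256).
#' @return list with `mask` (logical) and `centroid` (`c(row, col)`,
#'   real-valued).
#' @export
refine_pupil <- function(x, coarse_mask, seed, blur_sigma = 5,
                         refine_threshold = 3) {
  b <- as_brightness(x)
  if (!any(coarse_mask)) tf_error("coarse mask is empty", "tf_bad_input")
  # camera noise leaves pinholes in the coarse fill; close them so the
  # painted region is solid white before blurring
  coarse_mask <- EBImage::fillHull(coarse_mask * 1L) > 0
  b[coarse_mask] <- 255
  bb <- blur_matrix(b, blur_sigma)
  mask <- flood_fill(bb, seed, refine_threshold)
  if (sum(mask) <= 1) mask <- coarse_mask
  list(mask = mask, centroid = mask_centroid(mask))
}

#' Choose the eye center with the darkest-window fallback
#'
#' Uses the refined pupil centroid unless it drifted away from the darkest
#' window (e.g. the refinement leaked into the iris), in which case the
#' darkest-window center is used. The comparison is inclusive: a distance
#' exactly at `max_distance` keeps the centroid.
#'
#' @param pupil_centroid,darkest_seed points `c(row, col)`.
#' @param max_distance fallback distance in pixels.
#' @return `c(row, col)` eye center.
#' @export
choose_eye_center <- function(pupil_centroid, darkest_seed, max_distance) {
  if (sqrt(sum((pupil_centroid - darkest_seed)^2)) <= max_distance)
    pupil_centroid
  else c(row = unname(darkest_seed[1]), col = unname(darkest_seed[2]))
}

#' Estimate the iris radius from orientation-filtered edges
#'
#' Flood-fills the iris from a seed placed up and to the left of the eye
#' center at about 0.7 expected radii (mid-iris above the horizontal
#' meridian: clear of the pupil, of the interference band on the inferior
#' iris, and of the eyelids), runs Canny edge detection on
#' the filled region, and keeps boundary pixels whose edge tangent is within
#' `angular_tol` of vertical (gradient within `angular_tol` of horizontal)
#' and whose distance from the eye center lies within `band` times the
#' expected radius. Eyelid boundaries are nearly horizontal and are thereby
#' discarded; the surviving left/right iris arcs give the radius as their
#' mean distance from the center.
#'
#' @param x frame, RGB array or brightness matrix.
#' @param eye_center `c(row, col)`.
#' @param expected_radius approximate iris radius in pixels at the camera's
#'   zoom (default 240, i.e. a 480-pixel iris diameter).
#' @param angular_tol tolerance on the gradient orientation, degrees
#'   (default 15).
#' @param band multiplicative distance band around `expected_radius`
#'   (default `c(0.8, 1.2)`).
#' @param fill_threshold flood-fill brightness tolerance for the iris region
#'   (default 25: larger than the pupil's because the iris is textured).
#' @param sigma Canny smoothing sigma.
#' @return list with `radius` (pixels), `seed`, the iris `mask`, and the
#'   kept boundary `points` (matrix of row, col, dist).
#' @export
estimate_iris_radius <- function(x, eye_center, expected_radius = 240,
                                 angular_tol = 15, band = c(0.8, 1.2),
                                 fill_threshold = 25, sigma = 2) {
  b <- as_brightness(x)
  h <- nrow(b); w <- ncol(b)
  if (expected_radius <= 0)
    tf_error("expected_radius must be positive", "tf_bad_input")
  seed <- c(clamp(round(eye_center[1] - 0.35 * expected_radius), 1, h),
            clamp(round(eye_center[2] - 0.6 * expected_radius), 1, w))
  # reference the local 5x5 mean rather than the seed pixel alone, so iris
  # texture or noise on that one pixel cannot shift the acceptance band
  nb <- b[max(1, seed[1] - 2):min(h, seed[1] + 2),
          max(1, seed[2] - 2):min(w, seed[2] + 2)]
  mask <- flood_fill(b, seed, fill_threshold, ref = mean(nb))
  ce <- canny_edges(mask * 255, sigma = sigma)
  idx <- which(ce$edges, arr.ind = TRUE)
  if (nrow(idx) == 0) tf_error("iris not found: no edges", "tf_iris_not_found")
  gx <- ce$gx[ce$edges]; gy <- ce$gy[ce$edges]
  to_horizontal <- atan2(abs(gy), abs(gx))  # 0 = horizontal gradient
  dist <- sqrt((idx[, 1] - eye_center[1])^2 + (idx[, 2] - eye_center[2])^2)
  keep <- to_horizontal <= angular_tol * pi / 180 &
    dist >= band[1] * expected_radius & dist <= band[2] * expected_radius
  if (!any(keep))
    tf_error("iris not found: no near-vertical boundary in the distance band",
             "tf_iris_not_found")
  pts <- cbind(row = idx[keep, 1], col = idx[keep, 2], dist = dist[keep])
  list(radius = mean(dist[keep]), seed = seed, mask = mask, points = pts)
}

#' Full per-frame eye geometry
#'
#' Runs the darkest-window search, the coarse (threshold 5) and refined
#' (threshold 3) pupil flood fills, the center fallback rule and the iris
#' radius estimation for one frame.
#'
#' @param x frame, RGB array or brightness matrix.
#' @param expected_radius,angular_tol,band,fill_threshold see
#'   [estimate_iris_radius()].
#' @param pupil_threshold coarse pupil flood-fill tolerance (default 5 of
#'   256).
#' @param refine_threshold refined pupil tolerance (default 3).
#' @param blur_sigma refinement blur sigma (default 5).
#' @param window darkest-window side (default 21).
#' @param max_distance centroid-vs-darkest-window fallback distance;
#'   default `0.5 * expected_radius` (large enough that a darkest-window
#'   seed anywhere inside a pupil up to half the iris radius does not
#'   reject a valid centroid).
#' @return list of class `eye_geometry`: `darkest_seed`, `pupil_mask`,
#'   `pupil_centroid`, `eye_center`, `iris_radius`, `iris_points`.
#' @export
eye_geometry <- function(x, expected_radius = 240, pupil_threshold = 5,
                         refine_threshold = 3, blur_sigma = 5, window = 21L,
                         max_distance = 0.5 * expected_radius,
                         angular_tol = 15, band = c(0.8, 1.2),
                         fill_threshold = 25) {
  b <- as_brightness(x)
  seed <- find_darkest_seed(b, window)
  # the darkest window's mean is a noise-robust reference for the fill:
  # the center pixel itself can be a noise outlier
  coarse <- flood_fill(b, seed, pupil_threshold,
                       ref = attr(seed, "window_mean"))
  ref <- refine_pupil(b, coarse, seed, blur_sigma, refine_threshold)
  center <- choose_eye_center(ref$centroid, seed, max_distance)
  iris <- estimate_iris_radius(b, center, expected_radius, angular_tol,
                               band, fill_threshold)
  structure(list(darkest_seed = seed, pupil_mask = ref$mask,
                 pupil_centroid = ref$centroid, eye_center = center,
                 iris_radius = iris$radius, iris_points = iris$points),
            class = "eye_geometry")
}

#' Extract the inferior-iris region of interest
#'
#' The ROI is the set of pixels that (a) lie within 80% of the iris radius
#' of the eye center, (b) lie strictly below the eye-center row, (c) are
#' laterally within 80% of that inner circle's radius of the center column
#' (cropping saturated sclera at the left/right edges), are not pupil
#' pixels, and (d) are at least as bright as the mean brightness of the
#' pixels satisfying (a)-(c) (dropping shadows and dark iris).
#'
#' @param x frame, RGB array or brightness matrix.
#' @param eye_center `c(row, col)`.
#' @param iris_radius iris radius in pixels.
#' @param pupil_mask optional logical mask of pupil pixels to exclude.
#' @return list of class `roi_mask` with `mask`, `pixel_count`,
#'   `mean_brightness` (the pre-removal region mean used in (d)).
#' @export
extract_roi <- function(x, eye_center, iris_radius, pupil_mask = NULL) {
  b <- as_brightness(x)
  h <- nrow(b); w <- ncol(b)
  dr <- matrix(seq_len(h) - eye_center[1], h, w)
  dc <- matrix(seq_len(w) - eye_center[2], h, w, byrow = TRUE)
  r_in <- 0.8 * iris_radius
  region <- (dr^2 + dc^2 <= r_in^2) & (dr > 0) & (abs(dc) <= 0.8 * r_in)
  if (!is.null(pupil_mask)) region <- region & !pupil_mask
  if (!any(region)) tf_error("empty ROI: degenerate geometry", "tf_empty_roi")
  mb <- mean(b[region])
  mask <- region & b >= mb
  if (!any(mask)) tf_error("empty ROI after brightness filtering",
                           "tf_empty_roi")
  structure(list(mask = mask, pixel_count = sum(mask), mean_brightness = mb),
            class = "roi_mask")
}
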