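# Phases 4-5: remove the iris color component from the ROI and correct the
# illumination/camera color bias against the sclera as an in-scene white
# reference. Iris subtraction runs before the illumination gain, matching
# the pipeline's phase order.

#' Estimate the iris color outside the ROI
#'
#' Mean RGB over iris pixels that carry no interference signal: the annulus
#' between 80% and (by default) 95% of the iris radius — the part of the
#' iris outside the ROI circle, trimmed at the outer edge so that small
#' errors in the estimated center or radius do not let the far brighter
#' sclera bleed into the sample — excluding ROI and pupil pixels.
#'
#' @param img `H x W x 3` array or [tf_frame()].
#' @param eye_center `c(row, col)`.
#' @param iris_radius iris radius in pixels.
#' @param roi_mask optional logical ROI mask to exclude.
#' @param pupil_mask optional logical pupil mask to exclude.
#' @param outer_frac outer sampling limit as a fraction of the iris radius
#'   (default 0.95).
#' @return length-3 RGB triple.
#' @export
estimate_iris_color <- function(img, eye_center, iris_radius,
                                roi_mask = NULL, pupil_mask = NULL,
                                outer_frac = 0.95) {
  if (inherits(img, "tf_frame")) img <- img$img
  check_rgb_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  dr <- matrix(seq_len(h) - eye_center[1], h, w)
  dc <- matrix(seq_len(w) - eye_center[2], h, w, byrow = TRUE)
  d2 <- dr^2 + dc^2
  sel <- d2 > (0.8 * iris_radius)^2 & d2 <= (outer_frac * iris_radius)^2
  if (!is.null(roi_mask)) sel <- sel & !roi_mask
  if (!is.null(pupil_mask)) sel <- sel & !pupil_mask
  if (!any(sel))
    tf_error("empty iris sampling region", "tf_empty_sample")
  vapply(1:3, function(ch) mean(img[, , ch][sel]), numeric(1))
}

#' Subtract the iris color from ROI pixels
#'
#' Per-channel subtraction, clamped at zero.
#'
#' @param pixels `N x 3` matrix of RGB triples (8-bit scale).
#' @param iris_color length-3 RGB triple.
#' @return `N x 3` matrix with channels in `[0, 255]`.
#' @export
subtract_iris <- function(pixels, iris_color) {
  pixels <- rbind(pixels)  # promote a single triple to a 1 x 3 matrix
  clamp(sweep(pixels, 2, iris_color, `-`))
}

#' Sample the sclera as a white reference
#'
#' Selects the brightest fraction of non-saturated pixels outside the iris
#' circle. Selection runs on a lightly smoothed brightness field so that
#' single-pixel camera noise does not bias the picked set upward; the
#' returned color is the mean of the original (unsmoothed) pixels.
#'
#' @inheritParams estimate_iris_color
#' @param frac brightest fraction to keep (default 0.01).
#' @param smooth_sigma selection-smoothing sigma in pixels (default 2).
#' @return list with `color` (RGB triple) and `mask` (logical).
#' @export
sample_sclera <- function(img, eye_center, iris_radius, frac = 0.01,
                          smooth_sigma = 2) {
  if (inherits(img, "tf_frame")) img <- img$img
  check_rgb_array(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  dr <- matrix(seq_len(h) - eye_center[1], h, w)
  dc <- matrix(seq_len(w) - eye_center[2], h, w, byrow = TRUE)
  outside <- dr^2 + dc^2 > iris_radius^2
  saturated <- img[, , 1] >= 255 | img[, , 2] >= 255 | img[, , 3] >= 255
  cand <- outside & !saturated
  if (!any(cand)) tf_error("no sclera candidates", "tf_empty_sample")
  bs <- blur_matrix(pixel_brightness(img), smooth_sigma)
  thr <- quantile(bs[cand], 1 - frac)
  sel <- cand & bs >= thr
  list(color = vapply(1:3, function(ch) mean(img[, , ch][sel]), numeric(1)),
       mask = sel)
}

#' Per-channel illumination gains from a sclera sample
#'
#' Von-Kries-style white balancing: `gain_c = reference_white_c /
#' sclera_sample_c`, so that multiplying the sclera sample by the gains
#' returns the reference white exactly.
#'
#' @param sclera_sample RGB triple of the sampled sclera (all channels
#'   `> 0`).
#' @param reference_white target white, default `c(255, 255, 255)`.
#' @return length-3 gain vector.
#' @export
estimate_illumination_gains <- function(sclera_sample,
                                        reference_white = c(255, 255, 255)) {
  if (any(sclera_sample <= 0))
    tf_error("sclera sample has a non-positive channel", "tf_bad_input")
  reference_white / sclera_sample
}

#' Apply illumination gains to pixels
#'
#' Per-channel multiplication, clamped to `[0, 255]`.
#'
#' @param pixels `N x 3` matrix of RGB triples.
#' @param channel_gains length-3 positive gain vector.
#' @return corrected `N x 3` matrix.
#' @export
apply_gains <- function(pixels, channel_gains) {
  if (any(channel_gains <= 0))
    tf_error("gains must be positive", "tf_bad_input")
  pixels <- rbind(pixels)
  clamp(sweep(pixels, 2, channel_gains, `*`))
}

#' Correct ROI pixels for iris color and illumination
#'
#' Applies the two corrections in pipeline order: iris subtraction first,
#' illumination gains second.
#'
#' @param img `H x W x 3` array or [tf_frame()].
#' @param roi_mask logical ROI mask.
#' @param iris_color RGB triple from [estimate_iris_color()].
#' @param channel_gains gains from [estimate_illumination_gains()].
#' @return `N x 3` matrix of corrected pixels, rows in the column-major
#'   scan order of `which(roi_mask)`.
#' @export
correct_roi <- function(img, roi_mask, iris_color, channel_gains) {
  if (inherits(img, "tf_frame")) img <- img$img
  check_rgb_array(img)
  px <- cbind(img[, , 1][roi_mask], img[, , 2][roi_mask],
              img[, , 3][roi_mask])
  apply_gains(subtract_iris(px, iris_color), channel_gains)
}
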