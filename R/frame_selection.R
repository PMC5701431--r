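# Phase 1: discard blink frames by global-brightness thresholding.
#
# When the lids close, the LED reflects off the eyelid and the whole image
# brightens, so blink frames separate from open-eye frames in mean frame
# brightness. B_opened is the mode of the per-frame brightness series (the
# typical open-eye level), B_closed its maximum; frames brighter than
# B_opened + c (B_closed - B_opened) are dropped.

#' Mean brightness of one frame
#'
#' @param frame a [tf_frame()] or a raw `H x W x 3` array.
#' @param method brightness definition, see [pixel_brightness()].
#' @return scalar mean of per-pixel brightness over the whole frame.
#' @export
frame_brightness <- function(frame, method = "mean") {
  img <- if (inherits(frame, "tf_frame")) frame$img else frame
  check_rgb_array(img)
  mean(pixel_brightness(img, method))
}

#' Per-frame brightness profile of a sequence
#'
#' Computes the brightness series, its mode (`B_opened`), its maximum
#' (`B_closed`) and the blink threshold. The mode of the near-continuous
#' series is estimated on 256 integer-centered bins (bin `k` covers
#' `[k - 0.5, k + 0.5)`); ties go to the smallest bin.
#'
#' @param frames list of [tf_frame()] objects.
#' @param blink_coef blink coefficient `c` in `(0, 1)`, default 0.33.
#' @param method brightness definition, see [pixel_brightness()].
#' @return list of class `brightness_profile` with `brightness` (per-frame
#'   vector), `B_opened`, `B_closed`, `threshold`.
#' @export
brightness_profile <- function(frames, blink_coef = 0.33, method = "mean") {
  if (length(frames) == 0) tf_error("empty frame sequence", "tf_bad_input")
  b <- vapply(frames, frame_brightness, numeric(1), method = method)
  counts <- tabulate(clamp(round(b), 0, 255) + 1L, nbins = 256L)
  b_open <- which.max(counts) - 1L  # smallest bin on ties
  b_closed <- max(b)
  structure(list(brightness = b, B_opened = as.numeric(b_open),
                 B_closed = b_closed, blink_coef = blink_coef,
                 threshold = blink_threshold_value(b_open, b_closed,
                                                  blink_coef)),
            class = "brightness_profile")
}

blink_threshold_value <- function(b_open, b_closed, blink_coef) {
  # B_closed within one mode bin (1 brightness unit) of B_opened is jitter,
  # not blink evidence: keep all frames.
  if (b_closed <= b_open + 1) return(Inf)
  b_open + blink_coef * (b_closed - b_open)
}

#' Blink-rejection brightness threshold
#'
#' `threshold = B_opened + c (B_closed - B_opened)`. A series with no
#' brightness spread (`B_closed <= B_opened`) carries no blink evidence and
#' yields `Inf`, i.e. every frame is kept.
#'
#' @param profile a [brightness_profile()].
#' @param blink_coef coefficient `c`; 0 gives `B_opened`, 1 gives
#'   `B_closed`.
#' @return scalar threshold.
#' @export
blink_threshold <- function(profile, blink_coef = 0.33) {
  blink_threshold_value(profile$B_opened, profile$B_closed, blink_coef)
}

#' Select usable frames of a sequence
#'
#' Retains frames whose mean brightness does not exceed the blink threshold,
#' preserving order, indices and timestamps.
#'
#' @inheritParams brightness_profile
#' @return list of class `frame_selection` with `frames` (the retained
#'   frames) and `report`, a data frame with one row per input frame:
#'   `index`, `time`, `brightness`, `kept`, `reason`.
#' @export
select_frames <- function(frames, blink_coef = 0.33, method = "mean") {
  prof <- brightness_profile(frames, blink_coef, method)
  keep <- prof$brightness <= prof$threshold
  if (!any(keep)) tf_error("no usable frames after blink filtering",
                           "tf_no_frames")
  report <- data.frame(
    index = vapply(frames, `[[`, integer(1), "index"),
    time = vapply(frames, `[[`, numeric(1), "time"),
    brightness = prof$brightness,
    kept = keep,
    reason = ifelse(keep, "", "blink"))
  structure(list(frames = frames[keep], report = report, profile = prof),
            class = "frame_selection")
}
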