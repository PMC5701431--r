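# Phase 6 and outputs: nearest-color thickness assignment, per-frame and
# pooled statistics, surface grids and RGB scatter exports.

#' Assign thicknesses by nearest LUT color
#'
#' Each pixel gets the lookup-table thickness whose color minimizes the
#' Euclidean distance in RGB space; exact ties go to the smaller thickness
#' (the thinner film, a conservative and deterministic choice).
#'
#' @param pixel_rgb length-3 triple or `N x 3` matrix.
#' @param lut a `color_lut` from [build_lut()] or [read_lut()].
#' @return numeric vector of thicknesses in nm (length `N`).
#' @export
assign_thickness <- function(pixel_rgb, lut) {
  if (nrow(lut) == 0) tf_error("empty LUT", "tf_bad_input")
  px <- rbind(pixel_rgb)
  cols <- lut_colors(lut)
  d2 <- outer(px[, 1], cols[, 1], `-`)^2 +
    outer(px[, 2], cols[, 2], `-`)^2 +
    outer(px[, 3], cols[, 3], `-`)^2
  # ties.method "first" keeps the lowest index = smallest thickness
  lut$thickness_nm[max.col(-d2, ties.method = "first")]
}

#' Map corrected ROI pixels to a thickness raster
#'
#' Pixels darker than `shadow_floor` after correction are treated as eyelash
#' shadow and excluded before any statistics; remaining pixels receive a
#' nearest-color thickness. Non-ROI and excluded positions carry `NA`.
#'
#' @param corrected_pixels `N x 3` matrix from [correct_roi()].
#' @param roi_mask logical `H x W` mask whose `which()` order matches the
#'   pixel rows.
#' @param lut a `color_lut`.
#' @param shadow_floor brightness floor on the 8-bit scale (default 10).
#' @param frame_index frame number carried through to outputs.
#' @return list of class `llt_map` with `thickness` (`H x W` matrix, NA
#'   sentinel), `mask` (pixels actually assigned), `colors` (their corrected
#'   RGB triples), `values` (their thicknesses) and `frame_index`.
#' @export
map_frame <- function(corrected_pixels, roi_mask, lut, shadow_floor = 10,
                      frame_index = NA_integer_) {
  if (!any(roi_mask)) tf_error("empty ROI", "tf_empty_roi")
  corrected_pixels <- rbind(corrected_pixels)
  if (nrow(corrected_pixels) != sum(roi_mask))
    tf_error("pixel rows do not match the ROI mask", "tf_bad_input")
  bright <- pixel_brightness(corrected_pixels)
  keep <- bright >= shadow_floor
  if (!any(keep))
    tf_error("empty ROI after shadow exclusion", "tf_empty_roi")
  th <- assign_thickness(corrected_pixels[keep, , drop = FALSE], lut)
  raster <- matrix(NA_real_, nrow(roi_mask), ncol(roi_mask))
  pos <- which(roi_mask)[keep]
  raster[pos] <- th
  mask <- matrix(FALSE, nrow(roi_mask), ncol(roi_mask))
  mask[pos] <- TRUE
  structure(list(thickness = raster, mask = mask,
                 colors = corrected_pixels[keep, , drop = FALSE],
                 values = th, frame_index = frame_index),
            class = "llt_map")
}

#' Per-frame thickness statistics
#'
#' Mean and population standard deviation over the assigned pixels, plus a
#' relative-frequency histogram over `[0, 240]` nm.
#'
#' @param llt_map an `llt_map` from [map_frame()].
#' @param bin_width histogram bin width in nm (default 10).
#' @param time frame timestamp in seconds (optional).
#' @param range histogram range, default `c(0, 240)`.
#' @return list of class `frame_stats`: `frame_index`, `time`, `mean_llt`,
#'   `sd_llt` (population SD), `n_pixels`, `breaks`, `rel_freq`.
#' @export
frame_statistics <- function(llt_map, bin_width = 10, time = NA_real_,
                             range = c(0, 240)) {
  v <- llt_map$values
  if (length(v) == 0) tf_error("empty thickness map", "tf_empty_roi")
  breaks <- seq(range[1], range[2], by = bin_width)
  counts <- table(cut(v, breaks = breaks, include.lowest = TRUE,
                      right = FALSE))
  # cut(right = FALSE) puts the range maximum in its own implicit overflow;
  # include.lowest with right = FALSE closes the last bin at the top.
  structure(list(frame_index = llt_map$frame_index, time = time,
                 mean_llt = mean(v),
                 sd_llt = sqrt(mean((v - mean(v))^2)),
                 n_pixels = length(v),
                 breaks = breaks,
                 rel_freq = as.numeric(counts) / length(v)),
            class = "frame_stats")
}

#' Pooled statistics over a frame sequence
#'
#' Pools all assigned pixels of all frames: the video-level mean is the
#' pixel-weighted mean of frame means and the video-level SD the population
#' SD of the pooled pixel set (not the SD of frame means).
#'
#' @param stats_list list of `frame_stats`.
#' @return list of class `sequence_stats`: `mean_llt`, `sd_llt`,
#'   `n_pixels`, `n_frames` and `per_frame` (data frame `frame_index`,
#'   `time_s`, `mean_nm`, `sd_nm`, `n_pixels`).
#' @export
sequence_statistics <- function(stats_list) {
  if (length(stats_list) == 0) tf_error("no frames", "tf_bad_input")
  n <- vapply(stats_list, `[[`, numeric(1), "n_pixels")
  m <- vapply(stats_list, `[[`, numeric(1), "mean_llt")
  s <- vapply(stats_list, `[[`, numeric(1), "sd_llt")
  N <- sum(n)
  pooled_mean <- sum(n * m) / N
  pooled_var <- sum(n * (s^2 + m^2)) / N - pooled_mean^2
  per_frame <- data.frame(
    frame_index = vapply(stats_list, `[[`, numeric(1), "frame_index"),
    time_s = vapply(stats_list, `[[`, numeric(1), "time"),
    mean_nm = m, sd_nm = s, n_pixels = n)
  structure(list(mean_llt = pooled_mean,
                 sd_llt = sqrt(max(pooled_var, 0)),
                 n_pixels = N, n_frames = length(stats_list),
                 per_frame = per_frame),
            class = "sequence_stats")
}

#' Resample a thickness map onto a 50 x 50 grid
#'
#' The ROI's bounding box is resampled to a fixed `grid_size x grid_size`
#' raster by nearest-pixel sampling (every source pixel is hit at least once
#' when the box is smaller than the grid); cells with no assigned pixel
#' carry `NA`.
#'
#' @param llt_map an `llt_map`.
#' @param grid_size grid side (default 50).
#' @return `grid_size x grid_size` matrix of thicknesses (nm) with NA
#'   sentinel.
#' @export
surface_grid <- function(llt_map, grid_size = 50L) {
  idx <- which(llt_map$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) tf_error("empty thickness map", "tf_empty_roi")
  r1 <- min(idx[, 1]); r2 <- max(idx[, 1])
  c1 <- min(idx[, 2]); c2 <- max(idx[, 2])
  nr <- r2 - r1 + 1L; nc <- c2 - c1 + 1L
  src_r <- r1 + floor((seq_len(grid_size) - 0.5) * nr / grid_size)
  src_c <- c1 + floor((seq_len(grid_size) - 0.5) * nc / grid_size)
  llt_map$thickness[src_r, src_c, drop = FALSE]
}

#' Pool RGB/thickness pairs from consecutive frames
#'
#' Pools (corrected color, assigned thickness) pairs from up to three
#' consecutive mapped frames and downsamples deterministically, keeping
#' every `1/downsample`-th pixel in scan order.
#'
#' @param maps list of `llt_map` objects (normally three consecutive
#'   retained frames; fewer are used with a warning).
#' @param downsample kept fraction, default `1/3`.
#' @return data frame with columns `R`, `G`, `B`, `thickness_nm`.
#' @export
rgb_scatter <- function(maps, downsample = 1 / 3) {
  if (length(maps) < 3)
    warning("fewer than three frames available for the RGB scatter")
  cols <- do.call(rbind, lapply(maps, `[[`, "colors"))
  th <- unlist(lapply(maps, `[[`, "values"))
  step <- max(1L, as.integer(round(1 / downsample)))
  sel <- seq(1L, length(th), by = step)
  data.frame(R = cols[sel, 1], G = cols[sel, 2], B = cols[sel, 3],
             thickness_nm = th[sel])
}
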