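# Seeded flood fill over a brightness raster.
#
# Region growing from a seed pixel: a pixel joins the region if it is
# 8-connected (or 4-connected) to it and its brightness differs from the
# *seed pixel's* brightness by strictly less than the threshold. This is the
# primitive used both for the pupil (threshold 5 of 256) and, after blur
# refinement, for the smooth pupil (threshold 3), and again for the iris.

#' Flood fill from a seed pixel
#'
#' @param x brightness matrix (`H x W`, 8-bit scale), an `H x W x 3` RGB
#'   array (its channel-mean brightness is used), or a [tf_frame()].
#' @param seed integer `c(row, col)`, 1-based.
#' @param threshold brightness tolerance (`> 0`): a pixel qualifies when
#'   `|b(pixel) - ref| < threshold`.
#' @param connectivity 8 (default) or 4.
#' @param ref reference brightness; defaults to the seed pixel's own value.
#'   Callers that seed from a region (e.g. the darkest window) can pass the
#'   region's mean, which is robust to single-pixel camera noise on the
#'   seed.
#' @return logical `H x W` mask of the filled region; always contains the
#'   seed.
#' @export
flood_fill <- function(x, seed, threshold, connectivity = 8, ref = NULL) {
  b <- as_brightness(x)
  h <- nrow(b); w <- ncol(b)
  seed <- as.integer(seed)
  if (length(seed) != 2 || seed[1] < 1 || seed[1] > h ||
      seed[2] < 1 || seed[2] > w)
    tf_error("seed out of bounds", "tf_bad_input")
  if (threshold <= 0) tf_error("threshold must be > 0", "tf_bad_input")
  if (!connectivity %in% c(4, 8))
    tf_error("connectivity must be 4 or 8", "tf_bad_input")
  if (is.null(ref)) ref <- b[seed[1], seed[2]]
  qual <- abs(b - ref) < threshold
  mask <- matrix(FALSE, h, w)
  start <- (seed[2] - 1L) * h + seed[1]
  mask[start] <- TRUE
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  n_dir <- if (connectivity == 8) 8L else 4L
  frontier <- start
  while (length(frontier) > 0) {
    r <- (frontier - 1L) %% h + 1L
    cc <- (frontier - 1L) %/% h + 1L
    nxt <- integer(0)
    for (k in seq_len(n_dir)) {
      rr <- r + dr[k]; ccc <- cc + dc[k]
      ok <- rr >= 1L & rr <= h & ccc >= 1L & ccc <= w
      if (!any(ok)) next
      idx <- (ccc[ok] - 1L) * h + rr[ok]
      idx <- idx[qual[idx] & !mask[idx]]
      if (length(idx)) {
        mask[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  mask
}

as_brightness <- function(x) {
  if (inherits(x, "tf_frame")) x <- x$img
  if (is.matrix(x)) return(x)
  check_rgb_array(x, "image")
  pixel_brightness(x)
}
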