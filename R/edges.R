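# Canny edge detection on a brightness raster: Gaussian smoothing, Sobel
# gradients, non-maximum suppression, and hysteresis with median-based
# automatic thresholds.

#' Canny edge detection
#'
#' @param x brightness matrix (`H x W`). Rows increase downward; the
#'   gradient components are `gy` along rows and `gx` along columns.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param low,high hysteresis thresholds on gradient magnitude; when `NULL`
#'   they default to 0.66 and 1.33 times the median nonzero magnitude.
#' @return list with logical `edges`, plus `gx`, `gy`, `magnitude` and the
#'   gradient `orientation` (radians, `atan2(gy, gx)`).
#' @export
canny_edges <- function(x, sigma = 2, low = NULL, high = NULL) {
  if (!is.matrix(x)) tf_error("canny_edges needs a matrix", "tf_bad_input")
  xs <- blur_matrix(x, sigma)
  # Sobel operators
  gx <- (shift_matrix(xs, 0, -1) - shift_matrix(xs, 0, 1)) * 2 +
    (shift_matrix(xs, -1, -1) - shift_matrix(xs, -1, 1)) +
    (shift_matrix(xs, 1, -1) - shift_matrix(xs, 1, 1))
  gy <- (shift_matrix(xs, -1, 0) - shift_matrix(xs, 1, 0)) * 2 +
    (shift_matrix(xs, -1, -1) - shift_matrix(xs, 1, -1)) +
    (shift_matrix(xs, -1, 1) - shift_matrix(xs, 1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)
  # non-maximum suppression along the gradient direction (4 sectors)
  sector <- (round(ori / (pi / 4)) %% 4)
  nb <- function(dr, dc) pmax(shift_matrix(mag, dr, dc),
                              shift_matrix(mag, -dr, -dc))
  keep <- matrix(FALSE, nrow(x), ncol(x))
  keep[sector == 0] <- (mag >= nb(0, 1))[sector == 0]    # horizontal grad
  keep[sector == 1] <- (mag >= nb(1, 1))[sector == 1]    # diagonal
  keep[sector == 2] <- (mag >= nb(1, 0))[sector == 2]    # vertical grad
  keep[sector == 3] <- (mag >= nb(1, -1))[sector == 3]   # anti-diagonal
  nz <- mag[mag > 1e-12]
  if (length(nz) == 0)
    return(list(edges = matrix(FALSE, nrow(x), ncol(x)),
                gx = gx, gy = gy, magnitude = mag, orientation = ori))
  m0 <- median(nz)
  if (is.null(low)) low <- 0.66 * m0
  if (is.null(high)) high <- 1.33 * m0
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  # hysteresis: grow strong edges through weak, 8-connected
  repeat {
    grown <- weak & dilate8(strong)
    new <- grown & !strong
    if (!any(new)) break
    strong <- strong | new
  }
  list(edges = strong, gx = gx, gy = gy, magnitude = mag, orientation = ori)
}

dilate8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_matrix(m, dr, dc)
  }
  out
}
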