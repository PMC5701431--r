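# Small shared helpers: brightness, clamping, transfer curves, conditions.

#' Per-pixel brightness of an RGB raster
#'
#' Brightness of a pixel is defined throughout the package as the plain
#' channel mean `(R + G + B) / 3` on the 8-bit scale; a Rec.601 luma
#' weighting is available as an alternative.
#'
#' @param img numeric array `H x W x 3` with values in `[0, 255]`, or an
#'   `N x 3` matrix of pixel triples.
#' @param method `"mean"` (default) or `"luma"` (0.299 R + 0.587 G + 0.114 B).
#' @return an `H x W` matrix (array input) or length-`N` vector (matrix input).
#' @export
pixel_brightness <- function(img, method = c("mean", "luma")) {
  method <- match.arg(method)
  w <- if (method == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  if (is.matrix(img)) {
    stopifnot(ncol(img) == 3)
    return(drop(img %*% w))
  }
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
}

clamp <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' sRGB transfer curve
#'
#' Standard display transfer (gamma) encoding applied to linear values in
#' `[0, 1]`; used when a lookup table is normalized to the 8-bit scale so
#' that theoretical colors are comparable with gamma-encoded camera output.
#'
#' @param x numeric vector of linear values in `[0, 1]`.
#' @return encoded values in `[0, 1]`.
#' @export
srgb_encode <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

# Edge-replicating integer shift of a matrix: positive dr moves content down.
shift_matrix <- function(m, dr = 0, dc = 0) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) - dr, 1, h)
  ci <- clamp(seq_len(w) - dc, 1, w)
  m[ri, ci, drop = FALSE]
}

# Gaussian blur on a plain matrix, replicate boundary (wraps EBImage).
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma, boundary = "replicate")
}

tf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tearfilm_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate an H x W x 3 8-bit RGB array.
check_rgb_array <- function(img, what = "frame") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    tf_error(sprintf("%s must be an H x W x 3 array", what), "tf_bad_input")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    tf_error(sprintf("%s is empty", what), "tf_bad_input")
  invisible(img)
}
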