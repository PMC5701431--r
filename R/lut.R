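# Thickness-to-color lookup table: the inversion target of the pipeline.

#' Build the thickness-to-RGB lookup table
#'
#' Evaluates the interference model at every thickness of the grid, converts
#' each reflected spectrum to RGB through the observer and illuminant, clamps
#' negative channels at zero, scales the whole curve by one global gain so
#' the maximum channel over the grid is 255, and (by default) applies the
#' standard display transfer curve so the table is comparable with
#' gamma-encoded 8-bit camera output. Colors are kept at double precision on
#' the 8-bit scale; [write_lut()] rounds to integers on export.
#'
#' @param stack an [optical_stack()].
#' @param observer observer table, default [cie1964_observer()].
#' @param illuminant illuminant table, default [blackbody_illuminant()]
#'   at 6500 K.
#' @param thickness_grid thickness grid in nm, strictly increasing, step at
#'   least 0.1 nm; default 0..240 nm in 1-nm steps.
#' @param gamma logical; apply the sRGB transfer curve (default `TRUE`).
#' @param phase_convention passed to [interfere()].
#' @param tol,max_orders truncation controls passed to [interfere()].
#' @return data frame of class `color_lut` with columns `thickness_nm`, `R`,
#'   `G`, `B`; the build configuration is stored in `attr(, "config")`.
#' @export
build_lut <- function(stack = optical_stack(),
                      observer = cie1964_observer(),
                      illuminant = blackbody_illuminant(),
                      thickness_grid = 0:240,
                      gamma = TRUE,
                      phase_convention = c("fresnel", "literal"),
                      tol = 1e-9, max_orders = 50L) {
  phase_convention <- match.arg(phase_convention)
  if (length(thickness_grid) < 1)
    tf_error("thickness grid is empty", "tf_bad_input")
  if (any(diff(thickness_grid) < 0.1))
    tf_error("thickness grid must be strictly increasing with step >= 0.1 nm",
             "tf_bad_input")
  lam <- observer$wavelength
  spectra <- vapply(thickness_grid, function(d)
    interfere(stack, lam, d, phase_convention = phase_convention,
              tol = tol, max_orders = max_orders)$intensity,
    numeric(length(lam)))
  rgb_lin <- spectrum_to_rgb(spectra, observer, illuminant)
  rgb_lin <- pmax(rgb_lin, 0)
  gain <- 255 / max(rgb_lin)
  cols <- rgb_lin * gain
  if (gamma) cols <- 255 * srgb_encode(cols / 255)
  out <- data.frame(thickness_nm = thickness_grid,
                    R = cols[, 1], G = cols[, 2], B = cols[, 3])
  structure(out, class = c("color_lut", "data.frame"),
            config = list(
                n_air = stack$n_air, n_lipid = stack$n_lipid,
                n_tear = stack$n_tear,
                incidence_angle = stack$incidence_angle,
                illuminant = attr(illuminant, "name") %||% "custom",
                gamma = gamma, phase_convention = phase_convention,
                tol = tol, max_orders = max_orders,
                grid_min = min(thickness_grid),
                grid_max = max(thickness_grid),
                grid_n = length(thickness_grid)))
}

lut_colors <- function(lut) {
  unname(as.matrix(lut[, c("R", "G", "B")]))
}

# Colors for arbitrary thicknesses, by nearest grid entry; used by the
# synthetic renderer.
lut_color_at <- function(lut, thickness) {
  idx <- vapply(thickness, function(d)
    which.min(abs(lut$thickness_nm - d)), integer(1))
  lut_colors(lut)[idx, , drop = FALSE]
}

#' Export a lookup table as plain text
#'
#' Writes `thickness_nm,R,G,B` lines with 8-bit integer channels, and
#' optionally a key-value config file recording how the table was built.
#'
#' @param lut a `color_lut` from [build_lut()].
#' @param path output CSV path.
#' @param config_path optional path for a `key = value` text file with the
#'   build configuration.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path, config_path = NULL) {
  out <- data.frame(thickness_nm = lut$thickness_nm,
                    R = as.integer(round(lut$R)),
                    G = as.integer(round(lut$G)),
                    B = as.integer(round(lut$B)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(config_path)) {
    cfg <- attr(lut, "config") %||% list()
    writeLines(sprintf("%s = %s", names(cfg),
                       vapply(cfg, function(x) paste(format(x), collapse = ","),
                              character(1))),
               config_path)
  }
  invisible(path)
}

#' Read a lookup table written by [write_lut()]
#'
#' @param path CSV path with columns `thickness_nm,R,G,B`.
#' @return a `color_lut` data frame.
#' @export
read_lut <- function(path) {
  x <- read.csv(path)
  need <- c("thickness_nm", "R", "G", "B")
  if (!all(need %in% names(x)))
    tf_error("LUT file must have columns thickness_nm,R,G,B", "tf_bad_input")
  if (any(diff(x$thickness_nm) <= 0))
    tf_error("LUT thickness grid must be strictly increasing", "tf_bad_input")
  structure(x[, need], class = c("color_lut", "data.frame"))
}

#' Plot a lookup table as a color bar
#'
#' @param x a `color_lut`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.color_lut <- function(x, ...) {
  cols <- grDevices::rgb(clamp(x$R), clamp(x$G), clamp(x$B),
                         maxColorValue = 255)
  graphics::image(x = x$thickness_nm, y = 1, useRaster = TRUE,
                  z = matrix(seq_along(cols)), col = cols,
                  xlab = "lipid layer thickness (nm)", yaxt = "n", ylab = "",
                  ...)
  invisible(x)
}
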