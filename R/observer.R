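# CIE 1964 10-degree standard observer and broadband illuminants.

#' CIE 1964 10-degree standard observer in RGB primaries
#'
#' Color-matching functions of the CIE 1964 10-degree standard observer,
#' evaluated from the published multi-lobe Gaussian analytic approximations
#' to the x/y/z curves (Wyman, Sloan & Shirley 2013, Journal of Computer
#' Graphics Techniques) and converted to linear sRGB primaries with the
#' standard XYZ-to-sRGB matrix. The RGB matching functions carry the small
#' negative lobes inherent to physical RGB primaries; downstream lookup-table
#' construction clamps colors at zero.
#'
#' @param wavelengths wavelength grid in nm, strictly increasing, within
#'   `[360, 830]` (default 1-nm steps over the full visible grid).
#' @return data frame of class `observer_cmf` with columns `wavelength`,
#'   `r_bar`, `g_bar`, `b_bar`.
#' @export
cie1964_observer <- function(wavelengths = 360:830) {
  check_wavelengths(wavelengths)
  xyz <- cie1964_xyz(wavelengths)
  m <- xyz_to_srgb_matrix()
  rgb <- as.matrix(xyz[, c("x_bar", "y_bar", "z_bar")]) %*% t(m)
  structure(
    data.frame(wavelength = wavelengths,
               r_bar = rgb[, 1], g_bar = rgb[, 2], b_bar = rgb[, 3]),
    class = c("observer_cmf", "data.frame"))
}

#' CIE 1964 10-degree color-matching functions (XYZ)
#'
#' Analytic approximation (sums of log-normal / Gaussian lobes) to the
#' CIE 1964 x, y, z color-matching functions.
#'
#' @inheritParams cie1964_observer
#' @return data frame with columns `wavelength`, `x_bar`, `y_bar`, `z_bar`.
#' @export
cie1964_xyz <- function(wavelengths = 360:830) {
  check_wavelengths(wavelengths)
  l <- wavelengths
  x_bar <- 0.398 * exp(-1250 * log((l + 570.1) / 1014)^2) +
    1.132 * exp(-234 * log((1338 - l) / 743.5)^2)
  y_bar <- 1.011 * exp(-0.5 * ((l - 556.1) / 46.14)^2)
  z_bar <- 2.060 * exp(-32 * log((l - 265.8) / 180.4)^2)
  data.frame(wavelength = l, x_bar = x_bar, y_bar = y_bar, z_bar = z_bar)
}

# Linear sRGB primaries, D65 white.
xyz_to_srgb_matrix <- function() {
  matrix(c(3.2406, -1.5372, -0.4986,
           -0.9689, 1.8758, 0.0415,
           0.0557, -0.2040, 1.0570),
         nrow = 3, byrow = TRUE)
}

check_wavelengths <- function(wavelengths) {
  if (length(wavelengths) < 1 || any(diff(wavelengths) <= 0))
    tf_error("wavelengths must be strictly increasing", "tf_bad_input")
  if (min(wavelengths) < 360 || max(wavelengths) > 830)
    tf_error("wavelengths must lie within [360, 830] nm", "tf_bad_input")
  invisible(wavelengths)
}

#' Blackbody (Planck) illuminant
#'
#' Relative spectral power of a blackbody radiator, normalized to peak 1 on
#' the grid. The default 6500 K approximates the white LED panel used for
#' tear-film illumination.
#'
#' @param temperature color temperature in kelvin.
#' @inheritParams cie1964_observer
#' @return data frame of class `illuminant` with columns `wavelength`,
#'   `power`.
#' @export
blackbody_illuminant <- function(temperature = 6500, wavelengths = 360:830) {
  check_wavelengths(wavelengths)
  if (temperature <= 0) tf_error("temperature must be positive", "tf_bad_input")
  c2 <- 1.4388e7  # second radiation constant, nm K
  p <- wavelengths^-5 / (exp(c2 / (wavelengths * temperature)) - 1)
  structure(data.frame(wavelength = wavelengths, power = p / max(p),
                       row.names = NULL),
            class = c("illuminant", "data.frame"),
            name = sprintf("blackbody_%gK", temperature))
}

#' Equal-energy illuminant
#'
#' @inheritParams cie1964_observer
#' @return data frame of class `illuminant`.
#' @export
equal_energy_illuminant <- function(wavelengths = 360:830) {
  check_wavelengths(wavelengths)
  structure(data.frame(wavelength = wavelengths,
                       power = rep(1, length(wavelengths))),
            class = c("illuminant", "data.frame"), name = "equal_energy")
}
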