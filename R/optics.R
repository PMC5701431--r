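# Thin-film interference model for the tear-film lipid layer.
#
# The lipid layer (refractive index ~1.48) sits on the aqueous layer (~1.337)
# under air. Light reflected at the air-lipid interface interferes with rays
# bouncing m times between the lipid-aqueous and lipid-air interfaces; the
# resulting spectrum, weighted by the illuminant and the CIE 1964 standard
# observer, gives the interference color as a function of lipid thickness.

#' Optical description of the air / lipid / aqueous stack
#'
#' @param n_air,n_lipid,n_tear refractive indices of air, meibum (lipid) and
#'   the aqueous tear layer. Defaults are standard literature values for
#'   meibum (1.48) and tears (1.337); all dimensionless and `>= 1`.
#' @param incidence_angle angle of incidence in air, radians, in `[0, pi/2)`.
#'   Default 0 (normal incidence).
#' @return an object of class `optical_stack`.
#' @export
optical_stack <- function(n_air = 1.000, n_lipid = 1.48, n_tear = 1.337,
                          incidence_angle = 0) {
  if (any(c(n_air, n_lipid, n_tear) < 1))
    tf_error("refractive indices must be >= 1", "tf_bad_input")
  if (incidence_angle < 0 || incidence_angle >= pi / 2)
    tf_error("incidence_angle must lie in [0, pi/2)", "tf_bad_input")
  structure(list(n_air = n_air, n_lipid = n_lipid, n_tear = n_tear,
                 incidence_angle = incidence_angle),
            class = "optical_stack")
}

stack_index <- function(stack, layer) {
  switch(layer,
         air = stack$n_air, lipid = stack$n_lipid, tear = stack$n_tear,
         tf_error("unknown layer (use 'air', 'lipid' or 'tear')",
                  "tf_bad_input"))
}

# Incidence angle at the top of `layer`, propagated from the air-side
# incidence angle through Snell's law.
angle_in_layer <- function(stack, layer) {
  th <- stack$incidence_angle
  if (layer == "air") return(th)
  th <- snell_angle(stack$n_air, stack$n_lipid, th)
  if (layer == "lipid") return(th)
  snell_angle(stack$n_lipid, stack$n_tear, th)
}

snell_angle <- function(n_i, n_j, theta_i) {
  s <- n_i * sin(theta_i) / n_j
  if (s > 1)
    tf_error("total internal reflection: no real refraction angle",
             "tf_total_internal_reflection")
  asin(s)
}

#' Refraction angle between adjacent layers of the stack
#'
#' Applies Snell's law `n_i sin(theta_i) = n_j sin(theta_j)` between two
#' adjacent layers of the air / lipid / tear stack. The incident angle in the
#' `from` layer is the stack's incidence angle propagated down from air
#' unless given explicitly.
#'
#' @param stack an [optical_stack()].
#' @param from,to adjacent layer names among `"air"`, `"lipid"`, `"tear"`.
#' @param angle optional incident angle in the `from` layer (radians).
#' @return the refraction angle in the `to` layer, radians.
#' @export
snell_refraction_angle <- function(stack, from = "air", to = "lipid",
                                   angle = NULL) {
  layers <- c("air", "lipid", "tear")
  i <- match(from, layers); j <- match(to, layers)
  if (is.na(i) || is.na(j) || abs(i - j) != 1L)
    tf_error("layers must be adjacent among air, lipid, tear", "tf_bad_input")
  if (is.null(angle)) angle <- angle_in_layer(stack, from)
  snell_angle(stack_index(stack, from), stack_index(stack, to), angle)
}

#' Optical path difference of successive reflections
#'
#' `OPD = 2 n_lipid d cos(beta)` where `beta` is the refraction angle inside
#' the lipid film and `d` its thickness.
#'
#' @param stack an [optical_stack()].
#' @param d lipid layer thickness in nm (vectorized, `>= 0`).
#' @return OPD in nm.
#' @export
optical_path_difference <- function(stack, d) {
  if (any(d < 0)) tf_error("thickness d must be >= 0", "tf_bad_input")
  beta <- angle_in_layer(stack, "lipid")
  2 * stack$n_lipid * d * cos(beta)
}

#' Phase difference between successive reflected rays
#'
#' @param opd optical path difference in nm.
#' @param lambda wavelength in nm (`> 0`).
#' @return phase difference in radians, `2 pi OPD / lambda`.
#' @export
phase_difference <- function(opd, lambda) {
  if (any(lambda <= 0)) tf_error("wavelength must be positive", "tf_bad_input")
  2 * pi * opd / lambda
}

#' Fresnel amplitude coefficients at an interface
#'
#' Amplitude reflection and transmission coefficients for s- and
#' p-polarization at a planar interface between media `n_i` and `n_j`,
#' with the refraction angle from Snell's law.
#'
#' @param n_i,n_j refractive indices on the incident and transmitted side.
#' @param theta_i incidence angle, radians.
#' @return list with `r_s`, `t_s`, `r_p`, `t_p` and the refraction angle
#'   `theta_j`.
#' @export
fresnel_amplitudes <- function(n_i, n_j, theta_i) {
  theta_j <- snell_angle(n_i, n_j, theta_i)
  ci <- cos(theta_i); cj <- cos(theta_j)
  list(
    r_s = (n_i * ci - n_j * cj) / (n_i * ci + n_j * cj),
    t_s = 2 * n_i * ci / (n_i * ci + n_j * cj),
    r_p = (n_j * ci - n_i * cj) / (n_j * ci + n_i * cj),
    t_p = 2 * n_i * ci / (n_i * cj + n_j * ci),
    theta_j = theta_j
  )
}

#' Reflectance and transmittance at an interface
#'
#' Power coefficients `R = |r|^2` and `T = (n_j cos theta_j)/(n_i cos
#' theta_i) |t|^2` per polarization; a lossless interface satisfies
#' `R + T = 1` for each polarization.
#'
#' @inheritParams fresnel_amplitudes
#' @return list with `R_s`, `T_s`, `R_p`, `T_p`.
#' @export
reflectance_transmittance <- function(n_i, n_j, theta_i) {
  a <- fresnel_amplitudes(n_i, n_j, theta_i)
  geom <- (n_j * cos(a$theta_j)) / (n_i * cos(theta_i))
  list(R_s = a$r_s^2, T_s = geom * a$t_s^2,
       R_p = a$r_p^2, T_p = geom * a$t_p^2)
}

# Interface power/amplitude bookkeeping for the multi-reflection model.
# Layers: 1 air, 2 lipid, 3 tear.
stack_interfaces <- function(stack, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  th1 <- stack$incidence_angle
  th2 <- snell_angle(stack$n_air, stack$n_lipid, th1)
  pick <- function(l, which) l[[paste0(which, "_", polarization)]]
  rt12 <- reflectance_transmittance(stack$n_air, stack$n_lipid, th1)
  rt21 <- reflectance_transmittance(stack$n_lipid, stack$n_air, th2)
  rt23 <- reflectance_transmittance(stack$n_lipid, stack$n_tear, th2)
  a12 <- fresnel_amplitudes(stack$n_air, stack$n_lipid, th1)
  a21 <- fresnel_amplitudes(stack$n_lipid, stack$n_air, th2)
  a23 <- fresnel_amplitudes(stack$n_lipid, stack$n_tear, th2)
  list(
    R12 = pick(rt12, "R"), T12 = pick(rt12, "T"),
    R21 = pick(rt21, "R"), T21 = pick(rt21, "T"),
    R23 = pick(rt23, "R"),
    sign_r12 = sign(pick(a12, "r")),
    sign_r21 = sign(pick(a21, "r")),
    sign_r23 = sign(pick(a23, "r")),
    beta = th2
  )
}

# Intensities of the reflection orders (lambda-independent without
# dispersion): I_0 = R12 I, I_1 = T12 R23 T21 I, I_m = (R21 R23) I_{m-1}.
order_intensities <- function(iface, I_incident, tol, max_orders) {
  ratio <- iface$R21 * iface$R23
  if (ratio >= 1)
    tf_error("non-convergent geometry: R21 * R23 >= 1", "tf_bad_input")
  I0 <- iface$R12 * I_incident
  I1 <- iface$T12 * iface$R23 * iface$T21 * I_incident
  ints <- c(I0, I1)
  m <- 1L
  while (m < max_orders) {
    nxt <- ints[length(ints)] * ratio
    if (nxt / I_incident < tol) break
    ints <- c(ints, nxt)
    m <- m + 1L
  }
  list(intensity = ints, m = seq_along(ints) - 1L, ratio = ratio)
}

#' Intensities and phases of the reflection orders
#'
#' In the simple reflection-transmission model, ray `m` is reflected `m`
#' times between the lipid-tear and lipid-air interfaces before exiting.
#' Its intensity is `I_0 = R12 I_i`, `I_1 = T12 R23 T21 I_i`, and
#' `I_m = R21 R23 I_{m-1}` for `m > 1`; its phase lag is `m` times the
#' phase difference of one round trip. The series is truncated when
#' `I_m / I_i` falls below `tol` or at `max_orders` orders, whichever is
#' reached first.
#'
#' @param stack an [optical_stack()].
#' @param lambda wavelength in nm.
#' @param d lipid thickness in nm.
#' @param I_incident incident intensity (`> 0`).
#' @param polarization `"s"` or `"p"`.
#' @param tol relative intensity at which the series is truncated.
#' @param max_orders hard cap on the number of reflection orders.
#' @return data frame with columns `m`, `intensity`, `phase`.
#' @export
multibeam_intensities <- function(stack, lambda, d, I_incident = 1,
                                  polarization = c("s", "p"),
                                  tol = 1e-9, max_orders = 50L) {
  if (d < 0 || I_incident <= 0)
    tf_error("need d >= 0 and I_incident > 0", "tf_bad_input")
  iface <- stack_interfaces(stack, match.arg(polarization))
  ords <- order_intensities(iface, I_incident, tol, max_orders)
  delta <- phase_difference(optical_path_difference(stack, d), lambda)
  data.frame(m = ords$m, intensity = ords$intensity, phase = ords$m * delta)
}

#' Coherent superposition of the reflection orders
#'
#' Sums the reflected rays in the complex plane,
#' `A = sum_m s_m sqrt(I_m) exp(i m Delta)`, and returns the interference
#' intensity `|A|^2`, averaged over s- and p-polarization (the broadband LED
#' source is unpolarized). With `phase_convention = "fresnel"` (default) the
#' sign `s_m` of each ray's amplitude is taken from the product of its
#' Fresnel amplitude coefficients, so the half-wave phase jump of the
#' air-to-lipid reflection is kept and a vanishing film interferes
#' destructively (thin film = dark). `phase_convention = "literal"` sets all
#' `s_m = +1`, i.e. the magnitude-only reading of the reflection-transmission
#' model, under which `d = 0` is the in-phase maximum.
#'
#' @param stack an [optical_stack()].
#' @param lambda wavelength(s) in nm (vectorized).
#' @param d lipid thickness in nm (scalar).
#' @param I_incident incident intensity.
#' @param phase_convention `"fresnel"` or `"literal"`, see Details.
#' @param tol,max_orders truncation controls, as in
#'   [multibeam_intensities()].
#' @return list with `wavelength`, `thickness`, per-polarization complex
#'   `amplitude_s`/`amplitude_p`, and unpolarized `intensity` (all vectors
#'   along `lambda`).
#' @export
interfere <- function(stack, lambda, d, I_incident = 1,
                      phase_convention = c("fresnel", "literal"),
                      tol = 1e-9, max_orders = 50L) {
  phase_convention <- match.arg(phase_convention)
  if (d < 0) tf_error("thickness d must be >= 0", "tf_bad_input")
  delta <- phase_difference(optical_path_difference(stack, d), lambda)
  amp <- lapply(c(s = "s", p = "p"), function(pol) {
    iface <- stack_interfaces(stack, pol)
    ords <- order_intensities(iface, I_incident, tol, max_orders)
    signs <- if (phase_convention == "literal") {
      rep(1, length(ords$m))
    } else {
      # ray 0: r12; ray m >= 1: t12 r23 t21 (r21 r23)^(m-1); transmission
      # coefficients are positive, so only reflection signs matter.
      c(iface$sign_r12,
        iface$sign_r23 * (iface$sign_r21 * iface$sign_r23)^(ords$m[-1] - 1L))
    }
    a <- signs * sqrt(ords$intensity)
    # A(lambda) = sum_m a_m exp(i m delta)
    z <- exp(1i * outer(delta, ords$m))
    drop(z %*% a)
  })
  list(wavelength = lambda, thickness = d,
       amplitude_s = amp$s, amplitude_p = amp$p,
       intensity = (Mod(amp$s)^2 + Mod(amp$p)^2) / 2)
}

#' Integrate a spectrum against observer color-matching functions
#'
#' Each output channel is the wavelength sum of spectral intensity times
#' illuminant weight times the corresponding color-matching function, i.e.
#' `Red = sum_lambda I(lambda) S(lambda) r_bar(lambda)` and likewise for
#' green and blue.
#'
#' @param intensity spectral intensity: a vector over the wavelength grid or
#'   a matrix with one column per spectrum (rows = wavelengths).
#' @param observer an observer table from [cie1964_observer()].
#' @param illuminant an illuminant table from [blackbody_illuminant()] or
#'   [equal_energy_illuminant()]; must share the observer's grid.
#' @return a length-3 vector (R, G, B) for a single spectrum, otherwise a
#'   matrix with 3 columns.
#' @export
spectrum_to_rgb <- function(intensity, observer, illuminant) {
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1)
  if (nrow(intensity) != nrow(observer) ||
      !isTRUE(all.equal(observer$wavelength, illuminant$wavelength)))
    tf_error("intensity, observer and illuminant must share one wavelength grid",
             "tf_grid_mismatch")
  cmf <- as.matrix(observer[, c("r_bar", "g_bar", "b_bar")])
  out <- t(intensity * illuminant$power) %*% cmf
  colnames(out) <- c("R", "G", "B")
  if (ncol(intensity) == 1) drop(out) else out
}
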