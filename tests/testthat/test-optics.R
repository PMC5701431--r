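# Fresnel interface physics and the multi-reflection interference model.

test_that("Snell refraction follows the law and its symmetries", {
  st <- optical_stack()
  expect_equal(snell_refraction_angle(st, "air", "lipid", angle = 0), 0)
  st2 <- optical_stack(n_air = 1, n_lipid = 2)
  expect_equal(snell_refraction_angle(st2, "air", "lipid", angle = pi / 6),
               asin(0.25))
  # round trip air -> lipid -> air restores the incidence angle
  th1 <- 0.4
  th2 <- snell_refraction_angle(st, "air", "lipid", angle = th1)
  expect_equal(snell_refraction_angle(st, "lipid", "air", angle = th2), th1)
  expect_error(snell_refraction_angle(st, "air", "tear"), "adjacent")
  # total internal reflection is signaled for a decreasing-index interface
  expect_error(fresnel_amplitudes(1.48, 1.0, 1.2),
               class = "tf_total_internal_reflection")
})

test_that("optical path difference is 2 n d cos(beta)", {
  st <- optical_stack(n_lipid = 1.5)
  expect_equal(optical_path_difference(st, 0), 0)
  expect_equal(optical_path_difference(st, 100), 300)  # beta = 0
  d <- seq(0, 200, by = 10)
  expect_true(all(diff(optical_path_difference(st, d)) > 0))
  expect_error(optical_path_difference(st, -1), class = "tf_bad_input")
})

test_that("phase difference is 2 pi OPD / lambda", {
  expect_equal(phase_difference(300, 600), pi)
  expect_equal(phase_difference(0, 500), 0)
  expect_equal(phase_difference(300, 1200), phase_difference(300, 600) / 2)
  expect_error(phase_difference(300, 0), class = "tf_bad_input")
})

test_that("Fresnel amplitudes match closed forms at special angles", {
  a <- fresnel_amplitudes(1, 1.5, 0)
  expect_equal(a$r_s, -0.2)
  expect_equal(a$r_p, 0.2)  # sign convention: r_p = (n2 c1 - n1 c2)/(...)
  expect_equal(abs(a$r_s), 0.2)
  # Brewster angle: p reflection vanishes
  thb <- atan(1.5 / 1)
  expect_lt(abs(fresnel_amplitudes(1, 1.5, thb)$r_p), 1e-12)
  # no interface
  same <- fresnel_amplitudes(1.4, 1.4, 0.3)
  expect_equal(same$r_s, 0)
  expect_equal(same$r_p, 0)
  expect_equal(same$t_s, 1)
  expect_equal(same$t_p, 1)
})

test_that("energy is conserved at every interface", {
  rt <- reflectance_transmittance(1, 1.5, 0)
  expect_equal(rt$R_s, 0.04)
  expect_equal(rt$R_p, 0.04)
  # normal incidence: reflectance symmetric under swapping media
  expect_equal(reflectance_transmittance(1.5, 1, 0)$R_s, rt$R_s)
  set.seed(11)
  for (i in 1:100) {
    n1 <- runif(1, 1, 1.8); n2 <- runif(1, 1, 1.8)
    th <- runif(1, 0, pi / 2 - 0.05)
    if (n1 * sin(th) / n2 > 1) next
    rt <- reflectance_transmittance(n1, n2, th)
    expect_lt(abs(rt$R_s + rt$T_s - 1), 1e-12)
    expect_lt(abs(rt$R_p + rt$T_p - 1), 1e-12)
  }
})

test_that("reflection orders form a geometric sequence matching the closed form", {
  set.seed(21)
  for (i in 1:50) {
    st <- optical_stack(n_lipid = runif(1, 1.3, 1.7),
                        n_tear = runif(1, 1.2, 1.5),
                        incidence_angle = runif(1, 0, 0.8))
    mb <- multibeam_intensities(st, runif(1, 400, 700), runif(1, 0, 240),
                                tol = 1e-14, max_orders = 40)
    I <- mb$intensity
    if (length(I) > 2) {
      ratios <- I[-(1:2)] / I[-c(1, length(I))]
      expect_equal(ratios, rep(ratios[1], length(ratios)), tolerance = 1e-10)
    }
    # brute-force partial sum vs geometric closed form for the tail
    iface <- tearfilm:::stack_interfaces(st, "s")
    rho <- iface$R21 * iface$R23
    I1 <- iface$T12 * iface$R23 * iface$T21
    closed <- iface$R12 + I1 / (1 - rho)
    brute <- iface$R12 + sum(I1 * rho^(0:200))
    expect_lt(abs(closed - brute), 1e-10)
  }
})

test_that("multibeam phases vanish at zero thickness and truncation behaves", {
  st <- optical_stack()
  mb <- multibeam_intensities(st, 550, 0)
  expect_true(all(mb$phase == 0))
  # looser tolerance keeps fewer orders
  n_tight <- nrow(multibeam_intensities(st, 550, 80, tol = 1e-14))
  n_loose <- nrow(multibeam_intensities(st, 550, 80, tol = 1e-3))
  expect_gt(n_tight, n_loose)
})

test_that("the literal coherent sum peaks at zero thickness", {
  st <- optical_stack()
  mb <- multibeam_intensities(st, 550, 0)
  expect_equal(interfere(st, 550, 0, phase_convention = "literal")$intensity,
               sum(sqrt(mb$intensity))^2)
})

test_that("interference intensity is bounded and periodic in thickness", {
  st <- optical_stack()
  mb <- multibeam_intensities(st, 600, 0)
  upper <- sum(sqrt(mb$intensity))^2
  for (d in c(0, 35, 90, 170)) {
    ii <- interfere(st, 600, d)$intensity
    expect_gte(ii, 0)
    expect_lte(ii, upper + 1e-12)
  }
  period <- 600 / (2 * st$n_lipid)  # normal incidence
  expect_equal(interfere(st, 600, 30)$intensity,
               interfere(st, 600, 30 + period)$intensity, tolerance = 1e-6)
})

test_that("truncation error of the coherent sum is tiny for the default stack", {
  st <- optical_stack()
  lam <- seq(400, 700, by = 50)
  for (d in c(10, 80, 200)) {
    i2 <- interfere(st, lam, d, max_orders = 2, tol = 0)$intensity
    i50 <- interfere(st, lam, d, max_orders = 50, tol = 1e-15)$intensity
    # omitted orders contribute through amplitude cross terms, ~2e-6 here
    expect_lt(max(abs(i2 - i50)), 1e-5)
  }
})

test_that("spectrum integration matches a term-by-term oracle and is linear", {
  obs <- cie1964_observer(seq(400, 700, by = 10))
  ill <- equal_energy_illuminant(seq(400, 700, by = 10))
  expect_equal(spectrum_to_rgb(rep(0, nrow(obs)), obs, ill),
               c(R = 0, G = 0, B = 0))
  set.seed(5)
  I <- runif(nrow(obs))
  got <- spectrum_to_rgb(I, obs, ill)
  oracle <- c(0, 0, 0)
  for (k in seq_len(nrow(obs))) {
    oracle <- oracle + I[k] * ill$power[k] *
      c(obs$r_bar[k], obs$g_bar[k], obs$b_bar[k])
  }
  expect_lt(max(abs(got - oracle)), 1e-12)
  expect_equal(unname(spectrum_to_rgb(3 * I, obs, ill)), unname(3 * got))
  expect_error(spectrum_to_rgb(I[-1], obs, ill), class = "tf_grid_mismatch")
})

test_that("observer and illuminant tables satisfy their invariants", {
  obs <- cie1964_observer()
  expect_equal(obs$wavelength, 360:830)
  expect_true(all(is.finite(c(obs$r_bar, obs$g_bar, obs$b_bar))))
  # the y (luminance) matching function peaks near 557 nm
  xyz <- cie1964_xyz()
  expect_equal(xyz$wavelength[which.max(xyz$y_bar)], 556, tolerance = 2)
  ill <- blackbody_illuminant(6500)
  expect_true(all(ill$power >= 0) && any(ill$power > 0))
  expect_equal(max(ill$power), 1)
  # hotter blackbody shifts weight toward the blue end
  hot <- blackbody_illuminant(10000)
  expect_gt(hot$power[1] / hot$power[471], ill$power[1] / ill$power[471])
  expect_error(blackbody_illuminant(6500, c(300, 400)), class = "tf_bad_input")
})
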