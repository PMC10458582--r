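test_that("phase follows the double-pass law and its symmetries", {
  cav <- fp_cavity(d_um = 300)
  # direct substitution: 4 pi n d / lambda at 1550 nm
  expect_equal(fp_phase(1550, cav), 4 * pi * 3e5 / 1550)
  # resonance condition: lambda = 4 n d / (2k+1) gives an odd multiple of pi
  for (k in c(0, 5, 396)) {
    lam <- 4 * 3e5 / (2 * k + 1)
    expect_equal(fp_phase(lam, cav), (2 * k + 1) * pi)
  }
  # an extra phase offset shifts the phase exactly
  cav_pi <- fp_cavity(d_um = 300, phi0 = pi)
  expect_equal(fp_phase(1550, cav_pi) - fp_phase(1550, cav), pi)
  # strictly decreasing in wavelength
  wl <- seq(1510, 1590, length.out = 101)
  expect_true(all(diff(fp_phase(wl, cav)) < 0))
  expect_error(fp_phase(-1, cav), class = "fp_invalid_input")
})

test_that("reflectance matches hand-evaluated values and fringe geometry", {
  # single-surface limit: no reflector, flat response at R1
  cav0 <- fp_cavity(d_um = 300, R2 = 0)
  expect_equal(fp_reflectance(c(1510, 1550, 1590), cav0), rep(0.04, 3))

  # hand evaluation of the two-beam expression at cos(delta) = -1 and +1
  expect_equal(oracle_reflectance_at_cos(0.04, 0.99, 1, -1), 0.9933223,
               tolerance = 1e-6)
  expect_equal(oracle_reflectance_at_cos(0.04, 0.99, 1, +1), 0.9850376,
               tolerance = 1e-6)

  # the model hits those values at resonance/anti-resonance wavelengths,
  # confirming that maxima are at odd multiples of pi
  cav <- fp_cavity(d_um = 300)
  lam_odd <- 4 * 3e5 / 775          # delta = 775 pi (odd)
  lam_even <- 4 * 3e5 / 776         # delta = 776 pi (even)
  expect_equal(fp_reflectance(lam_odd, cav), 0.9933223, tolerance = 1e-6)
  expect_equal(fp_reflectance(lam_even, cav), 0.9850376, tolerance = 1e-6)
  expect_gt(fp_reflectance(lam_odd, cav), fp_reflectance(lam_even, cav))

  # periodic in delta with period 2 pi: equal values at adjacent odd orders
  expect_equal(fp_reflectance(4 * 3e5 / 775, cav),
               fp_reflectance(4 * 3e5 / 777, cav))

  # monotone decreasing in cos(delta): extrema only at multiples of pi
  delta <- seq(775 * pi, 777 * pi, length.out = 401)
  ir <- fpsense:::fp_reflectance_phase(delta, cav)
  expect_equal(which.max(ir), 1L)  # odd multiple of pi at the left end
  expect_equal(which.min(ir), 201L)  # even multiple in the middle
  expect_true(all(ir >= 0 & ir <= 1))
})

test_that("generated spectra resolve the analytic fringe count", {
  cav <- fp_cavity(d_um = 300)
  s <- fp_spectrum(cav)
  expect_s3_class(s, "fp_spectrum")
  expect_true(all(diff(s$wavelength_nm) > 0))
  expect_true(all(s$intensity >= 0 & s$intensity <= 1))

  # interior local maxima count equals the closed-form odd-order count
  # for cavity lengths across the working range (resonances within two
  # samples of the span edge are censored by interior-maxima counting
  # and excluded from the comparison)
  spacing <- 80 / 16000
  for (d in c(133.7, 218.4, 300, 387.2, 471.9)) {
    res <- oracle_resonances(d)
    res <- res[res > 1510 + 2 * spacing & res < 1590 - 2 * spacing]
    sp <- fp_spectrum(fp_cavity(d_um = d))
    pk <- detect_peaks(sp, min_peaks = 0)
    inner <- pk$wavelength_nm[pk$wavelength_nm > 1510 + 2 * spacing &
                                pk$wavelength_nm < 1590 - 2 * spacing]
    expect_length(inner, length(res))
  }

  # sub-wavelength cavity: a single broad fringe at most
  tiny <- fp_spectrum(fp_cavity(d_um = 0.3875), check = "none")
  pk <- detect_peaks(tiny, min_peaks = 0)
  expect_lte(nrow(pk), 1)

  # doubling d approximately halves the FSR near 1550 nm
  expect_equal(fsr_nm(fp_cavity(d_um = 600)) / fsr_nm(fp_cavity(d_um = 300)),
               0.5)

  # coarse grids trigger the resolvability warning / error
  expect_warning(fp_spectrum(cav, n_samples = 101), class = "fp_grid_warning")
  expect_error(fp_spectrum(cav, n_samples = 101, check = "error"),
               class = "fp_grid_error")
})

test_that("resonance_wavelengths matches the independent odd-order oracle", {
  for (d in c(100, 250, 300, 499.5)) {
    expect_equal(resonance_wavelengths(fp_cavity(d_um = d))$wavelength_nm,
                 oracle_resonances(d), tolerance = 1e-12)
  }
  # with an extra phase the resonances shift; they still satisfy the
  # odd-multiple condition of the full phase
  cav <- fp_cavity(d_um = 300, phi0 = 1)
  res <- resonance_wavelengths(cav)
  expect_true(all(abs((fp_phase(res$wavelength_nm, cav) / pi) %% 2 - 1)
                  < 1e-9))
})

test_that("temperature sensitivity implements the CTE-mismatch model", {
  th <- thermal_params(l_mm = 6, alpha1_per_C = 15e-6, alpha2_per_C = 5.5e-7)
  s <- temperature_sensitivity(th, 300)
  expect_equal(s, 6 * 15e-6 * 1e3 - (6 - 0.3) * 5.5e-7 * 1e3)
  expect_equal(round(s, 3), 0.087)

  # matched materials with zero cavity cancel exactly
  expect_equal(
    temperature_sensitivity(thermal_params(6, 1e-5, 1e-5), 0), 0)
  # d -> l recovers l * alpha1
  expect_equal(
    temperature_sensitivity(th, 6e3 - 1e-6), 6 * 15e-6 * 1e3,
    tolerance = 1e-6)
  # cavity longer than the gauge is impossible geometry
  expect_error(temperature_sensitivity(th, 7e3),
               class = "fp_invalid_geometry")

  # linear in l, alpha1, alpha2; increasing in d when alpha2 > 0
  expect_equal(temperature_sensitivity(thermal_params(12, 15e-6, 0), 300),
               2 * temperature_sensitivity(thermal_params(6, 15e-6, 0), 300))
  expect_gt(temperature_sensitivity(th, 400),
            temperature_sensitivity(th, 300))
})

test_that("apply_temperature drifts linearly, with model or empirical slope", {
  th <- thermal_params()
  expect_equal(apply_temperature(300, 0, th), 300)
  # 20 degC with the modelled sensitivity
  expect_equal(apply_temperature(300, 20, th), 300 + 20 * 0.086865,
               tolerance = 1e-9)
  # an empirically fitted sensitivity can replace the model value
  expect_equal(apply_temperature(300, 20, sensitivity_um_per_C = 0.1081),
               300 + 2.162)
})
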