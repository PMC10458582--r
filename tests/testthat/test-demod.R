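test_that("detect_peaks finds and refines all interior maxima", {
  s <- fp_spectrum(fp_cavity(d_um = 300))
  pk <- detect_peaks(s)
  truth <- oracle_resonances(300)
  expect_equal(nrow(pk), 20)
  expect_equal(length(truth), 20)
  # refined wavelengths within 2 pm of the analytic resonances
  expect_lt(max(abs(pk$wavelength_nm - truth)), 2e-3)
  expect_true(all(diff(pk$wavelength_nm) > 0))
  # the last peak sits 0.6 nm from the span edge (< half a fringe):
  # kept but flagged
  expect_true(pk$edge[20])
  expect_false(any(pk$edge[1:19]))

  # no fringes at all -> insufficient-fringes error
  flat <- fp_spectrum(fp_cavity(d_um = 300, R2 = 0))
  expect_error(detect_peaks(flat), class = "fp_insufficient_fringes")
})

test_that("fringe_order recovers the integer order from peak pairs", {
  # forward simulation at d = 300 um: odd orders m = 755..793, so the
  # first peak has m = 793 = 2k+1 -> k = 396
  res300 <- oracle_resonances(300)
  fo <- fringe_order(res300[1], res300[20], i = 20)
  expect_equal(fo$k, 396L)
  expect_lt(fo$k_residual, 1e-9)

  # d = 250 um: 17 odd orders 629..661, first peak m = 661 -> k = 330
  res250 <- oracle_resonances(250)
  expect_equal(length(res250), 17)
  fo <- fringe_order(res250[1], res250[17], i = 17)
  expect_equal(fo$k, 330L)

  # algebraic identity on two adjacent constructed resonances
  for (k_true in c(3, 57, 396)) {
    d_nm <- 123456.7
    lam1 <- 4 * d_nm / (2 * k_true + 1)
    lam2 <- 4 * d_nm / (2 * k_true - 1)
    fo <- fringe_order(lam1, lam2, i = 2)
    expect_equal(fo$k, k_true)
    expect_lt(fo$k_residual, 1e-6)
  }

  # exact on analytic resonances; robust to +/-10 pm perturbations for
  # d up to 500 um
  withr::with_seed(11, {
    for (d in c(150, 300, 500)) {
      res <- oracle_resonances(d)
      m <- length(res)
      k_true <- fringe_order(res[1], res[m], i = m)$k
      for (r in 1:20) {
        lam1 <- res[1] + stats::runif(1, -0.01, 0.01)
        lamm <- res[m] + stats::runif(1, -0.01, 0.01)
        expect_equal(fringe_order(lam1, lamm, i = m)$k, k_true)
      }
    }
  })

  expect_error(fringe_order(1550, 1540, i = 2), class = "fp_invalid_input")
  # a wavelength far from any consistent order is ambiguous
  expect_error(fringe_order(1513, 1589.404, i = 20,
                            residual_tolerance = 1e-4),
               class = "fp_ambiguous_order")
})

test_that("cavity_length implements the quarter-wave relation", {
  expect_equal(cavity_length(1550, 0), 0.3875)
  res300 <- oracle_resonances(300)
  expect_equal(cavity_length(res300[1], 396), 300, tolerance = 1e-12)
  res250 <- oracle_resonances(250)
  expect_equal(cavity_length(res250[1], 330), 250, tolerance = 1e-12)
  # refractive index scales the length down
  expect_equal(cavity_length(1550, 0, n = 1.45), 0.3875 / 1.45)
})

test_that("demodulation round-trips the forward model", {
  # the two bench sensors' initial cavity lengths
  for (d in c(285, 300)) {
    est <- demodulate(fp_spectrum(fp_cavity(d_um = d)))
    expect_lt(abs(est$d_um - d), 1e-3)  # < 1 nm
    expect_equal(est$opd_um, 2 * est$d_um)
  }
  # round-trip identity across the working range (coarse lattice here;
  # the fine lattice runs in the acceptance suite)
  for (d in seq(105.3, 495.3, by = 65)) {
    est <- demodulate(fp_spectrum(fp_cavity(d_um = d)))
    expect_lt(abs(est$d_um - d), 1e-3)
  }

  # wavelength jitter of the interrogator scale propagates as
  # ~ (2k+1)/4 * shift in d
  withr::with_seed(4, {
    errs <- vapply(1:15, function(r) {
      sh <- stats::rnorm(1, sd = 2e-3)
      est <- demodulate(jittered_spectrum(300, shift_nm = sh))
      est$d_um - (2 * 396 + 1) / 4 * sh / 1e3 - 300
    }, numeric(1))
    expect_lt(max(abs(errs)), 1e-3)
  })

  # consensus and first/last agree on clean spectra
  s <- fp_spectrum(fp_cavity(d_um = 300))
  expect_equal(demodulate(s, method = "consensus")$k, demodulate(s)$k)
  expect_equal(demodulate(s, method = "consensus")$k_disagreement, 0L)
})

test_that("peak count over a fixed span is non-decreasing in d", {
  counts <- vapply(seq(120, 480, by = 40), function(d) {
    nrow(detect_peaks(fp_spectrum(fp_cavity(d_um = d))))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("track demodulates sequences and isolates faults", {
  cav <- fp_cavity(d_um = 300)
  frames <- lapply(0:4, function(t) {
    fp_spectrum(cav, timestamp_s = t, channel = "ch1")
  })
  ser <- track(frames)
  expect_s3_class(ser, "fp_series")
  expect_equal(nrow(ser), 5)
  expect_true(all(ser$flag == "ok"))
  expect_equal(stats::var(ser$d_um), 0)

  # staircase ground truth reproduced within interpolation error
  d_levels <- c(300, 430, 560, 690)
  frames <- purrr::imap(rep(d_levels, each = 3), function(d, i) {
    fp_spectrum(fp_cavity(d_um = d), timestamp_s = i - 1, channel = "ch1")
  })
  ser <- track(frames, jump_threshold_um = Inf)
  expect_equal(ser$d_um, rep(d_levels, each = 3), tolerance = 1e-5)

  # one corrupted frame becomes a flagged gap; neighbours unaffected
  frames <- lapply(0:4, function(t) {
    fp_spectrum(cav, timestamp_s = t, channel = "ch1")
  })
  frames[[3]] <- as_fp_spectrum(
    tibble::tibble(wavelength_nm = seq(1510, 1590, length.out = 100),
                   intensity = rep(0.04, 100)),
    timestamp_s = 2, channel = "ch1")
  ser <- track(frames)
  expect_equal(sum(startsWith(ser$flag, "failed")), 1L)
  expect_true(is.na(ser$d_um[3]))
  expect_equal(sum(ser$flag == "ok"), 4L)
  expect_lt(max(abs(ser$d_um[ser$flag == "ok"] - 300)), 1e-3)

  # large unexpected jumps are advisory-flagged, activation-scale steps
  # pass the default threshold
  frames2 <- purrr::imap(c(300, 300, 590), function(d, i) {
    fp_spectrum(fp_cavity(d_um = d), timestamp_s = i - 1, channel = "ch1")
  })
  ser2 <- track(frames2)
  expect_equal(ser2$flag, c("ok", "ok", "suspect_jump"))

  expect_error(track(list()), class = "fp_invalid_input")
})

test_that("demodulate_peaks accepts interrogator-style peak tables", {
  res <- oracle_resonances(300)
  tbl <- tibble::tibble(wavelength_nm = res, intensity = 0.99)
  est <- demodulate_peaks(tbl)
  expect_lt(abs(est$d_um - 300), 1e-9)
  expect_error(demodulate_peaks(tbl[1, ]),
               class = "fp_insufficient_fringes")
})
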