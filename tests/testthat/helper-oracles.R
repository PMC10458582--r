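# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: resonances are enumerated directly from
# the odd-order condition lambda = 4 n d / m.

oracle_resonances <- function(d_um, wl_min = 1510, wl_max = 1590, n = 1) {
  d_nm <- d_um * 1e3
  m_hi <- floor(4 * n * d_nm / wl_min)
  m_lo <- ceiling(4 * n * d_nm / wl_max)
  if (m_hi < m_lo) return(numeric(0))
  m <- seq(m_lo, m_hi)
  m <- m[m %% 2 == 1]
  sort(4 * n * d_nm / m)
}

# hand evaluation of the two-beam reflectance at a given cos(delta)
oracle_reflectance_at_cos <- function(R1, R2, q, cd) {
  b <- 2 * q * sqrt(R1 * R2)
  (R1 + q^2 * R2 - b * cd) / (1 + q^2 * R1 * R2 - b * cd)
}

# spectrum tibble with peaks rigidly shifted by `shift_nm` and optional
# intensity noise, built outside the package's simulators
jittered_spectrum <- function(d_um, shift_nm = 0, intensity_sd = 0,
                              wl_min = 1510, wl_max = 1590,
                              n_samples = 16001, timestamp_s = NA,
                              channel = NA) {
  wl <- seq(wl_min, wl_max, length.out = n_samples)
  cav <- fp_cavity(d_um = d_um)
  y <- fp_reflectance(wl - shift_nm, cav)
  if (intensity_sd > 0) y <- y + stats::rnorm(length(y), sd = intensity_sd)
  as_fp_spectrum(tibble::tibble(wavelength_nm = wl, intensity = y),
                 timestamp_s = timestamp_s, channel = channel)
}

# noisy plateau staircase series (ground truth in displacement space,
# bypassing the optics) for step-detection tests
staircase_series <- function(levels_um, n_per = 30, noise_sd = 0,
                             channel = "ch1", t0 = 0) {
  d <- rep(levels_um, each = n_per)
  if (noise_sd > 0) d <- d + stats::rnorm(length(d), sd = noise_sd)
  tibble::tibble(
    timestamp_s = t0 + seq_along(d) - 1,
    channel = channel,
    d_um = d,
    k = NA_integer_,
    flag = "ok"
  )
}
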