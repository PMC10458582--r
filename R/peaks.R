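#' Detect interference maxima in a reflection spectrum
#'
#' Finds interior local maxima of the reflected intensity, filters them
#' by prominence relative to the fringe amplitude, and refines each
#' retained peak to sub-sample wavelength precision.
#'
#' Candidate maxima are located on a lightly Savitzky-Golay-smoothed
#' copy of the intensity so that sample-to-sample noise does not spawn
#' spurious candidates; each candidate's prominence (height above the
#' higher of its two flanking valleys) must exceed `min_prominence`
#' times the overall fringe amplitude. Refinement fits a least-squares
#' parabola to the raw intensity over a window confined to the top of
#' the fringe (falling back to the classic 3-point quadratic when the
#' window is tiny); the fringe shape is symmetric in phase at its
#' maximum, so the parabola vertex localizes the peak at the picometre
#' scale on the default grid.
#'
#' Maxima lying within half a local fringe spacing of either span
#' boundary are kept but flagged `edge = TRUE`: their fringes may be
#' truncated and the interpolation less reliable.
#'
#' @param spectrum An `fp_spectrum` (or data frame with `wavelength_nm`
#'   and `intensity`).
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   fringe amplitude (max - min of the smoothed intensity).
#' @param min_amplitude Minimum fringe amplitude (normalized intensity
#'   units) below which the spectrum is considered fringe-free; the
#'   default 0.002 sits well under the ~0.008 contrast of a cleaved
#'   fiber / high-reflectivity cavity but above smoothed noise.
#' @param min_peaks Minimum number of peaks required; fewer raises an
#'   insufficient-fringes error. Set to 0 to allow any count.
#' @param refine Logical; refine peak wavelengths by parabolic
#'   interpolation (default `TRUE`).
#' @return A tibble (class `fp_peaks`) with columns `peak_index`,
#'   `wavelength_nm`, `intensity`, `prominence`, `edge`, ordered by
#'   ascending wavelength, carrying `timestamp_s` and `channel`
#'   attributes from the input.
#' @examples
#' s <- fp_spectrum(fp_cavity(d_um = 300))
#' detect_peaks(s)
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.25, min_peaks = 2,
                         refine = TRUE, min_amplitude = 0.002) {
  if (!inherits(spectrum, "fp_spectrum")) {
    spectrum <- as_fp_spectrum(spectrum)
  }
  x <- spectrum$wavelength_nm
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3) {
    fp_abort("Spectrum has fewer than 3 samples.", "fp_invalid_input")
  }
  h <- stats::median(diff(x))

  # smoothing for candidate detection only (~0.4 nm window, well under
  # any resolvable fringe)
  w <- round(0.4 / h)
  w <- max(5, min(w, floor(n / 10)))
  if (w %% 2 == 0) w <- w + 1
  ys <- if (n >= 15 && w >= 5) signal::sgolayfilt(y, p = 2, n = w) else y

  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                  ys[2:(n - 1)] >= ys[3:n]) + 1L
  amp <- max(ys) - min(ys)
  if (amp < min_amplitude) cand <- integer(0)  # fringe-free spectrum
  peaks <- empty_peaks(spectrum)
  if (length(cand) > 0) {
    prom <- peak_prominences(ys, cand)
    keep <- prom >= min_prominence * amp
    cand <- cand[keep]
    prom <- prom[keep]
    if (length(cand) > 0) {
      lam <- numeric(length(cand))
      val <- numeric(length(cand))
      gaps <- candidate_gaps(cand, n)
      for (j in seq_along(cand)) {
        r <- refine_peak(x, y, ys, cand[j], gaps[j], refine)
        lam[j] <- r[1]
        val[j] <- r[2]
      }
      fringe_nm <- gaps * h
      edge <- (lam - x[1]) < 0.5 * fringe_nm |
        (x[n] - lam) < 0.5 * fringe_nm
      peaks <- tibble::tibble(
        peak_index = seq_along(cand),
        wavelength_nm = lam,
        intensity = val,
        prominence = prom,
        edge = edge
      )
    }
  }
  if (nrow(peaks) < min_peaks) {
    fp_abort(sprintf(
      "Only %d interference peak(s) found; at least %d required for fringe-order demodulation.",
      nrow(peaks), min_peaks), "fp_insufficient_fringes")
  }
  class(peaks) <- c("fp_peaks", class(peaks))
  attr(peaks, "timestamp_s") <- attr(spectrum, "timestamp_s")
  attr(peaks, "channel") <- attr(spectrum, "channel")
  peaks
}

empty_peaks <- function(spectrum) {
  tibble::tibble(peak_index = integer(), wavelength_nm = numeric(),
                 intensity = numeric(), prominence = numeric(),
                 edge = logical())
}

# Topographic prominence of each candidate: walk outward (over the
# other candidates) until a strictly higher one is found, tracking the
# lowest valley crossed; the reference level is the higher of the two
# side valleys. A walk that reaches a span boundary without meeting a
# higher candidate is "open": the fringe may be truncated there, so an
# open side is ignored (both open: the lower valley is used). This keeps
# genuine outermost fringes -- later edge-flagged -- while rejecting
# noise bumps riding on a flank, whose nearest higher sample is close by.
peak_prominences <- function(ys, cand) {
  n <- length(ys)
  m <- length(cand)
  h <- ys[cand]
  # valley minima between consecutive candidates and out to the ends
  v_mid <- if (m > 1) {
    vapply(seq_len(m - 1), function(j) min(ys[cand[j]:cand[j + 1]]),
           numeric(1))
  } else {
    numeric(0)
  }
  v_left0 <- min(ys[1:cand[1]])
  v_rightm <- min(ys[cand[m]:n])
  side <- function(j, dir) {
    minv <- Inf
    i <- j + dir
    while (i >= 1 && i <= m) {
      minv <- min(minv, if (dir < 0) v_mid[i] else v_mid[i - 1])
      if (h[i] > h[j]) {
        return(list(closed = TRUE, minv = minv))
      }
      i <- i + dir
    }
    minv <- min(minv, if (dir < 0) v_left0 else v_rightm)
    list(closed = FALSE, minv = minv)
  }
  vapply(seq_len(m), function(j) {
    l <- side(j, -1L)
    r <- side(j, 1L)
    ref <- if (l$closed && r$closed) {
      max(l$minv, r$minv)
    } else if (l$closed) {
      l$minv
    } else if (r$closed) {
      r$minv
    } else {
      min(l$minv, r$minv)
    }
    h[j] - ref
  }, numeric(1))
}

# distance (in samples) from each candidate to its nearest neighbour,
# used both as a local fringe-spacing estimate and to bound the
# refinement window
candidate_gaps <- function(cand, n) {
  m <- length(cand)
  if (m == 1L) {
    return(max(2L, floor(n / 4)))
  }
  d <- diff(cand)
  pmax(2L, pmin(c(d[1], d), c(d, d[m - 1L])))
}

refine_peak <- function(x, y, ys, i, gap, refine) {
  n <- length(y)
  if (!refine) {
    return(c(x[i], y[i]))
  }
  hw <- min(floor(0.3 * gap), i - 1L, n - i)
  if (hw >= 2L) {
    idx <- (i - hw):(i + hw)
    t <- x[idx] - x[i]
    fit <- tryCatch(stats::lm.fit(cbind(1, t, t^2), y[idx])$coefficients,
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit[3]) && fit[3] < 0) {
      v <- -fit[2] / (2 * fit[3])
      if (abs(v) <= max(abs(t))) {
        return(c(x[i] + v, fit[1] - fit[2]^2 / (4 * fit[3])))
      }
    }
  }
  if (i > 1L && i < n) {
    denom <- ys[i - 1] - 2 * ys[i] + ys[i + 1]
    if (denom < 0) {
      off <- 0.5 * (ys[i - 1] - ys[i + 1]) / denom
      off <- max(-0.5, min(0.5, off))
      return(c(x[i] + off * (x[i + 1] - x[i - 1]) / 2, y[i]))
    }
  }
  c(x[i], y[i])
}
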