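#' Fringe order from two interference-peak wavelengths
#'
#' Adjacent interference maxima of a two-beam F-P cavity satisfy
#' \eqn{4 \pi n d / \lambda_i = (2(k - (i-1)) + 1)\pi}, where
#' \eqn{\lambda_1} is the shortest-wavelength peak in the span and `k`
#' its (integer) fringe order. Eliminating `d` between the first and the
#' i-th peak gives
#' \deqn{k = \frac{(2i-3)\,\lambda_i + \lambda_1}{2(\lambda_i - \lambda_1)},}
#' which is rounded to the nearest integer; the distance to that integer
#' is returned as a quality measure and must not exceed
#' `residual_tolerance`.
#'
#' @param lam1_nm Wavelength of the first (shortest-wavelength) peak, nm.
#' @param lami_nm Wavelength of the i-th peak, nm; must exceed `lam1_nm`.
#' @param i Index of the second peak counted from the first (`i >= 2`).
#' @param residual_tolerance Maximum allowed distance of the raw order
#'   from an integer before the order is declared ambiguous.
#' @return A one-row tibble with columns `k` (integer fringe order),
#'   `k_raw` and `k_residual`.
#' @examples
#' # two adjacent resonances of a 300 um air cavity (orders 793 and 791)
#' fringe_order(1.2e6 / 793, 1.2e6 / 791, i = 2)
#' @export
fringe_order <- function(lam1_nm, lami_nm, i, residual_tolerance = 0.3) {
  check_number(lam1_nm, "lam1_nm", lower = 0, strict_lower = TRUE)
  check_number(lami_nm, "lami_nm", lower = 0, strict_lower = TRUE)
  check_number(i, "i", lower = 2)
  if (i != round(i)) {
    fp_abort("`i` must be an integer peak index.", "fp_invalid_input")
  }
  if (lami_nm <= lam1_nm) {
    fp_abort("`lami_nm` must exceed `lam1_nm`: the first peak is the shortest-wavelength peak.",
             "fp_invalid_input")
  }
  k_raw <- ((2 * i - 3) * lami_nm + lam1_nm) / (2 * (lami_nm - lam1_nm))
  k <- round(k_raw)
  residual <- abs(k_raw - k)
  if (residual > residual_tolerance) {
    fp_abort(sprintf(
      "Ambiguous fringe order: raw value %.4f is %.3f away from the nearest integer (tolerance %.3f).",
      k_raw, residual, residual_tolerance), "fp_ambiguous_order")
  }
  if (k < 0) {
    fp_abort("Negative fringe order; peak ordering or indices are inconsistent.",
             "fp_invalid_input")
  }
  tibble::tibble(k = as.integer(k), k_raw = k_raw, k_residual = residual)
}

#' Cavity length from the first-peak wavelength and its fringe order
#'
#' With the fringe order `k` of the shortest-wavelength peak known, the
#' absolute cavity length follows from the resonance condition:
#' \deqn{d = \frac{(2k+1)\,\lambda_1}{4 n}.}
#'
#' @param lam1_nm First-peak wavelength in nm.
#' @param k Integer fringe order (>= 0).
#' @param n Refractive index of the cavity medium.
#' @return Cavity length in micrometres.
#' @examples
#' cavity_length(1.2e6 / 793, k = 396)  # ~300 um
#' @export
cavity_length <- function(lam1_nm, k, n = 1) {
  check_number(lam1_nm, "lam1_nm", lower = 0, strict_lower = TRUE)
  check_number(k, "k", lower = 0)
  if (k != round(k)) {
    fp_abort("`k` must be an integer fringe order.", "fp_invalid_input")
  }
  check_number(n, "n", lower = 1)
  (2 * k + 1) * lam1_nm / (4 * n) / 1e3
}

#' Demodulate one reflection spectrum to a cavity-length estimate
#'
#' Full single-frame pipeline: [detect_peaks()], fringe order from the
#' first and last detected peaks ([fringe_order()] with `i` = number of
#' peaks), then [cavity_length()]. The `"consensus"` method instead
#' computes the order from every (first, j-th) peak pair and takes the
#' modal `k`, recording how many pairs disagreed — a robustness mode for
#' noisy spectra.
#'
#' @param spectrum An `fp_spectrum` (or plain data frame spectrum).
#' @param method `"first_last"` (default) or `"consensus"`.
#' @param n Refractive index of the cavity medium.
#' @param min_prominence Passed to [detect_peaks()].
#' @param residual_tolerance Passed to [fringe_order()].
#' @return A one-row tibble (class `fp_estimate`) with columns
#'   `timestamp_s`, `channel`, `d_um`, `k`, `opd_um`, `k_residual`,
#'   `n_peaks_used`, `k_disagreement`, `method`.
#' @examples
#' demodulate(fp_spectrum(fp_cavity(d_um = 300)))
#' @export
demodulate <- function(spectrum, method = c("first_last", "consensus"),
                       n = 1, min_prominence = 0.25,
                       residual_tolerance = 0.3) {
  method <- match.arg(method)
  peaks <- detect_peaks(spectrum, min_prominence = min_prominence,
                        min_peaks = 2)
  # edge-flagged peaks may sit on truncated fringes whose interpolated
  # wavelength is biased; skip them whenever enough interior peaks remain
  interior <- peaks[!peaks$edge, , drop = FALSE]
  if (nrow(interior) >= 2) {
    attr(interior, "timestamp_s") <- attr(peaks, "timestamp_s")
    attr(interior, "channel") <- attr(peaks, "channel")
    peaks <- interior
  }
  demodulate_peaks(peaks, method = method, n = n,
                   residual_tolerance = residual_tolerance)
}

#' Demodulate a pre-extracted peak set
#'
#' Same as [demodulate()] but starting from a table of peak wavelengths
#' (e.g. an interrogator export) rather than a full spectrum.
#'
#' @param peaks A data frame with ascending `wavelength_nm` (one row per
#'   interference maximum); at least 2 rows.
#' @inheritParams demodulate
#' @return A one-row tibble as in [demodulate()].
#' @export
demodulate_peaks <- function(peaks, method = c("first_last", "consensus"),
                             n = 1, residual_tolerance = 0.3) {
  method <- match.arg(method)
  if (!is.data.frame(peaks) || !"wavelength_nm" %in% names(peaks)) {
    fp_abort("`peaks` must be a data frame with a `wavelength_nm` column.",
             "fp_invalid_input")
  }
  lam <- sort(peaks$wavelength_nm)
  m <- length(lam)
  if (m < 2) {
    fp_abort("At least 2 peaks are required for fringe-order demodulation.",
             "fp_insufficient_fringes")
  }
  disagreement <- 0L
  if (method == "first_last") {
    fo <- fringe_order(lam[1], lam[m], i = m,
                       residual_tolerance = residual_tolerance)
  } else {
    # every (first, j-th) pair votes for an order; individual pairs may
    # be noisy (close pairs have high order sensitivity), so voting uses
    # the maximal tolerance and ambiguity is judged on the majority
    orders <- purrr::map(2:m, function(j) {
      fringe_order(lam[1], lam[j], i = j, residual_tolerance = 0.5)
    })
    ks <- purrr::map_int(orders, "k")
    tab <- sort(table(ks), decreasing = TRUE)
    k_mode <- as.integer(names(tab)[1])
    disagreement <- sum(ks != k_mode)
    if (tab[1] <= (m - 1) / 2) {
      fp_abort(sprintf(
        "Ambiguous fringe order: modal order %d carries only %d of %d pair votes.",
        k_mode, tab[1], m - 1L), "fp_ambiguous_order")
    }
    sel <- which(ks == k_mode)
    best <- sel[which.min(purrr::map_dbl(orders[sel], "k_residual"))]
    fo <- orders[[best]]
  }
  d_um <- cavity_length(lam[1], fo$k, n = n)
  out <- tibble::tibble(
    timestamp_s = attr(peaks, "timestamp_s") %||% NA_real_,
    channel = attr(peaks, "channel") %||% NA_character_,
    d_um = d_um,
    k = fo$k,
    opd_um = 2 * n * d_um,
    k_residual = fo$k_residual,
    n_peaks_used = m,
    k_disagreement = disagreement,
    method = method
  )
  class(out) <- c("fp_estimate", class(out))
  out
}

#' Track cavity length over a sequence of spectrum frames
#'
#' Demodulates each frame independently. Frames that fail (too few
#' fringes, ambiguous order, malformed data) are kept as flagged gaps
#' with `d_um = NA` — never interpolated — so a single corrupted frame
#' does not contaminate its neighbours. An advisory continuity check
#' flags frame-to-frame jumps larger than `jump_threshold_um` as
#' possible fringe-order slips; genuine activation steps (~130 um) stay
#' below the default threshold.
#'
#' @param frames A list of `fp_spectrum` frames (one channel,
#'   time-ordered), or an `fp_experiment` from [simulate_experiment()]
#'   (all channels are tracked and row-bound).
#' @param jump_threshold_um Advisory continuity threshold in um
#'   (default 200); `Inf` disables the check.
#' @inheritParams demodulate
#' @return A tibble (class `fp_series`) with columns `timestamp_s`,
#'   `channel`, `d_um`, `k`, `flag` (`"ok"`, `"suspect_jump"`, or
#'   `"failed:<error class>"`).
#' @examples
#' cav <- fp_cavity(d_um = 300)
#' frames <- lapply(0:2, function(t)
#'   fp_spectrum(cav, timestamp_s = t, channel = "ch1"))
#' track(frames)
#' @export
track <- function(frames, method = c("first_last", "consensus"), n = 1,
                  min_prominence = 0.25, residual_tolerance = 0.3,
                  jump_threshold_um = 200) {
  method <- match.arg(method)
  if (inherits(frames, "fp_experiment")) {
    out <- purrr::map(frames$frames, track, method = method, n = n,
                      min_prominence = min_prominence,
                      residual_tolerance = residual_tolerance,
                      jump_threshold_um = jump_threshold_um)
    out <- dplyr::bind_rows(out)
    class(out) <- c("fp_series", class(out))
    return(out)
  }
  if (!is.list(frames) || length(frames) == 0) {
    fp_abort("`frames` must be a non-empty list of spectra.",
             "fp_invalid_input")
  }
  rows <- purrr::imap(frames, function(fr, idx) {
    est <- tryCatch(
      demodulate(fr, method = method, n = n,
                 min_prominence = min_prominence,
                 residual_tolerance = residual_tolerance),
      error = function(e) {
        tibble::tibble(
          timestamp_s = attr(fr, "timestamp_s") %||% NA_real_,
          channel = attr(fr, "channel") %||% NA_character_,
          d_um = NA_real_, k = NA_integer_, opd_um = NA_real_,
          k_residual = NA_real_, n_peaks_used = NA_integer_,
          k_disagreement = NA_integer_, method = method,
          .fail = class(e)[1]
        )
      })
    est
  })
  out <- dplyr::bind_rows(rows)
  if (!".fail" %in% names(out)) out$.fail <- NA_character_
  out$flag <- ifelse(is.na(out$d_um),
                     paste0("failed:", dplyr::coalesce(out$.fail,
                                                       "demodulation")),
                     "ok")
  out$.fail <- NULL
  if (all(is.na(out$timestamp_s))) {
    out$timestamp_s <- seq_len(nrow(out)) - 1
  }
  out <- dplyr::arrange(out, .data$timestamp_s)
  if (is.finite(jump_threshold_um)) {
    d <- out$d_um
    jump <- c(FALSE, abs(diff(d)) > jump_threshold_um)
    jump[is.na(jump)] <- FALSE
    out$flag[jump & out$flag == "ok"] <- "suspect_jump"
  }
  out <- dplyr::select(out, "timestamp_s", "channel", "d_um", "k", "flag",
                       dplyr::everything())
  class(out) <- c("fp_series", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
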