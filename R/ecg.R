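#' Synthetic single-lead ECG and interval measurement
#'
#' The case reports behind the packaged cohort measured QRS and QT from
#' admission ECGs. This module reconstructs that measurement step at desk
#' scale: a minimal sum-of-Gaussians beat model generates waveforms whose true
#' intervals are known, and a derivative-threshold / tangent-method
#' delineator measures them back. The beat template is deliberately minimal —
#' its purpose is testing the measurement contract, not physiological realism.
#'
#' @name ecg
#' @keywords internal
NULL

# template geometry, fractions of the QRS duration unless stated; the Q and S
# bump placement compensates the threshold-crossing bias of the delineator so
# the detected onset/offset sit at the nominal QRS bounds
ecg_template <- list(
  p_offset_s = 0.140,  # P centre ahead of QRS onset
  p_sigma_s  = 0.025,
  p_amp      = 0.10,
  q_frac     = 0.15,   # Q centre into the QRS
  qs_sigma   = 1 / 18, # Q and S width
  q_amp      = -0.12,
  r_sigma    = 1 / 7,
  r_amp      = 1.0,
  s_frac     = 0.85,   # S centre into the QRS
  s_amp      = -0.18,
  t_sigma_s  = 0.040,
  t_amp      = 0.30,
  slope_frac = 0.05,   # delineation: fraction of max |dV/dt| within the beat
  hold_s     = 0.016   # delineation: quiet period closing a QRS bound
)

gauss_bump <- function(t, centre, sigma, amp) {
  amp * exp(-((t - centre)^2) / (2 * sigma^2))
}

#' Synthesize a single-lead ECG waveform
#'
#' Builds a beat template from Gaussian P, Q, R, S and T bumps, placed so that
#' the QRS onset-to-offset span equals `qrs_ms` and the onset-to-T-end span
#' (tangent convention: the tangent at the steepest T downslope crosses
#' baseline two T-widths after the T centre) equals `qt_ms` by construction.
#' Beats repeat at RR = 60 / `hr_bpm`; Gaussian noise with SD `noise_sd`
#' (in units of the R amplitude) is added on top. Deterministic for a fixed
#' `seed`.
#'
#' @param hr_bpm Heart rate, beats/min, in \[20, 250\].
#' @param qrs_ms QRS duration, ms, in \[40, 300\].
#' @param qt_ms QT interval, ms, in \[200, 800\]; must exceed `qrs_ms` by at
#'   least 150 ms so the T wave is separated from the QRS, and must not exceed
#'   75% of the RR interval so the T wave ends before the next beat.
#' @param fs Sampling rate, Hz, >= 250 (default 500).
#' @param noise_sd Additive Gaussian noise SD relative to the R amplitude.
#' @param seed Integer seed for the noise, or `NULL`.
#' @param n_beats Number of beats (default 8; at least 5).
#' @return An `ecg_waveform` object: `time_s`, `voltage`, `fs`, and
#'   `true_intervals` (one-row tibble of the generating values).
#' @examples
#' wave <- synthesize_ecg(75, 100, 400)
#' wave$true_intervals
#' @export
synthesize_ecg <- function(hr_bpm, qrs_ms, qt_ms, fs = 500, noise_sd = 0,
                           seed = NULL, n_beats = 8) {
  if (hr_bpm < 20 || hr_bpm > 250) {
    qrsqtc_abort("hr_bpm must be in [20, 250]", "qrsqtc_domain_error")
  }
  if (qrs_ms < 40 || qrs_ms > 300) {
    qrsqtc_abort("qrs_ms must be in [40, 300]", "qrsqtc_domain_error")
  }
  if (qt_ms < 200 || qt_ms > 800) {
    qrsqtc_abort("qt_ms must be in [200, 800]", "qrsqtc_domain_error")
  }
  if (qrs_ms >= qt_ms) {
    qrsqtc_abort("qrs_ms must be strictly less than qt_ms", "qrsqtc_domain_error")
  }
  if (qt_ms - qrs_ms < 150) {
    qrsqtc_abort("qt_ms must exceed qrs_ms by at least 150 ms for a separable T wave",
                 "qrsqtc_domain_error")
  }
  if (qt_ms > 0.75 * 60000 / hr_bpm) {
    qrsqtc_abort("qt_ms must not exceed 75% of the RR interval at this heart rate",
                 "qrsqtc_domain_error")
  }
  if (fs < 250) {
    qrsqtc_abort("fs must be at least 250 Hz", "qrsqtc_domain_error")
  }
  if (n_beats < 5) {
    qrsqtc_abort("n_beats must be at least 5", "qrsqtc_domain_error")
  }
  tpl <- ecg_template
  rr <- 60 / hr_bpm
  qrs <- qrs_ms / 1000
  qt <- qt_ms / 1000
  lead_in <- 0.4
  duration <- lead_in + n_beats * rr + 0.4
  time_s <- seq(0, duration, by = 1 / fs)
  v <- numeric(length(time_s))
  onsets <- lead_in + (seq_len(n_beats) - 1) * rr
  for (o in onsets) {
    v <- v +
      gauss_bump(time_s, o - tpl$p_offset_s, tpl$p_sigma_s, tpl$p_amp) +
      gauss_bump(time_s, o + tpl$q_frac * qrs, tpl$qs_sigma * qrs, tpl$q_amp) +
      gauss_bump(time_s, o + 0.5 * qrs, tpl$r_sigma * qrs, tpl$r_amp) +
      gauss_bump(time_s, o + tpl$s_frac * qrs, tpl$qs_sigma * qrs, tpl$s_amp) +
      gauss_bump(time_s, o + qt - 2 * tpl$t_sigma_s, tpl$t_sigma_s, tpl$t_amp)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  structure(
    list(
      time_s = time_s,
      voltage = v,
      fs = fs,
      true_intervals = tibble::tibble(qrs_ms = qrs_ms, qt_ms = qt_ms,
                                      hr_bpm = hr_bpm)
    ),
    class = "ecg_waveform"
  )
}

#' @export
print.ecg_waveform <- function(x, ...) {
  cat(sprintf("ecg_waveform: %d samples at %g Hz (%.1f s)\n",
              length(x$voltage), x$fs, max(x$time_s)))
  if (!is.null(x$true_intervals)) {
    ti <- x$true_intervals
    cat(sprintf("  generating intervals: QRS %g ms, QT %g ms, HR %g bpm\n",
                ti$qrs_ms, ti$qt_ms, ti$hr_bpm))
  }
  invisible(x)
}

#' Write / read a waveform as two-column CSV
#'
#' Plain-text waveform interchange: columns `time_s`, `voltage`. The sampling
#' rate is recovered from the time column on reading; `true_intervals` is not
#' serialised (measured files have no ground truth).
#'
#' @param waveform An `ecg_waveform`.
#' @param path CSV file path.
#' @return `read_ecg_csv()` returns an `ecg_waveform`; `write_ecg_csv()`
#'   returns `path` invisibly.
#' @export
write_ecg_csv <- function(waveform, path) {
  readr::write_csv(tibble::tibble(time_s = waveform$time_s,
                                  voltage = waveform$voltage), path)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), voltage = readr::col_double()
  ), progress = FALSE)
  fs <- 1 / median(diff(x$time_s))
  structure(
    list(time_s = x$time_s, voltage = x$voltage, fs = fs,
         true_intervals = NULL),
    class = "ecg_waveform"
  )
}

# 5-point binomial smoother; keeps endpoints by padding
smooth_signal <- function(x) {
  k <- c(1, 4, 6, 4, 1) / 16
  n <- length(x)
  xp <- c(rep(x[1], 2), x, rep(x[n], 2))
  as.numeric(stats::filter(xp, k, sides = 2))[3:(n + 2)]
}

#' Delineate an ECG waveform
#'
#' Measures per-beat QRS onset/offset and T-end, and the median intervals
#' across beats, using standard manual-measurement conventions:
#' * R peaks: local maxima above half the signal maximum; heart rate from the
#'   median RR.
#' * QRS bounds: the first derivative exceeds 5% of its within-beat maximum;
#'   a bound is closed by a quiet run of at least 16 ms below that threshold.
#' * T-end: the tangent at the steepest T-wave downslope extrapolated to the
#'   isoelectric baseline.
#'
#' All thresholds are relative, so delineation is invariant to uniform
#' amplitude scaling. The first and last beats are dropped as edge-incomplete;
#' at least 3 detectable beats are required.
#'
#' @param waveform An `ecg_waveform`.
#' @return A `delineation_result`: `beats` (per-beat tibble with onset,
#'   offset and T-end times in seconds plus per-beat intervals), and median
#'   `qrs_ms`, `qt_ms`, `hr_bpm`.
#' @examples
#' res <- delineate(synthesize_ecg(75, 100, 400))
#' c(res$qrs_ms, res$qt_ms, res$hr_bpm)
#' @export
delineate <- function(waveform) {
  x <- waveform$voltage
  fs <- waveform$fs
  if (length(x) < fs || !any(is.finite(x)) || diff(range(x)) < 1e-9) {
    qrsqtc_abort("no beats detected", "qrsqtc_signal_error")
  }
  x <- smooth_signal(smooth_signal(x - median(x)))
  tpl <- ecg_template

  # R peaks: maxima of runs above half the global maximum
  above <- x > 0.5 * max(x)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peak_idx <- purrr::map_int(which(r$values), function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(x[seg])]
  })
  if (length(peak_idx) < 3) {
    qrsqtc_abort("no beats detected", "qrsqtc_signal_error")
  }
  rr_samp <- median(diff(peak_idx))
  hr_bpm <- 60 * fs / rr_samp

  # central difference over +/- 3 samples: slope estimate robust to residual
  # high-frequency noise without displacing the threshold crossings
  n <- length(x)
  k <- 3L
  dx <- (x[pmin(seq_len(n) + k, n)] - x[pmax(seq_len(n) - k, 1L)]) *
    fs / (2 * k)
  hold <- max(2L, as.integer(round(tpl$hold_s * fs)))
  below_cum <- function(below) cumsum(as.integer(below))

  beats <- purrr::map_dfr(peak_idx[-c(1, length(peak_idx))], function(pk) {
    lo <- max(1L, pk - as.integer(round(0.35 * rr_samp)))
    hi <- min(length(x), pk + as.integer(round(0.5 * rr_samp)))
    qrs_lo <- max(lo, pk - as.integer(round(0.2 * fs)))
    qrs_hi <- min(hi, pk + as.integer(round(0.2 * fs)))
    # threshold: fraction of the within-beat maximum slope, floored above the
    # beat's noise slope level (the median |dV/dt| is noise-dominated because
    # most of a beat is isoelectric)
    thr <- max(tpl$slope_frac * max(abs(dx[qrs_lo:qrs_hi])),
               5 * quantile(abs(dx[lo:hi]), 0.25, names = FALSE))
    below <- abs(dx) < thr
    cs <- c(0, below_cum(below))
    quiet_ending_at <- function(j) (cs[j + 1] - cs[j + 1 - hold]) == hold
    # onset: last sample before the peak preceded by a quiet run
    onset <- NA_integer_
    for (j in seq(pk, lo + hold, by = -1L)) {
      if (quiet_ending_at(j)) { onset <- j; break }
    }
    # offset: first sample after the peak followed by a quiet run
    offset <- NA_integer_
    for (j in seq(pk, hi - hold, by = 1L)) {
      if ((cs[min(j + hold, length(cs))] - cs[j]) == hold) { offset <- j; break }
    }
    if (is.na(onset) || is.na(offset)) {
      return(tibble::tibble())
    }
    # T wave: peak then steepest downslope, tangent to baseline; the search
    # stops 250 ms short of the next beat to keep clear of its P wave
    hi_t <- min(length(x), pk + as.integer(round(rr_samp)) -
                  as.integer(round(0.25 * fs)))
    t_lo <- min(offset + as.integer(round(0.02 * fs)), hi_t - 1L)
    t_region <- t_lo:hi_t
    t_peak <- t_region[which.max(x[t_region])]
    down_region <- t_peak:hi_t
    i_star <- down_region[which.min(dx[down_region])]
    if (dx[i_star] >= 0) {
      return(tibble::tibble())
    }
    t_end_s <- waveform$time_s[i_star] - x[i_star] / dx[i_star]
    onset_s <- waveform$time_s[onset]
    offset_s <- waveform$time_s[offset]
    tibble::tibble(
      onset_s = onset_s, offset_s = offset_s, t_end_s = t_end_s,
      qrs_ms = (offset_s - onset_s) * 1000,
      qt_ms = (t_end_s - onset_s) * 1000
    )
  })
  if (nrow(beats) < 1) {
    qrsqtc_abort("no beats delineated", "qrsqtc_signal_error")
  }
  beats <- dplyr::mutate(beats, beat = dplyr::row_number(), .before = 1)
  structure(
    list(
      beats = beats,
      qrs_ms = median(beats$qrs_ms),
      qt_ms = median(beats$qt_ms),
      hr_bpm = hr_bpm
    ),
    class = "delineation_result"
  )
}

#' @export
print.delineation_result <- function(x, ...) {
  cat(sprintf("delineation over %d beats: QRS %.1f ms, QT %.1f ms, HR %.1f bpm\n",
              nrow(x$beats), x$qrs_ms, x$qt_ms, x$hr_bpm))
  invisible(x)
}

#' Measure ECG intervals from a waveform
#'
#' Delineates the waveform, applies the chosen heart-rate correction to the
#' measured QT, and assembles the interval record including the QRS/QTc
#' ratio — the full measurement path a case report would have followed from an
#' attached ECG.
#'
#' @param waveform An `ecg_waveform`.
#' @param formula Correction formula, see [correct_qt()].
#' @param ratio_digits Ratio rounding, see [qrs_qtc_ratio()]; `NULL` (full
#'   precision) by default.
#' @return One-row tibble: `qrs_ms`, `qt_ms`, `qtc_ms`, `hr_bpm`, `ratio`.
#' @examples
#' measure_case(synthesize_ecg(60, 90, 446))
#' @export
measure_case <- function(waveform, formula = "bazett", ratio_digits = NULL) {
  d <- delineate(waveform)
  qtc <- correct_qt(d$qt_ms, rr_from_hr(d$hr_bpm), formula)
  tibble::tibble(
    qrs_ms = d$qrs_ms,
    qt_ms = d$qt_ms,
    qtc_ms = qtc,
    hr_bpm = d$hr_bpm,
    ratio = qrs_qtc_ratio(d$qrs_ms, qtc, digits = ratio_digits)
  )
}
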