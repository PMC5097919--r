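#' Low-pass filter an MVC force trace
#'
#' Zero-phase 4th-order Butterworth, 15 Hz cutoff by default (the standard
#' choice after residual analysis of knee-extension force signals).
#'
#' @param trace data frame `t, force, stim` (stim: 0 none, 1 relaxed
#'   doublet, 2 superimposed doublet).
#' @param order filter order.
#' @param cutoff_hz cutoff frequency in Hz.
#' @return The trace with `force` filtered.
#' @export
filter_force <- function(trace, order = 4L, cutoff_hz = 15) {
  fs <- 1 / stats::median(diff(trace$t))
  trace$force <- butter_zerophase(trace$force, fs, cutoff_hz, order)
  trace
}

stim_times <- function(trace) {
  list(relaxed = trace$t[trace$stim == 1L],
       superimposed = trace$t[trace$stim == 2L])
}

#' Locate the MVC force plateau and peak force
#'
#' F_PEAK is the maximum over the trace of the 100-ms moving average of
#' force, computed only over windows free of stimulation artifact: any
#' window overlapping `[stim, stim + artifact_ms]` after a superimposed
#' doublet is excluded, so the evoked twitch cannot inflate the peak.
#'
#' @param trace filtered force trace (`t, force, stim`).
#' @param window_ms averaging window in milliseconds.
#' @param artifact_ms masked interval after each superimposed stimulation.
#' @param pre_ms masked interval before each superimposed stimulation
#'   (zero-phase filtering spreads the evoked response backwards in time).
#' @return List with `F_PEAK` (N) and `window` (`c(start, end)` seconds of
#'   the peak window).
#' @export
detect_plateau <- function(trace, window_ms = 100, artifact_ms = 300,
                           pre_ms = 100) {
  fs <- 1 / stats::median(diff(trace$t))
  w <- max(2L, round(window_ms / 1000 * fs))
  n <- nrow(trace)
  if (w > n) stop_config("trace shorter than the averaging window")
  masked <- rep(FALSE, n)
  for (s in stim_times(trace)$superimposed) {
    masked <- masked | (trace$t >= s - pre_ms / 1000 &
                          trace$t <= s + artifact_ms / 1000)
  }
  rm_ <- rolling_mean(trace$force, w)
  # a window is valid iff it contains no masked sample
  bad <- rolling_mean(as.numeric(masked), w) > 0
  if (all(bad)) stop_config("no %g-ms window free of stimulation artifact",
                            window_ms)
  rm_[bad] <- -Inf
  i <- which.max(rm_)
  list(F_PEAK = rm_[i],
       window = c(start = trace$t[i], end = trace$t[i + w - 1L]))
}

#' Amplitude of an evoked doublet twitch
#'
#' For a doublet on relaxed muscle (control twitch, TC) or superimposed on
#' an MVC (superimposed twitch, TS): peak force within
#' `(stim, stim + artifact_ms]` minus the pre-stimulus baseline (mean of the
#' `baseline_ms` before the stimulation).
#'
#' @param trace force trace (`t, force, stim`).
#' @param stim_time stimulation time in seconds.
#' @param artifact_ms search window after the stimulation (ms).
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return List with `amplitude` (N) and `baseline` (N, the force level at
#'   stimulation).
#' @export
twitch_amplitude <- function(trace, stim_time, artifact_ms = 300,
                             baseline_ms = 50) {
  t <- trace$t
  if (stim_time < min(t) + baseline_ms / 1000 ||
      stim_time + artifact_ms / 1000 > max(t)) {
    stop_config("twitch window around t = %g s exceeds the trace", stim_time)
  }
  base <- mean(trace$force[t >= stim_time - baseline_ms / 1000 &
                             t < stim_time])
  pk <- max(trace$force[t > stim_time & t <= stim_time + artifact_ms / 1000])
  list(amplitude = max(pk - base, 0), baseline = base)
}

#' Voluntary activation by twitch interpolation
#'
#' Uncorrected form: `VA = (1 - TS / TC) * 100`. When the superimposed
#' doublet fell slightly off the force plateau, the corrected form scales
#' the superimposed twitch by the ratio of the force level at stimulation to
#' the peak force: `VA = (1 - TS * (F_stim / F_PEAK) / TC) * 100`.
#'
#' @param TS superimposed twitch amplitude (N).
#' @param TC control twitch amplitude (N, > 0).
#' @param force_at_stim voluntary force level at stimulation (N); needed for
#'   the corrected form.
#' @param F_PEAK peak MVC force (N); needed for the corrected form.
#' @param on_plateau logical: was the stimulation delivered on the force
#'   plateau? `TRUE` selects the uncorrected formula.
#' @return Object of class `twitch_result`: list with `VA` (percent), `TS`,
#'   `TC`, `corrected` flag and `out_of_range` flag (VA outside `[0, 100]`
#'   is reported as-is, only flagged).
#' @export
voluntary_activation <- function(TS, TC, force_at_stim = NULL, F_PEAK = NULL,
                                 on_plateau = TRUE) {
  if (TC <= 0) stop_config("TC must be positive for VA computation")
  corrected <- !on_plateau
  if (corrected) {
    if (is.null(force_at_stim) || is.null(F_PEAK) || F_PEAK <= 0) {
      stop_config("corrected VA needs force_at_stim and positive F_PEAK")
    }
    va <- (1 - TS * (force_at_stim / F_PEAK) / TC) * 100
  } else {
    va <- (1 - TS / TC) * 100
  }
  structure(list(VA = va, TS = TS, TC = TC, corrected = corrected,
                 out_of_range = va < 0 || va > 100),
            class = "twitch_result")
}

#' @export
print.twitch_result <- function(x, ...) {
  cat(sprintf("Voluntary activation: %.1f%% (%s formula)%s\n", x$VA,
              if (x$corrected) "corrected" else "uncorrected",
              if (x$out_of_range) " [outside 0-100, flagged]" else ""))
  cat(sprintf("  TS = %.2f N, TC = %.2f N\n", x$TS, x$TC))
  invisible(x)
}

#' Full twitch-interpolation analysis of one MVC trace
#'
#' Filters the force trace, locates the plateau and F_PEAK, measures the
#' control and superimposed doublet amplitudes, decides plateau membership
#' of the superimposed stimulation (force at stimulation at or above
#' `plateau_frac` of F_PEAK) and computes VA with the appropriate formula.
#' Twitch amplitudes are measured on the filtered trace: the zero-phase
#' filter changes both evoked peaks by the same small factor, which cancels
#' exactly in the TS/TC ratio, while suppressing the noise-peak bias a raw
#' maximum would pick up.
#'
#' @param trace raw force trace (`t, force, stim`).
#' @param artifact_ms twitch search / masking window (ms).
#' @param plateau_frac fraction of F_PEAK above which the stimulation counts
#'   as on-plateau.
#' @param filter_order,cutoff_hz force filter settings.
#' @return List with `F_PEAK`, `TC`, `TS`, `force_at_stim`, `va` (a
#'   `twitch_result`) and the plateau window.
#' @export
analyze_mvc <- function(trace, artifact_ms = 300, plateau_frac = 0.95,
                        filter_order = 4L, cutoff_hz = 15) {
  st <- stim_times(trace)
  if (!length(st$relaxed) || !length(st$superimposed)) {
    stop_config("trace needs one relaxed and one superimposed stimulation")
  }
  filt <- filter_force(trace, filter_order, cutoff_hz)
  plat <- detect_plateau(filt, artifact_ms = artifact_ms)
  tc <- twitch_amplitude(filt, st$relaxed[1], artifact_ms)
  ts <- twitch_amplitude(filt, st$superimposed[1], artifact_ms)
  on_plat <- ts$baseline >= plateau_frac * plat$F_PEAK
  va <- voluntary_activation(ts$amplitude, tc$amplitude,
                             force_at_stim = ts$baseline,
                             F_PEAK = plat$F_PEAK, on_plateau = on_plat)
  list(F_PEAK = plat$F_PEAK, TC = tc$amplitude, TS = ts$amplitude,
       force_at_stim = ts$baseline, va = va, plateau = plat$window)
}

#' Band-pass filter an EMG trace
#'
#' Zero-phase Butterworth band-pass, 20-500 Hz by default.
#'
#' @param trace data frame `t, mv, stim`.
#' @param band length-2 pass band in Hz.
#' @param order order of each filter section.
#' @return The trace with `mv` filtered.
#' @export
bandpass_emg <- function(trace, band = c(20, 500), order = 2L) {
  fs <- 1 / stats::median(diff(trace$t))
  trace$mv <- butter_zerophase(trace$mv, fs, band, order, type = "pass")
  trace
}

#' EMG RMS over the force-plateau window
#'
#' Root mean square of the band-passed EMG over a window of `span_s` seconds
#' centred on the force-plateau window identified in the force trace.
#'
#' @param emg band-passed EMG trace (`t, mv`).
#' @param plateau_window length-2 `c(start, end)` seconds from
#'   [detect_plateau()], in the EMG timebase.
#' @param span_s analysis span in seconds.
#' @return RMS in mV.
#' @export
rms_over_plateau <- function(emg, plateau_window, span_s = 1.0) {
  centre <- mean(plateau_window)
  sel <- emg$t >= centre - span_s / 2 & emg$t < centre + span_s / 2
  if (!any(sel)) stop_config("plateau window unavailable in the EMG timebase")
  sqrt(mean(emg$mv[sel]^2))
}

#' M-wave amplitude and RMS / M-wave ratio
#'
#' Peak-to-peak amplitude of the evoked compound muscle action potential
#' within `window_ms` after the marked supramaximal stimulation, on the
#' band-passed signal. The amplitude is flagged unreliable when it is below
#' three times the background noise SD.
#'
#' @param emg band-passed EMG trace (`t, mv, stim`; stim = 1 marks the
#'   stimulation).
#' @param window_ms search window after the marker (ms).
#' @param rms optional voluntary RMS (mV); when given, the RMS/MW ratio is
#'   returned too.
#' @return List with `MWave` (mV), `reliable` flag, and `RMS_MW` (or `NA`
#'   when no RMS is supplied).
#' @export
mwave_amplitude <- function(emg, window_ms = 50, rms = NULL) {
  mk <- emg$t[emg$stim == 1L]
  if (!length(mk)) {
    return(list(MWave = NA_real_, reliable = FALSE, RMS_MW = NA_real_))
  }
  sel <- emg$t > mk[1] & emg$t <= mk[1] + window_ms / 1000
  if (!any(sel)) stop_config("M-wave window exceeds the trace")
  amp <- max(emg$mv[sel]) - min(emg$mv[sel])
  bg <- emg$mv[!sel & emg$t < mk[1]]
  reliable <- length(bg) == 0 || amp >= 3 * stats::sd(bg)
  list(MWave = amp, reliable = reliable,
       RMS_MW = if (is.null(rms)) NA_real_ else rms / amp)
}
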