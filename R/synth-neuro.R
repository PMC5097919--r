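#' Configuration for the MVC force-trace simulator
#'
#' Builds a knee-extension force trace: baseline at zero, a half-cosine ramp
#' to a sustained plateau at `mvc_force`, a ramp back down, plus doublet
#' twitch transients at the stimulation times. The superimposed twitch
#' amplitude is constructed as `tc_amp * (1 - va_true / 100)`, so the true
#' voluntary activation is recoverable by the twitch-interpolation formula.
#'
#' @param mvc_force true plateau force (N).
#' @param va_true true voluntary activation, percent in (0, 100].
#' @param tc_amp true control-doublet amplitude on relaxed muscle (N).
#' @param twitch_tau_rise,twitch_tau_decay twitch time constants (s); the
#'   difference-of-exponentials waveform is normalised so its peak equals the
#'   configured amplitude.
#' @param ramp_s seconds from rest to plateau (and back).
#' @param mvc_start_s time the ramp-up begins.
#' @param plateau_s plateau duration (s).
#' @param stim_relaxed_s doublet time on relaxed muscle (voluntary force 0).
#' @param stim_mvc_s doublet time during the MVC plateau.
#' @param noise_sd additive Gaussian force noise SD (N).
#' @param sample_rate Hz.
#' @param duration_s total trace duration (s).
#' @param seed integer seed.
#' @return An `mvc_sim_config` list.
#' @export
mvc_sim_config <- function(mvc_force = 840.2, va_true = 85.9,
                           tc_amp = 288.6,
                           twitch_tau_rise = 0.03, twitch_tau_decay = 0.12,
                           ramp_s = 1.0, mvc_start_s = 6.0, plateau_s = 4.0,
                           stim_relaxed_s = 1.0, stim_mvc_s = 9.5,
                           noise_sd = 2.0, sample_rate = 1000,
                           duration_s = 13.0, seed = 1L) {
  if (va_true <= 0 || va_true > 100) {
    stop_config("va_true must lie in (0, 100], got %g", va_true)
  }
  if (mvc_force <= 0 || tc_amp <= 0) stop_config("forces must be positive")
  if (noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (stim_relaxed_s >= mvc_start_s) {
    stop_config("relaxed doublet must precede the MVC ramp")
  }
  plateau_start <- mvc_start_s + ramp_s
  plateau_end <- plateau_start + plateau_s
  if (stim_mvc_s <= plateau_start || stim_mvc_s >= plateau_end) {
    stop_config("superimposed doublet must fall inside the plateau")
  }
  if (duration_s <= plateau_end + ramp_s) {
    stop_config("duration_s too short for the MVC profile")
  }
  structure(list(mvc_force = mvc_force, va_true = va_true, tc_amp = tc_amp,
                 twitch_tau_rise = twitch_tau_rise,
                 twitch_tau_decay = twitch_tau_decay,
                 ramp_s = ramp_s, mvc_start_s = mvc_start_s,
                 plateau_s = plateau_s, stim_relaxed_s = stim_relaxed_s,
                 stim_mvc_s = stim_mvc_s, noise_sd = noise_sd,
                 sample_rate = sample_rate, duration_s = duration_s,
                 seed = seed),
            class = "mvc_sim_config")
}

# Difference-of-exponentials twitch, normalised to unit peak.
twitch_waveform <- function(t, tau_rise, tau_decay) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  w <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  w / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

#' Simulate an MVC force trace with doublet stimulation
#'
#' @param cfg an [mvc_sim_config()].
#' @return List with `trace` (data frame `t, force, stim` where stim codes
#'   0 none / 1 relaxed / 2 superimposed, matching the `force.csv` schema)
#'   and `truth` (`F_PEAK`, `TC`, `TS`, `VA`, plateau window).
#' @export
gen_mvc_trace <- function(cfg) {
  stopifnot(inherits(cfg, "mvc_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    t <- seq(0, cfg$duration_s, by = 1 / fs)
    p_start <- cfg$mvc_start_s + cfg$ramp_s
    p_end <- p_start + cfg$plateau_s
    voluntary <- numeric(length(t))
    up <- t >= cfg$mvc_start_s & t < p_start
    voluntary[up] <- cfg$mvc_force *
      0.5 * (1 - cos(pi * (t[up] - cfg$mvc_start_s) / cfg$ramp_s))
    voluntary[t >= p_start & t <= p_end] <- cfg$mvc_force
    dn <- t > p_end & t < p_end + cfg$ramp_s
    voluntary[dn] <- cfg$mvc_force *
      0.5 * (1 + cos(pi * (t[dn] - p_end) / cfg$ramp_s))

    ts_amp <- cfg$tc_amp * (1 - cfg$va_true / 100)
    force <- voluntary +
      cfg$tc_amp * twitch_waveform(t - cfg$stim_relaxed_s,
                                   cfg$twitch_tau_rise, cfg$twitch_tau_decay) +
      ts_amp * twitch_waveform(t - cfg$stim_mvc_s,
                               cfg$twitch_tau_rise, cfg$twitch_tau_decay)
    if (cfg$noise_sd > 0) {
      force <- force + stats::rnorm(length(t), 0, cfg$noise_sd)
    }
    stim <- integer(length(t))
    stim[which.min(abs(t - cfg$stim_relaxed_s))] <- 1L
    stim[which.min(abs(t - cfg$stim_mvc_s))] <- 2L
    list(trace = data.frame(t = t, force = force, stim = stim),
         truth = list(F_PEAK = cfg$mvc_force, TC = cfg$tc_amp, TS = ts_amp,
                      VA = cfg$va_true,
                      plateau = c(start = p_start, end = p_end)))
  })
}

#' Configuration for the surface-EMG simulator
#'
#' Band-limited Gaussian interference-pattern noise scaled to a known RMS,
#' plus one biphasic M-wave (a Gaussian-windowed sine cycle) at a marked
#' stimulation time, normalised so its peak-to-peak amplitude is exact.
#'
#' @param rms_true true RMS of the voluntary signal (mV).
#' @param band length-2 acquisition pass band in Hz (what the hardware
#'   band-pass would apply).
#' @param spectrum_band length-2 band in Hz shaping the voluntary
#'   interference pattern; the default 30-350 Hz is where surface-EMG power
#'   actually lives, comfortably inside the acquisition band so downstream
#'   band-passing leaves the RMS essentially unchanged.
#' @param mwave_amp M-wave peak-to-peak amplitude (mV).
#' @param mwave_freq dominant M-wave frequency (Hz); with `mwave_width_s`
#'   this sets the biphasic shape.
#' @param mwave_width_s Gaussian envelope SD of the M-wave (s).
#' @param mwave_time_s stimulation time of the evoked response (s); the
#'   voluntary component is silenced for 50 ms after it so the evoked wave
#'   rides on (near) zero background, as on relaxed muscle.
#' @param sample_rate Hz.
#' @param duration_s trace duration (s).
#' @param seed integer seed.
#' @return An `emg_sim_config` list.
#' @export
emg_sim_config <- function(rms_true = 0.53, band = c(20, 500),
                           spectrum_band = c(30, 350),
                           mwave_amp = 3.75, mwave_freq = 150,
                           mwave_width_s = 0.004, mwave_time_s = NULL,
                           sample_rate = 2000, duration_s = 12,
                           seed = 1L) {
  if (rms_true <= 0) stop_config("rms_true must be positive")
  if (length(band) != 2L || band[1] <= 0 || band[2] >= sample_rate / 2 ||
      band[1] >= band[2]) {
    stop_config("band must lie within (0, Nyquist) with low < high")
  }
  structure(list(rms_true = rms_true, band = band,
                 spectrum_band = spectrum_band, mwave_amp = mwave_amp,
                 mwave_freq = mwave_freq, mwave_width_s = mwave_width_s,
                 mwave_time_s = mwave_time_s, sample_rate = sample_rate,
                 duration_s = duration_s, seed = seed),
            class = "emg_sim_config")
}

# Biphasic wavelet normalised to unit peak-to-peak.
mwave_shape <- function(t, freq, width_s) {
  w <- sin(2 * pi * freq * t) * exp(-((t - 1.5 * width_s)^2) / (2 * width_s^2))
  w[t < 0] <- 0
  w / (max(w) - min(w))
}

#' Simulate a surface-EMG trace with a marked M-wave
#'
#' @param cfg an [emg_sim_config()].
#' @return List with `trace` (data frame `t, mv, stim`; stim = 1 marks the
#'   evoked-response stimulation sample) and `truth` (`RMS`, `MWave`,
#'   `mwave_time_s`).
#' @export
gen_emg_trace <- function(cfg) {
  stopifnot(inherits(cfg, "emg_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    t <- seq(0, cfg$duration_s, by = 1 / fs)
    n <- length(t)
    noise <- stats::rnorm(n)
    noise <- butter_zerophase(noise, fs, cfg$spectrum_band, order = 2L,
                              type = "pass")
    mw_t <- cfg$mwave_time_s %||% (cfg$duration_s / 2)
    evoked_win <- t >= mw_t & t <= mw_t + 0.05
    # scale the voluntary component so its own RMS is exact, then silence it
    # under the evoked response (relaxed muscle at stimulation)
    noise <- noise * cfg$rms_true / sqrt(mean(noise^2))
    noise[evoked_win] <- 0
    mv <- noise + cfg$mwave_amp *
      mwave_shape(t - mw_t, cfg$mwave_freq, cfg$mwave_width_s)
    stim <- integer(n)
    stim[which.min(abs(t - mw_t))] <- 1L
    list(trace = data.frame(t = t, mv = mv, stim = stim),
         truth = list(RMS = cfg$rms_true, MWave = cfg$mwave_amp,
                      mwave_time_s = mw_t))
  })
}
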