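# Synthetic electroporation pulse-train waveforms.
#
# Each train is a burst of rectangular high-voltage pulses across a resistive
# load; with no droop and no noise the energy of one pulse is exactly
# V^2 * tau / R, which anchors the dose-quantification tests.

#' Configuration for the EP pulse waveform generator
#'
#' @param n_trains number of pulse trains.
#' @param pulses_per_train pulses per train (the clinical protocol delivered 8
#'   per electrode pair).
#' @param pulse_us pulse width in microseconds (default 100).
#' @param amplitude_v pulse amplitude in volts; scalar or one value per train.
#' @param load_ohm resistive load defining the current trace.
#' @param waveform_fs_hz sampling rate of the V/I records; must give at least
#'   10 samples per pulse.
#' @param period_us pulse start-to-start period within a train.
#' @param droop_frac fractional exponential droop across each pulse (0 = flat).
#' @param noise_frac relative RMS of multiplicative noise on V and I.
#' @param tumor_id,patient_id identifiers stamped on the records.
#' @param seed RNG seed.
#' @return object of class `ep_sim_config`.
#' @export
ep_sim_config <- function(n_trains = 1L,
                          pulses_per_train = 8L,
                          pulse_us = 100,
                          amplitude_v = 1000,
                          load_ohm = 100,
                          waveform_fs_hz = 1e6,
                          period_us = 1000,
                          droop_frac = 0,
                          noise_frac = 0,
                          tumor_id = "T1",
                          patient_id = "P1",
                          seed = 1L) {
  if (n_trains < 1) cfg_stop("n_trains", "must be >= 1")
  if (pulses_per_train < 1) cfg_stop("pulses_per_train", "must be >= 1")
  if (pulse_us <= 0) cfg_stop("pulse_us", "must be > 0")
  if (any(amplitude_v < 0)) cfg_stop("amplitude_v", "must be >= 0")
  if (!length(amplitude_v) %in% c(1L, n_trains))
    cfg_stop("amplitude_v", "scalar or one value per train")
  if (load_ohm <= 0) cfg_stop("load_ohm", "must be > 0")
  if (waveform_fs_hz < 10 / (pulse_us * 1e-6))
    cfg_stop("waveform_fs_hz", "fewer than 10 samples per pulse")
  if (period_us <= pulse_us) cfg_stop("period_us", "must exceed pulse_us")
  if (droop_frac < 0 || droop_frac >= 1) cfg_stop("droop_frac", "must be in [0, 1)")
  if (noise_frac < 0) cfg_stop("noise_frac", "must be >= 0")
  structure(list(n_trains = as.integer(n_trains),
                 pulses_per_train = as.integer(pulses_per_train),
                 pulse_us = pulse_us, amplitude_v = rep(amplitude_v,
                                                        length.out = n_trains),
                 load_ohm = load_ohm, waveform_fs_hz = waveform_fs_hz,
                 period_us = period_us, droop_frac = droop_frac,
                 noise_frac = noise_frac, tumor_id = tumor_id,
                 patient_id = patient_id, seed = as.integer(seed)),
            class = "ep_sim_config")
}

#' Generate EP pulse-train voltage/current waveforms
#'
#' Pulse edges fall on sample boundaries, so the trapezoidal integral of
#' V*I over one ideal pulse equals V^2 tau / R to machine precision.
#'
#' @param cfg an [ep_sim_config()].
#' @return list of [pulse_train_record()], one per train.
#' @export
generate_ep_waveforms <- function(cfg) {
  stopifnot(inherits(cfg, "ep_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$waveform_fs_hz
    dt <- 1 / fs
    n_pulse <- round(cfg$pulse_us * 1e-6 * fs)       # samples spanning one pulse
    n_period <- round(cfg$period_us * 1e-6 * fs)
    n_rec <- (cfg$pulses_per_train - 1L) * n_period + n_pulse + 2L * n_pulse
    lapply(seq_len(cfg$n_trains), function(tr) {
      v <- numeric(n_rec)
      amp <- cfg$amplitude_v[tr]
      for (p in seq_len(cfg$pulses_per_train)) {
        i0 <- (p - 1L) * n_period + n_pulse %/% 2L + 1L
        idx <- i0:(i0 + n_pulse)                      # edges on sample boundaries
        frac <- seq(0, 1, length.out = length(idx))
        shape <- if (cfg$droop_frac > 0) {
          (1 - cfg$droop_frac)^frac                   # exponential droop
        } else rep(1, length(idx))
        v[idx] <- amp * shape
      }
      i <- v / cfg$load_ohm
      if (cfg$noise_frac > 0 && amp > 0) {
        on <- v > 0
        v[on] <- v[on] * (1 + stats::rnorm(sum(on), 0, cfg$noise_frac))
        i[on] <- i[on] * (1 + stats::rnorm(sum(on), 0, cfg$noise_frac))
      }
      pulse_train_record(time_s = (seq_len(n_rec) - 1) * dt, voltage_v = v,
                         current_a = i, train_id = tr, tumor_id = cfg$tumor_id,
                         patient_id = cfg$patient_id)
    })
  })
}
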