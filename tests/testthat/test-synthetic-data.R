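# Synthetic ECG and EP waveform generators: construction contracts,
# determinism, and statistical properties of the emitted ground truth.

test_that("constant-rate configuration yields the forced beat count and RR", {
  cfg <- ecg_sim_config(duration_s = 300, leads = "II", mean_rr_ms = 800)
  sim <- generate_ecg(cfg)
  tr <- sim$truth
  # ~375 beats fit in 300 s at 800 ms (minus template margins at the edges)
  expect_gt(length(tr$r_times_s), 370)
  expect_lte(length(tr$r_times_s), 375)
  expect_true(all(tr$labels == "N"))
  expect_equal(diff(tr$r_times_s), rep(0.8, length(tr$r_times_s) - 1),
               tolerance = 1e-12)
  expect_equal(length(sim$record$signals$II), 300 * 200)
})

test_that("generator is deterministic for a fixed seed", {
  cfg <- ecg_sim_config(duration_s = 60, leads = c("I", "II"),
                        ectopic_rate = 0.02, noise_uV = 15,
                        rr_jitter_ms = 10, seed = 42)
  a <- generate_ecg(cfg)
  b <- generate_ecg(cfg)
  expect_identical(a$record$signals, b$record$signals)
  expect_identical(a$truth, b$truth)
  # a different seed must change the waveform
  cfg2 <- ecg_sim_config(duration_s = 60, leads = c("I", "II"),
                         ectopic_rate = 0.02, noise_uV = 15,
                         rr_jitter_ms = 10, seed = 43)
  expect_false(identical(generate_ecg(cfg2)$record$signals, a$record$signals))
})

test_that("LF modulation injects the sinusoid's variance into the RR truth", {
  # Var of an a*sin() sampled over many cycles is a^2/2 = 1250 ms^2 at a = 50
  cfg <- ecg_sim_config(duration_s = 300, leads = "II",
                        lf_mod = c(0.1, 50), seed = 9)
  rr_ms <- diff(generate_ecg(cfg)$truth$r_times_s) * 1000
  v <- mean((rr_ms - mean(rr_ms))^2)
  expect_equal(v, 50^2 / 2, tolerance = 0.05)
})

test_that("abnormal-label fraction converges to the configured ectopic rate", {
  cfg <- ecg_sim_config(duration_s = 2400, leads = "II",
                        ectopic_rate = 0.03, seed = 4)
  tr <- generate_ecg(cfg)$truth
  n <- length(tr$labels)
  p_hat <- mean(tr$labels == "A")
  # binomial tolerance: 4 sigma around 0.03 (adjacent-ectopic thinning makes
  # the realized rate slightly conservative, still inside the band)
  expect_lt(abs(p_hat - 0.03), 4 * sqrt(0.03 * 0.97 / n) + 0.03^2 * 2)
})

test_that("ectopic beats are premature with a compensatory pause", {
  cfg <- ecg_sim_config(duration_s = 600, leads = "II",
                        ectopic_rate = 0.03, seed = 21)
  tr <- generate_ecg(cfg)$truth
  ect <- which(tr$labels == "A")
  ect <- ect[ect > 2 & ect < length(tr$labels) - 1]
  expect_gt(length(ect), 5)
  rr_before <- tr$r_times_s[ect] - tr$r_times_s[ect - 1]
  rr_after <- tr$r_times_s[ect + 1] - tr$r_times_s[ect]
  expect_true(all(rr_before <= 0.8 * 0.8 + 1e-9))   # >= 20% premature at 800 ms
  expect_true(all(rr_after > rr_before))            # pause after the ectopic
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(ecg_sim_config(duration_s = -1), "duration_s")
  expect_error(ecg_sim_config(duration_s = 10, ectopic_rate = 1.5), "ectopic_rate")
  expect_error(ecg_sim_config(duration_s = 10, leads = c("II", "XX")), "leads")
  expect_error(ecg_sim_config(duration_s = 10, mean_rr_ms = 60,
                              lf_mod = c(0.1, 40)), "mean_rr_ms")
  expect_error(ecg_sim_config(duration_s = 10, lf_mod = c(0.3, 40)), "lf_mod")
  expect_error(ep_sim_config(pulse_us = 0), "pulse_us")
  expect_error(ep_sim_config(waveform_fs_hz = 1e4), "waveform_fs_hz")
  expect_error(ep_sim_config(droop_frac = 1), "droop_frac")
})

test_that("ideal EP train carries exactly V^2 tau / R per pulse", {
  trains <- generate_ep_waveforms(ep_sim_config(n_trains = 1, amplitude_v = 1000,
                                                load_ohm = 100))
  td <- tumor_dose(trains)
  expect_equal(td$n_pulses, 8)
  expect_equal(td$energy_j, 8.0, tolerance = 1e-12)   # 1 J per pulse
  expect_equal(td$avg_voltage_v, 1000)
  expect_equal(td$avg_current_a, 10)
})

test_that("zero amplitude gives zero energy and current", {
  trains <- generate_ep_waveforms(ep_sim_config(n_trains = 1, amplitude_v = 0))
  expect_true(all(trains[[1]]$voltage_v == 0))
  expect_true(all(trains[[1]]$current_a == 0))
  expect_warning(b <- pulse_boundaries(trains[[1]]), "zero waveform")
  expect_equal(nrow(b), 0)
})

test_that("voltage droop strictly reduces train energy below the ideal", {
  trains <- generate_ep_waveforms(ep_sim_config(n_trains = 1, amplitude_v = 1000,
                                                load_ohm = 100, droop_frac = 0.1))
  td <- tumor_dose(trains)
  expect_equal(td$n_pulses, 8)          # droop stays above the 10% threshold
  expect_lt(td$energy_j, 8.0)
  expect_gt(td$energy_j, 8.0 * (1 - 0.1)^2)   # bounded by full-droop square
})

test_that("EP generator is deterministic and respects per-train amplitudes", {
  cfg <- ep_sim_config(n_trains = 3, amplitude_v = c(1000, 1200, 900),
                       noise_frac = 0.01, seed = 5)
  a <- generate_ep_waveforms(cfg)
  b <- generate_ep_waveforms(cfg)
  expect_identical(a, b)
  peaks <- vapply(a, function(tr) max(tr$voltage_v), numeric(1))
  expect_equal(order(peaks), order(c(1000, 1200, 900)))
})
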