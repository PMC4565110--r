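# Beat detection, classification, ST flagging, lead selection and counting
# conventions, validated against the generator's analytic ground truth.

make_clean_sim <- function(duration_s = 120, seed = 1, ...) {
  generate_ecg(ecg_sim_config(duration_s = duration_s, leads = "II",
                              seed = seed, ...))
}

test_that("detector is exact on a noiseless record (Q, R and T)", {
  sim <- make_clean_sim(120, seed = 6, rr_jitter_ms = 10)
  bs <- detect_beats(sim$record, "II")
  perf <- detector_performance(beat_times(bs), sim$truth$r_times_s)
  expect_equal(perf$sens, 1)
  expect_equal(perf$ppv, 1)
  # Q and T land on the analytic template peaks (within one sample)
  expect_lt(max(abs((bs$q_idx - 1) / 200 - sim$truth$q_times_s)), 1 / 200 + 1e-9)
  expect_lt(max(abs((bs$t_idx - 1) / 200 - sim$truth$t_times_s)), 1 / 200 + 1e-9)
})

test_that("detector keeps sensitivity and PPV above 0.99 at ~20 dB SNR", {
  clean <- make_clean_sim(600, seed = 13, rr_jitter_ms = 10)
  rms <- sqrt(mean(clean$record$signals$II^2))
  noisy <- generate_ecg(ecg_sim_config(duration_s = 600, leads = "II",
                                       rr_jitter_ms = 10, seed = 13,
                                       noise_uV = rms / 10))
  bs <- detect_beats(noisy$record, "II")
  perf <- detector_performance(beat_times(bs), noisy$truth$r_times_s)
  expect_gte(perf$sens, 0.99)
  expect_gte(perf$ppv, 0.99)
})

test_that("short records and flat lines are rejected or flagged", {
  sim <- make_clean_sim(5)
  expect_error(detect_beats(sim$record, "II"), "10 s")
  flat <- ecg_record(list(II = rep(0, 200 * 20)), fs_hz = 200)
  expect_warning(bs <- detect_beats(flat, "II"), "flat-line")
  expect_equal(n_beats(bs), 0)
})

test_that("classifier separates ectopics from normals with high balanced accuracy", {
  sim <- generate_ecg(ecg_sim_config(duration_s = 900, leads = "II",
                                     ectopic_rate = 0.02, rr_jitter_ms = 10,
                                     noise_uV = 15, seed = 31))
  bs <- classify_beats(detect_beats(sim$record, "II"), sim$record)
  tb <- beat_times(bs)
  m <- vapply(sim$truth$r_times_s, function(t) {
    j <- which.min(abs(tb - t)); if (abs(tb[j] - t) < 0.05) j else NA_integer_
  }, integer(1))
  tp <- !is.na(m)
  pred <- bs$labels[m[tp]]; tru <- sim$truth$labels[tp]
  sens <- mean(pred[tru == "A"] == "A")
  spec <- mean(pred[tru == "N"] == "N")
  expect_gte((sens + spec) / 2, 0.95)
})

test_that("an all-normal record gets zero abnormal labels", {
  sim <- make_clean_sim(120, seed = 3, rr_jitter_ms = 5)
  bs <- classify_beats(detect_beats(sim$record, "II"), sim$record)
  expect_equal(sum(bs$labels == "A"), 0)
})

test_that("the RR rule catches constructed premature beats", {
  # alternating rhythm: every 4th beat 30% premature (then compensated)
  fs <- 200
  t <- numeric(60); t[1] <- 1
  for (i in 2:60) {
    base <- 0.8
    t[i] <- t[i - 1] + if (i %% 4 == 0) 0.7 * base else
      if (i %% 4 == 1) 1.3 * base else base
  }
  bs <- beat_series("II", round(t * fs) + 1, fs_hz = fs)
  # classify on rhythm only: synthesize a matching clean record
  rec <- ecg_record(list(II = rep(0, round(max(t) * fs) + 400)), fs_hz = fs)
  x <- rec$signals$II
  for (ti in t) {  # simple identical spikes so morphology rules stay silent
    idx <- round(ti * fs) + 1
    x[(idx - 10):(idx + 10)] <- 1000 * exp(-((-10:10) / 3)^2 / 2)
  }
  rec$signals$II <- x
  out <- classify_beats(bs, rec)
  prem <- which(seq_along(t) %% 4 == 0 & seq_along(t) > 8)
  expect_true(all(out$labels[prem] == "A"))
})

test_that("ST flagging follows the offset and threshold", {
  all_on <- generate_ecg(ecg_sim_config(duration_s = 60, leads = "II",
                                        st_offset_uV = 200, st_fraction = 1,
                                        seed = 2))
  bs <- classify_beats(detect_beats(all_on$record, "II"), all_on$record)
  bs <- flag_st_deviation(all_on$record, bs)
  flags <- bs$st_dev[bs$labels == "N" & !is.na(bs$st_dev)]
  expect_true(all(flags))

  none <- generate_ecg(ecg_sim_config(duration_s = 60, leads = "II", seed = 2))
  bs0 <- flag_st_deviation(none$record,
                           classify_beats(detect_beats(none$record, "II"),
                                          none$record))
  expect_false(any(bs0$st_dev, na.rm = TRUE))
})

test_that("partial ST offsets reproduce the configured fraction", {
  sim <- generate_ecg(ecg_sim_config(duration_s = 600, leads = "II",
                                     st_offset_uV = 250, st_fraction = 0.3,
                                     seed = 17))
  bs <- classify_beats(detect_beats(sim$record, "II"), sim$record)
  bs <- flag_st_deviation(sim$record, bs)
  ok <- !is.na(bs$st_dev)
  frac <- mean(bs$st_dev[ok])
  n <- sum(ok)
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / n))
  # and the flags agree with the per-beat truth
  expect_gt(mean(bs$st_dev[ok] == sim$truth$st_flags[ok]), 0.98)
})

test_that("lead selection maximizes beats then minimizes abnormals with priority", {
  mk <- function(lead, n, a) {
    labels <- c(rep("A", a), rep("N", n - a))
    beat_series(lead, seq_len(n) * 100, labels = labels, fs_hz = 200)
  }
  cands <- list(I = mk("I", 17000, 20), II = mk("II", 17050, 15),
                V6 = mk("V6", 17050, 30))
  expect_identical(select_lead(cands), "II")
  expect_identical(select_lead(list(V6 = mk("V6", 10, 0))), "V6")
  same <- list(I = mk("I", 100, 5), II = mk("II", 100, 5), V6 = mk("V6", 100, 5))
  expect_identical(select_lead(same), "II")
  expect_error(select_lead(list()), "empty")
})

test_that("summary percentage conventions match the published per-patient cells", {
  # abnormal % over all beats; ST % over normal beats only
  expect_equal(beat_summary(14317, 12, 0)$pct_abnormal, 0.084)
  expect_equal(round(beat_summary(13857, 135, 10111)$pct_st, 1), 73.0)
  expect_equal(beat_summary(100, 0, 0),
               list(n_normal = 100, n_abnormal = 0, pct_abnormal = 0,
                    n_st = 0, pct_st = 0))
  expect_error(beat_summary(0, 0, 0), "zero beats")
})

test_that("ground-truth override reproduces the generator annotations", {
  sim <- generate_ecg(ecg_sim_config(duration_s = 60, leads = "II",
                                     ectopic_rate = 0.05, seed = 9))
  bs <- detect_beats(sim$record, "II")
  gt <- apply_ground_truth(bs, sim$truth)
  expect_equal(length(gt$r_idx), length(sim$truth$r_times_s))
  expect_identical(gt$labels, sim$truth$labels)
  expect_true(all(is.na(gt$q_idx[gt$labels == "A"])))
})
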