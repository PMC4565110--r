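# HRV processing chain: spline editing, 4 Hz resampling, detrending, the 13
# measures, and both spectral estimators.

mk_nn_bs <- function(times, labels = rep("N", length(times))) {
  bs_from_times(times, labels, fs = 1000)
}

test_that("editing an all-normal subsegment is the identity", {
  t <- cumsum(c(1, rep(0.8, 50)))
  nn <- edit_rr(mk_nn_bs(t))
  expect_equal(nn$nn_ms, rep(800, 50))
  expect_false(any(nn$edited))
})

test_that("spline editing reproduces a linear NN ramp exactly", {
  # RR ramps 700 -> 900 ms; one ectopic disturbs the middle
  rr <- seq(700, 900, length.out = 41) / 1000
  t <- cumsum(c(1, rr))
  labels <- rep("N", length(t)); labels[20] <- "A"
  nn <- edit_rr(mk_nn_bs(t, labels))
  expect_true(any(nn$edited))
  # a (natural) cubic spline through collinear points is that line
  ideal <- seq(700, 900, length.out = 41)
  expect_equal(nn$nn_ms, ideal, tolerance = 1e-6)
})

test_that("editing an ectopic inside a sinusoidal modulation recovers the truth", {
  sim <- generate_ecg(ecg_sim_config(duration_s = 320, leads = "II",
                                     lf_mod = c(0.1, 40), seed = 2))
  tr_clean <- sim$truth$r_times_s
  # corrupt one beat: 30% premature
  i <- 150
  t_cor <- tr_clean
  t_cor[i] <- t_cor[i] - 0.3 * (t_cor[i] - t_cor[i - 1])
  labels <- rep("N", length(t_cor)); labels[i] <- "A"
  nn <- edit_rr(mk_nn_bs(t_cor, labels))
  true_nn <- diff(tr_clean) * 1000
  err <- abs(nn$nn_ms[nn$edited] - true_nn[which(nn$edited)])
  expect_lt(max(err), 5)
})

test_that("the editing gate rejects subsegments beyond 5% abnormal", {
  t <- cumsum(c(1, rep(0.8, 50)))
  labels <- rep("N", length(t)); labels[seq(5, 45, by = 10)] <- "A"
  expect_gt(mean(labels == "A"), 0.05)
  expect_error(edit_rr(mk_nn_bs(t, labels)), "rejected")
})

test_that("resampling a constant NN series is constant with 1200 samples", {
  t <- cumsum(c(0, rep(0.8, 400)))
  nn <- nn_series(t[-1], rep(800, 400))
  rs <- resample_nn(nn, start_s = 0.8, duration_s = 300)
  expect_equal(length(rs$values_ms), 1200)
  expect_equal(rs$fs_hz, 4)
  expect_equal(rs$values_ms, rep(800, 1200), tolerance = 1e-9)
})

test_that("resampling tracks a 0.1 Hz sinusoid within 1 ms", {
  tbeat <- cumsum(c(0.5, rep(0.8, 380)))
  vals <- 800 + 50 * sin(2 * pi * 0.1 * tbeat)
  nn <- nn_series(tbeat, vals)
  rs <- resample_nn(nn, start_s = 5, duration_s = 290)
  ref <- 800 + 50 * sin(2 * pi * 0.1 * rs$t_s)
  expect_lt(max(abs(rs$values_ms - ref)), 1)
})

test_that("linear trends survive resampling and vanish under detrending", {
  tbeat <- cumsum(c(0.5, rep(0.8, 380)))
  vals <- 700 + 0.5 * tbeat
  rs <- resample_nn(nn_series(tbeat, vals), start_s = 5, duration_s = 290)
  ref <- 700 + 0.5 * rs$t_s
  expect_lt(max(abs(rs$values_ms - ref)), 1e-6)
  dt <- detrend_linear(rs)
  expect_lt(max(abs(dt$values_ms)), 1e-6)
  expect_true(dt$detrended)
})

test_that("detrending recovers a sinusoid on a line and never adds variance", {
  t <- seq(0, 300, by = 0.25)
  y <- 3 * t + 100 + 40 * sin(2 * pi * 0.1 * t)
  out <- detrend_linear(nn_series(t + 1, pmax(y, 1)))
  # leakage of the sinusoid into the fitted line is bounded
  expect_equal(sqrt(mean(out$nn_ms^2)), 40 / sqrt(2), tolerance = 0.02)
  set.seed(4)
  w <- rnorm(500)
  expect_lte(var(detrend_linear(w)), var(w))
})

test_that("time-domain measures match their definitions", {
  nn <- nn_series(cumsum(c(800, 860, 865)) / 1000, c(800, 860, 865))
  td <- time_domain_measures(nn)
  expect_equal(td$pnn50_pct, 100 / 3)   # one of two diffs > 50 ms, denominator 3
  expect_equal(td$mean_nn_ms, mean(c(800, 860, 865)))

  const <- nn_series(cumsum(rep(0.8, 20)), rep(800, 20))
  tdc <- time_domain_measures(const)
  expect_equal(tdc$sdnn_ms, 0)
  expect_equal(tdc$sdsd_ms, 0)
  expect_equal(tdc$rmssd_ms, 0)
  expect_equal(tdc$pnn50_pct, 0)

  # alternating 800/900: diffs are +-100 (zero mean), RMSSD = SDSD ~ 100
  alt <- rep(c(800, 900), 30)
  nna <- nn_series(cumsum(alt) / 1000, alt)
  tda <- time_domain_measures(nna)
  expect_equal(tda$rmssd_ms, 100, tolerance = 1e-3)
  expect_equal(tda$sdsd_ms, 100, tolerance = 2e-2)
})

test_that("pNN50 equals brute-force pair counting on random series", {
  set.seed(8)
  for (i in 1:10) {
    nn <- 800 + cumsum(rnorm(200, 0, 40))
    nn <- pmax(nn, 300)
    s <- nn_series(cumsum(nn) / 1000, nn)
    expect_equal(time_domain_measures(s)$pnn50_pct, pnn50_brute(nn))
  }
})

test_that("Poincare descriptors match their closed forms", {
  alt <- c(rep(c(800, 900), 25), 800)   # odd length: exactly balanced diffs
  pc <- poincare_measures(nn_series(cumsum(alt) / 1000, alt))
  expect_equal(pc$sd1_ms, sqrt(100^2 / 2), tolerance = 1e-3)  # 70.71 ms
  expect_equal(pc$sd2_ms, 0, tolerance = 1e-3)
  expect_true(is.na(pc$sd1_sd2))

  const <- nn_series(cumsum(rep(0.8, 10)), rep(800, 10))
  pcc <- poincare_measures(const)
  expect_equal(pcc$sd1_ms, 0)
  expect_equal(pcc$sd2_ms, 0)
  expect_true(is.na(pcc$sd1_sd2))
})

test_that("SD1/SD2 approaches 1 for white NN series", {
  set.seed(12)
  nn <- 800 + rnorm(5000, 0, 30)
  pc <- poincare_measures(nn_series(cumsum(nn) / 1000, nn))
  expect_equal(pc$sd1_sd2, 1, tolerance = 0.05)
})

test_that("RMSSD/SDSD/SD1 identities hold under the population convention", {
  set.seed(3)
  for (i in 1:8) {
    nn <- 800 + cumsum(rnorm(150, 0, 20))
    nn <- pmax(nn, 300)
    s <- nn_series(cumsum(nn) / 1000, nn)
    d <- diff(nn)
    rmssd_raw <- sqrt(mean(d^2))          # on the non-detrended series
    sdsd_pop <- sqrt(mean((d - mean(d))^2))
    expect_equal(rmssd_raw^2, sdsd_pop^2 + mean(d)^2, tolerance = 1e-9)
    pc <- poincare_measures(s)
    expect_equal(pc$sd1_ms, sqrt((rmssd_raw^2 - mean(d)^2) / 2), tolerance = 1e-9)
  }
})

test_that("both spectral estimators localize a sinusoid's power", {
  set.seed(2)
  t <- (0:1199) / 4
  x <- 50 * sin(2 * pi * 0.1 * t) + rnorm(1200, 0, 1)
  rs <- structure(list(fs_hz = 4, t_s = t, values_ms = x, detrended = TRUE),
                  class = "resampled_nn")
  for (m in c("welch", "ar_burg")) {
    bp <- band_powers(estimate_psd(rs, m))
    expect_equal(bp$lf_ms2, 1250, tolerance = 0.1)   # a^2/2
    expect_lt(bp$hf_ms2, 0.1 * bp$lf_ms2)
  }
})

test_that("integrated PSD obeys Parseval for white noise", {
  set.seed(6)
  x <- rnorm(1200, 0, 10)
  rs <- structure(list(fs_hz = 4, t_s = (0:1199) / 4, values_ms = x,
                       detrended = TRUE), class = "resampled_nn")
  for (m in c("welch", "ar_burg")) {
    s <- estimate_psd(rs, m)
    tot <- ecthrv:::trapz(s$freqs_hz, s$psd_ms2_per_hz)
    expect_equal(tot, var(x), tolerance = 0.15)
  }
})

test_that("a zero series yields a zero Welch PSD and short series error", {
  z <- structure(list(fs_hz = 4, t_s = (0:1199) / 4, values_ms = numeric(1200),
                      detrended = TRUE), class = "resampled_nn")
  s <- estimate_psd(z, "welch")
  expect_true(all(s$psd_ms2_per_hz == 0))
  short <- structure(list(fs_hz = 4, t_s = (0:99) / 4, values_ms = rnorm(100),
                          detrended = TRUE), class = "resampled_nn")
  expect_error(estimate_psd(short, "welch"), "Welch window")
})

test_that("band powers normalize to 100 and handle degenerate spectra", {
  set.seed(9)
  for (i in 1:10) {
    spec <- structure(list(freqs_hz = seq(0, 2, length.out = 512),
                           psd_ms2_per_hz = abs(rnorm(512)) + 0.01,
                           method = "welch", params = list()),
                      class = "spectral_estimate")
    bp <- band_powers(spec)
    expect_equal(bp$nlf_nu + bp$nhf_nu, 100)
    expect_gte(bp$lf_ms2, 0); expect_gte(bp$hf_ms2, 0)
  }
  # all power at 0.25 Hz -> nHF ~ 100
  f <- seq(0, 2, length.out = 2048)
  p <- exp(-((f - 0.25) / 0.005)^2)
  spec <- structure(list(freqs_hz = f, psd_ms2_per_hz = p, method = "welch",
                         params = list()), class = "spectral_estimate")
  bp <- band_powers(spec)
  expect_lt(bp$nlf_nu, 1); expect_gt(bp$nhf_nu, 99)
  # zero HF -> ratio undefined
  p0 <- ifelse(f < 0.12, 1, 0)
  bp0 <- band_powers(structure(list(freqs_hz = f, psd_ms2_per_hz = p0,
                                    method = "welch", params = list()),
                               class = "spectral_estimate"))
  expect_true(is.na(bp0$lf_hf))
})

test_that("LF/HF modulation amplitude ratio is recovered through the chain", {
  for (seed in c(5, 23)) {
    sim <- generate_ecg(ecg_sim_config(duration_s = 320, leads = "II",
                                       lf_mod = c(0.1, 40), hf_mod = c(0.25, 20),
                                       rr_jitter_ms = 5, seed = seed))
    bs <- classify_beats(detect_beats(sim$record, "II"), sim$record)
    rs <- detrend_linear(resample_nn(edit_rr(bs), start_s = 10,
                                     duration_s = 300))
    for (m in c("welch", "ar_burg")) {
      bp <- band_powers(estimate_psd(rs, m))
      expect_equal(bp$lf_hf, (40 / 20)^2, tolerance = 0.15)
    }
  }
})

test_that("per-patient medians summarize the accepted segments", {
  set.seed(14)
  st <- random_annotation_stream(4800, mean_rr_s = 0.8, rate = 0)
  bs <- bs_from_times(st$times, st$labels)
  sel <- select_subsegments(bs, duration_s = 4800)
  out <- hrv_for_patient(bs, sel, method = "welch")
  expect_equal(nrow(out$segments), 4)
  expect_named(out$patient)
  expect_equal(unname(out$patient["mean_nn_ms"]),
               median(out$segments$mean_nn_ms))
  # with no accepted segments the summary errors
  sel$accepted <- FALSE
  expect_error(hrv_for_patient(bs, sel), "no accepted")
})

test_that("a patient with only LF modulation has nLF above 95", {
  sim <- generate_ecg(ecg_sim_config(duration_s = 320, leads = "II",
                                     lf_mod = c(0.1, 40), rr_jitter_ms = 2,
                                     seed = 77))
  bs <- classify_beats(detect_beats(sim$record, "II"), sim$record)
  rs <- detrend_linear(resample_nn(edit_rr(bs), start_s = 10, duration_s = 300))
  bp <- band_powers(estimate_psd(rs, "ar_burg"))
  expect_gt(bp$nlf_nu, 95)
})
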