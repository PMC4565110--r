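# Heart rate variability measures for 5-min subsegments.
#
# Processing chain per subsegment: RR intervals with abnormal-interval
# editing by cubic spline -> (for spectra) spline fit at 1 kHz, downsampled
# to 4 Hz, linear detrend -> Welch or AR-Burg(16) PSD -> LF/HF band powers.
# Time-domain dispersion measures (SDNN, SDSD, RMSSD, pNN50) are computed on
# the linearly detrended NN sequence; mean NN and the Poincare descriptors
# on the non-detrended sequence.

#' Normal-to-normal interval series
#'
#' @param t_s occurrence time (s) of each interval's terminating beat,
#'   strictly increasing.
#' @param nn_ms interval values in ms, all positive.
#' @param edited logical; TRUE where an abnormal RR interval was replaced by
#'   spline interpolation.
#' @return object of class `nn_series`.
#' @export
nn_series <- function(t_s, nn_ms, edited = rep(FALSE, length(t_s))) {
  if (length(t_s) != length(nn_ms) || length(t_s) != length(edited))
    stop("t_s, nn_ms and edited must have equal length", call. = FALSE)
  if (length(t_s) > 1 && is.unsorted(t_s, strictly = TRUE))
    stop("t_s must be strictly increasing", call. = FALSE)
  if (any(nn_ms <= 0)) stop("nn_ms must be positive", call. = FALSE)
  structure(list(t_s = as.numeric(t_s), nn_ms = as.numeric(nn_ms),
                 edited = as.logical(edited)), class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series: %d intervals, %d edited, mean %.1f ms\n",
              length(x$nn_ms), sum(x$edited), mean(x$nn_ms)))
  invisible(x)
}

#' Edit abnormal RR intervals by cubic-spline interpolation
#'
#' Builds the RR interval sequence of a subsegment and replaces every
#' interval adjacent to an abnormal beat with the value of a cubic spline
#' fitted through the normal (time, RR) points; the time grid is preserved
#' and replaced intervals are flagged. Subsegments with more than
#' `max_abnormal_frac` abnormal beats are rejected (the caller must select a
#' different subsegment).
#'
#' @param bs a classified [beat_series()] restricted to one subsegment.
#' @param max_abnormal_frac rejection gate on the abnormal-beat fraction
#'   (default 0.05).
#' @return an [nn_series()].
#' @export
edit_rr <- function(bs, max_abnormal_frac = 0.05) {
  stopifnot(inherits(bs, "beat_series"))
  nb <- n_beats(bs)
  if (nb < 2) stop("need at least 2 beats to form RR intervals", call. = FALSE)
  frac <- mean(bs$labels == "A")
  if (frac > max_abnormal_frac)
    stop(sprintf("subsegment rejected: %.1f%% abnormal beats exceeds the %.0f%% gate",
                 100 * frac, 100 * max_abnormal_frac), call. = FALSE)
  t <- beat_times(bs)
  tv <- t[-1]
  rr <- diff(t) * 1000
  bad <- bs$labels[-1] == "A" | bs$labels[-nb] == "A"
  if (any(bad)) {
    if (sum(!bad) < 4)
      stop("too few normal intervals to fit the editing spline", call. = FALSE)
    sp <- stats::splinefun(tv[!bad], rr[!bad], method = "natural")
    rr[bad] <- sp(tv[bad])
  }
  nn_series(tv, rr, edited = bad)
}

#' Resample an NN series to an equidistant 4 Hz sequence
#'
#' A cubic spline is fitted through the non-equidistant (time, NN) points and
#' evaluated on a 1 kHz grid spanning the subsegment; the curve is then
#' downsampled to `fs_out` by decimation (every 250th sample for 4 Hz).
#'
#' @param nn an [nn_series()] with at least 4 intervals.
#' @param start_s,duration_s subsegment bounds; default to the span of the
#'   series. A 300 s subsegment yields 1200 samples at 4 Hz.
#' @param fs_out output rate in Hz (default 4).
#' @param fit_fs_hz dense spline evaluation rate in Hz (default 1000).
#' @return object of class `resampled_nn`: `fs_hz`, `t_s`, `values_ms`,
#'   `detrended`.
#' @export
resample_nn <- function(nn, start_s = NULL, duration_s = NULL,
                        fs_out = 4, fit_fs_hz = 1000) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$nn_ms) < 4)
    stop("need at least 4 intervals to resample", call. = FALSE)
  if (is.null(start_s)) start_s <- nn$t_s[1]
  if (is.null(duration_s)) duration_s <- nn$t_s[length(nn$t_s)] - start_s
  if (duration_s <= 0) stop("non-positive resampling span", call. = FALSE)
  n_dense <- round(duration_s * fit_fs_hz)
  tg <- start_s + (seq_len(n_dense) - 1) / fit_fs_hz
  sp <- stats::splinefun(nn$t_s, nn$nn_ms, method = "natural")
  dense <- sp(tg)
  step <- round(fit_fs_hz / fs_out)
  idx <- seq(1L, n_dense, by = step)
  structure(list(fs_hz = fs_out, t_s = tg[idx], values_ms = dense[idx],
                 detrended = FALSE), class = "resampled_nn")
}

#' Remove the least-squares linear trend
#'
#' Applied to NN sequences before the dispersion and spectral measures (the
#' mean NN interval and the Poincare descriptors are computed on the
#' non-detrended sequence). The output has zero mean.
#'
#' @param x an [nn_series()], a `resampled_nn`, or a plain numeric vector.
#' @return the same type with the fitted line removed.
#' @export
detrend_linear <- function(x) {
  resid_line <- function(t, y) {
    t <- t - mean(t)
    slope <- if (sum(t^2) > 0) sum(t * y) / sum(t^2) else 0
    y - mean(y) - slope * t
  }
  if (inherits(x, "nn_series")) {
    x$nn_ms <- resid_line(x$t_s, x$nn_ms)
    return(x)
  }
  if (inherits(x, "resampled_nn")) {
    x$values_ms <- resid_line(x$t_s, x$values_ms)
    x$detrended <- TRUE
    return(x)
  }
  if (length(x) < 2) stop("need at least 2 points to detrend", call. = FALSE)
  resid_line(seq_along(x), x)
}

#' Time-domain HRV measures
#'
#' Mean NN is computed on the series as given; SDNN, SDSD and RMSSD on the
#' linearly detrended series (SDNN and SDSD use the sample (1/(n-1))
#' standard deviation; RMSSD is the root mean square of successive
#' differences). pNN50 counts adjacent-interval differences strictly greater
#' than 50 ms on the non-detrended series -- its count is a property of the
#' raw successive differences -- and divides by the total number of NN
#' intervals.
#'
#' @param nn an edited [nn_series()].
#' @return list with `mean_nn_ms`, `sdnn_ms`, `sdsd_ms`, `rmssd_ms`,
#'   `pnn50_pct`.
#' @export
time_domain_measures <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$nn_ms
  if (length(v) < 2) stop("need at least 2 intervals", call. = FALSE)
  dv <- detrend_linear(nn)$nn_ms
  d <- diff(dv)
  list(mean_nn_ms = mean(v),
       sdnn_ms = stats::sd(dv),
       sdsd_ms = stats::sd(d),
       rmssd_ms = sqrt(mean(d^2)),
       pnn50_pct = 100 * sum(abs(diff(v)) > 50) / length(v))
}

#' Poincare-plot descriptors
#'
#' SD1 (dispersion perpendicular to the line of identity) and SD2 (along it)
#' from the closed forms `SD1^2 = Var(diff)/2` and
#' `SD2^2 = 2 Var(NN) - Var(diff)/2` with population (1/n) variances,
#' computed on the non-detrended series. The SD1/SD2 ratio is NA when
#' SD2 = 0.
#'
#' @param nn an edited [nn_series()] with at least 3 intervals.
#' @return list with `sd1_ms`, `sd2_ms`, `sd1_sd2`.
#' @export
poincare_measures <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$nn_ms
  if (length(v) < 3) stop("need at least 3 intervals", call. = FALSE)
  d <- diff(v)
  sd1 <- sqrt(var_pop(d) / 2)
  sd2sq <- 2 * var_pop(v) - var_pop(d) / 2
  sd2 <- sqrt(max(sd2sq, 0))
  list(sd1_ms = sd1, sd2_ms = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

#' Power spectral density of a resampled NN sequence
#'
#' Welch's periodogram (Hamming windows, 50% overlap, per-window mean
#' removal) or a parametric autoregressive estimate of order 16 with
#' reflection coefficients by the Burg method. Both return a one-sided PSD in
#' ms^2/Hz on a grid covering 0 to the Nyquist frequency, scaled so that the
#' integrated power matches the series variance (within window loss for
#' Welch).
#'
#' @param x a detrended `resampled_nn`.
#' @param method `"welch"` or `"ar_burg"`.
#' @param ar_order AR model order (default 16).
#' @param welch_nperseg,welch_overlap Welch window length and overlap in
#'   samples (defaults 256 and 128, i.e. 64 s windows at 4 Hz).
#' @param n_freq grid size for the AR spectrum (default 1024).
#' @return object of class `spectral_estimate`: `freqs_hz`, `psd_ms2_per_hz`,
#'   `method`, `params`.
#' @export
estimate_psd <- function(x, method = c("welch", "ar_burg"), ar_order = 16,
                         welch_nperseg = 256, welch_overlap = welch_nperseg / 2,
                         n_freq = 1024) {
  method <- match.arg(method)
  stopifnot(inherits(x, "resampled_nn"))
  v <- x$values_ms
  fs <- x$fs_hz
  if (method == "welch") {
    N <- welch_nperseg
    if (length(v) < N)
      stop(sprintf("series of %d samples is shorter than one Welch window (%d)",
                   length(v), N), call. = FALSE)
    step <- N - welch_overlap
    starts <- seq(1L, length(v) - N + 1L, by = step)
    k <- seq_len(N) - 1
    w <- 0.54 - 0.46 * cos(2 * pi * k / (N - 1))
    scale <- 1 / (fs * sum(w^2))
    nh <- N %/% 2 + 1L
    acc <- numeric(nh)
    for (s in starts) {
      seg <- v[s:(s + N - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(seg)[seq_len(nh)]
      p <- scale * (Mod(X)^2)
      p[2:(nh - 1L)] <- 2 * p[2:(nh - 1L)]   # one-sided: double interior bins
      acc <- acc + p
    }
    psd <- acc / length(starts)
    freqs <- (seq_len(nh) - 1) * fs / N
    params <- list(nperseg = N, overlap = welch_overlap, window = "hamming",
                   n_segments = length(starts))
  } else {
    if (length(v) <= ar_order)
      stop("series too short for the AR order", call. = FALSE)
    fit <- stats::ar(v, aic = FALSE, order.max = ar_order, method = "burg",
                     demean = TRUE)
    a <- fit$ar
    sigma2 <- fit$var.pred
    eval_psd <- function(f) {
      ew <- exp(-2i * pi * outer(f / fs, seq_along(a)))
      2 * sigma2 / fs / Mod(1 - as.vector(ew %*% a))^2
    }
    freqs <- seq(0, fs / 2, length.out = n_freq)
    psd <- eval_psd(freqs)
    # near-unit-circle poles make the spectrum locally far narrower than the
    # base grid; refine around every spectral peak so trapezoidal band
    # integration keeps the peak's mass
    pk <- which(diff(sign(diff(psd))) == -2) + 1L
    if (length(pk)) {
      lo <- freqs[pmax(pk - 2L, 1L)]
      hi <- freqs[pmin(pk + 2L, n_freq)]
      extra <- unlist(lapply(seq_along(pk), function(i)
        seq(lo[i], hi[i], length.out = 801L)))
      freqs <- sort(unique(c(freqs, extra)))
      psd <- eval_psd(freqs)
    }
    params <- list(order = ar_order, n_freq = n_freq)
  }
  structure(list(freqs_hz = freqs, psd_ms2_per_hz = psd, method = method,
                 params = params), class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("PSD (%s): %d frequencies 0-%.3g Hz, total power %.1f ms^2\n",
              x$method, length(x$freqs_hz), max(x$freqs_hz),
              trapz(x$freqs_hz, x$psd_ms2_per_hz)))
  invisible(x)
}

# trapezoidal band power over [lo, hi) with interpolated band edges
.band_power <- function(freqs, psd, lo, hi) {
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  p <- c(stats::approx(freqs, psd, lo, rule = 2)$y, psd[inside],
         stats::approx(freqs, psd, hi, rule = 2)$y)
  trapz(f, p)
}

#' LF and HF band powers and derived measures
#'
#' Trapezoidal integration of the PSD over the LF (0.04-0.15 Hz) and HF
#' (0.15-0.4 Hz) bands; normalized powers nLF = 100 LF/(LF+HF) and
#' nHF = 100 - nLF (so they sum to 100 exactly); LF/HF is NA when HF = 0.
#'
#' @param spec a `spectral_estimate`.
#' @param lf_band,hf_band band limits in Hz.
#' @return list with `lf_ms2`, `hf_ms2`, `nlf_nu`, `nhf_nu`, `lf_hf`.
#' @export
band_powers <- function(spec, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(spec, "spectral_estimate"))
  lf <- .band_power(spec$freqs_hz, spec$psd_ms2_per_hz, lf_band[1], lf_band[2])
  hf <- .band_power(spec$freqs_hz, spec$psd_ms2_per_hz, hf_band[1], hf_band[2])
  tot <- lf + hf
  nlf <- if (tot > 0) 100 * lf / tot else NA_real_
  list(lf_ms2 = lf, hf_ms2 = hf,
       nlf_nu = nlf, nhf_nu = if (is.na(nlf)) NA_real_ else 100 - nlf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

.hrv_measure_names <- c("mean_nn_ms", "sdnn_ms", "sdsd_ms", "rmssd_ms",
                        "pnn50_pct", "sd1_ms", "sd2_ms", "sd1_sd2",
                        "lf_ms2", "hf_ms2", "nlf_nu", "nhf_nu", "lf_hf")

#' The names of the 13 HRV measures
#' @return character vector in reporting order.
#' @export
hrv_measure_names <- function() .hrv_measure_names

#' All 13 HRV measures for one subsegment
#'
#' @param nn an edited [nn_series()].
#' @param method spectral method, `"welch"` or `"ar_burg"`.
#' @param start_s,duration_s subsegment bounds passed to [resample_nn()].
#' @param ... further arguments to [estimate_psd()].
#' @return one-row data.frame of the 13 measures plus `method`.
#' @export
hrv_segment_measures <- function(nn, method = "ar_burg",
                                 start_s = NULL, duration_s = NULL, ...) {
  td <- time_domain_measures(nn)
  pc <- poincare_measures(nn)
  rs <- detrend_linear(resample_nn(nn, start_s = start_s,
                                   duration_s = duration_s))
  bp <- band_powers(estimate_psd(rs, method = method, ...))
  out <- c(td, pc, bp)
  df <- as.data.frame(out[.hrv_measure_names])
  df$method <- method
  df
}

#' Per-segment HRV results and per-patient medians
#'
#' Computes the 13 measures for every accepted subsegment and summarizes the
#' patient as the median of each measure over its accepted segments.
#'
#' @param bs the window-based classified [beat_series()].
#' @param selections the [select_subsegments()] table.
#' @param method spectral method, `"welch"` or `"ar_burg"`.
#' @return list with `segments` (data.frame, one row per accepted segment,
#'   with `segment_index` and `threshold_used`) and `patient` (named numeric
#'   vector of the 13 medians).
#' @export
hrv_for_patient <- function(bs, selections, method = "ar_burg") {
  acc <- selections[selections$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted subsegments: cannot compute HRV",
                           call. = FALSE)
  rows <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    sel <- acc[i, ]
    sub <- subsegment_beats(bs, sel)
    if (n_beats(sub) < 6) {
      warning(sprintf("segment %d: too few beats, skipped", sel$segment_index))
      next
    }
    nn <- edit_rr(sub)
    m <- hrv_segment_measures(nn, method = method, start_s = sel$start_s,
                              duration_s = sel$end_s - sel$start_s)
    m$segment_index <- sel$segment_index
    m$threshold_used <- sel$threshold_used
    rows[[i]] <- m
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable subsegments for HRV", call. = FALSE)
  segments <- do.call(rbind, rows)
  patient <- vapply(.hrv_measure_names,
                    function(nm) median_mid(segments[[nm]][!is.na(segments[[nm]])]),
                    numeric(1))
  list(segments = segments, patient = patient)
}
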