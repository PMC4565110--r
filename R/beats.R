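# QRS/Q/T detection, beat classification, ST-deviation flagging and lead
# selection. The detector is Pan-Tompkins style: 5-15 Hz band-pass, squared
# derivative, moving-window integration, adaptive threshold with a 200 ms
# refractory period.

#' Per-beat annotation series for one lead
#'
#' @param lead lead name.
#' @param r_idx strictly increasing 1-based sample indices of R peaks.
#' @param q_idx,t_idx sample indices of Q and T peaks (NA where undefined;
#'   Q/T of abnormal beats are unreliable and therefore kept NA).
#' @param labels per-beat `"N"` or `"A"`.
#' @param st_dev per-beat logical ST-deviation flag (NA until computed).
#' @param fs_hz sampling rate.
#' @param start_clock clock time of sample 1 (seconds since midnight).
#' @return object of class `beat_series`.
#' @export
beat_series <- function(lead, r_idx, q_idx = rep(NA_integer_, length(r_idx)),
                        t_idx = rep(NA_integer_, length(r_idx)),
                        labels = rep("N", length(r_idx)),
                        st_dev = rep(NA, length(r_idx)),
                        fs_hz, start_clock = 0) {
  if (length(r_idx) && is.unsorted(r_idx, strictly = TRUE))
    stop("r_idx must be strictly increasing", call. = FALSE)
  if (length(labels) != length(r_idx) || length(q_idx) != length(r_idx) ||
      length(t_idx) != length(r_idx) || length(st_dev) != length(r_idx))
    stop("per-beat vectors must all match the number of R peaks", call. = FALSE)
  if (length(labels) && !all(labels %in% c("N", "A")))
    stop("labels must be 'N' or 'A'", call. = FALSE)
  if (any(!is.na(q_idx) & labels == "A") || any(!is.na(t_idx) & labels == "A"))
    stop("Q/T indices must be NA for abnormal beats", call. = FALSE)
  structure(list(lead = lead, r_idx = as.numeric(r_idx), q_idx = as.numeric(q_idx),
                 t_idx = as.numeric(t_idx), labels = labels, st_dev = st_dev,
                 fs_hz = fs_hz, start_clock = parse_clock(start_clock)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Beat series (lead %s): %d beats, %d abnormal, %d ST-flagged\n",
              x$lead, length(x$r_idx), sum(x$labels == "A"),
              sum(x$st_dev %in% TRUE)))
  invisible(x)
}

#' Number of beats in a beat series
#' @param bs a [beat_series()].
#' @return integer count.
#' @export
n_beats <- function(bs) length(bs$r_idx)

#' R-peak times in seconds from the start of the record
#' @param bs a [beat_series()].
#' @return numeric vector of seconds.
#' @export
beat_times <- function(bs) (bs$r_idx - 1) / bs$fs_hz

# 5-15 Hz zero-phase band-pass used by both detection and width estimation.
.bandpass_qrs <- function(x, fs) {
  ny <- fs / 2
  bf <- signal::butter(3, c(5, 15) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect Q, R and T peaks on one lead
#'
#' R peaks are found by adaptive thresholding of the moving-window integral
#' of the squared derivative of the band-passed signal, then refined to the
#' local extremum of the band-passed signal; detections closer than the
#' 200 ms refractory period are merged. The Q peak is the signal minimum in
#' a fixed window before R (-80 to -10 ms) and the T peak the dominant
#' extremum (relative to the PQ baseline) in an RR-adaptive window after R
#' (+120 ms to 0.6 RR).
#'
#' @param rec an [ecg_record()] of at least 10 s.
#' @param lead lead name to analyze.
#' @return a [beat_series()] with all beats provisionally labelled `"N"`
#'   (see [classify_beats()]).
#' @export
detect_beats <- function(rec, lead) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!lead %in% rec$lead_names)
    stop("lead not present in record: ", lead, call. = FALSE)
  fs <- rec$fs_hz
  x <- rec$signals[[lead]]
  if (length(x) < 10 * fs)
    stop("record shorter than 10 s; too short for beat detection", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("flat-line lead '", lead, "': no beats detected")
    return(beat_series(lead, numeric(0), numeric(0), numeric(0), character(0),
                       logical(0), fs_hz = fs, start_clock = rec$start_clock))
  }

  bp <- .bandpass_qrs(x, fs)
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  w <- max(3L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks of the integrated signal
  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] >= mwi[1:(n - 2)] & mwi[2:(n - 1)] > mwi[3:n]) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand))
    return(beat_series(lead, numeric(0), numeric(0), numeric(0), character(0),
                       logical(0), fs_hz = fs, start_clock = rec$start_clock))

  # adaptive signal/noise peak levels (Pan-Tompkins recursions)
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) / 3
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) / 2
  refr <- round(0.200 * fs)
  det <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] >= thr) {
      if (i - last >= refr) {
        det <- c(det, i)
        last <- i
      } else if (mwi[i] > mwi[last]) {      # merge within refractory: keep larger
        det[length(det)] <- i
        last <- i
      }
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (!length(det))
    return(beat_series(lead, numeric(0), numeric(0), numeric(0), character(0),
                       logical(0), fs_hz = fs, start_clock = rec$start_clock))

  # refine each detection to the local extremum of the band-passed signal
  hw <- round(0.100 * fs)
  r_idx <- vapply(det, function(i) {
    a <- max(1L, i - hw); b <- min(n, i + hw)
    as.integer(a + which.max(abs(bp[a:b])) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # re-enforce refractory after refinement
  keep <- c(TRUE, diff(r_idx) >= refr)
  r_idx <- r_idx[keep]

  qt <- .locate_qt(x, r_idx, fs)
  beat_series(lead, r_idx, qt$q_idx, qt$t_idx,
              labels = rep("N", length(r_idx)),
              st_dev = rep(NA, length(r_idx)),
              fs_hz = fs, start_clock = rec$start_clock)
}

# Q and T peak location relative to given R peaks.
.locate_qt <- function(x, r_idx, fs) {
  n <- length(x)
  nb <- length(r_idx)
  q_idx <- rep(NA_real_, nb)
  t_idx <- rep(NA_real_, nb)
  rr <- c(NA, diff(r_idx)) / fs
  med_rr <- if (nb > 1) stats::median(rr, na.rm = TRUE) else 0.8
  for (b in seq_len(nb)) {
    r <- r_idx[b]
    a <- r - round(0.080 * fs); z <- r - round(0.010 * fs)
    if (a >= 1 && z <= n && z > a)
      q_idx[b] <- a + which.min(x[a:z]) - 1
    rr_b <- if (is.na(rr[b])) med_rr else rr[b]
    a <- r + round(0.120 * fs); z <- r + round(0.6 * rr_b * fs)
    if (z > a && z <= n) {
      base_a <- max(1, r - round(0.120 * fs)); base_z <- max(1, r - round(0.080 * fs))
      base <- mean(x[base_a:base_z])
      t_idx[b] <- a + which.max(abs(x[a:z] - base)) - 1
    }
  }
  list(q_idx = q_idx, t_idx = t_idx)
}

# QRS width (s) from the band-passed signal: span where |bp| exceeds 25% of
# its local maximum within +-100 ms of R.
.qrs_widths <- function(bp, r_idx, fs) {
  hw <- round(0.100 * fs)
  n <- length(bp)
  vapply(r_idx, function(r) {
    a <- max(1L, r - hw); b <- min(n, r + hw)
    seg <- abs(bp[a:b])
    above <- which(seg > 0.25 * max(seg))
    (above[length(above)] - above[1] + 1) / fs
  }, numeric(1))
}

#' Classify beats as normal or abnormal
#'
#' A beat is labelled `"A"` (abnormal shape or rhythm) when any of the
#' following holds, each judged against running statistics of preceding
#' normal beats: QRS width exceeds 1.5x the running median width; the
#' preceding RR interval is shorter than 0.8x or longer than 1.2x the running
#' median of the last 8 normal-to-normal RR intervals; or the correlation of
#' the beat's waveform (+-100 ms around R) with the running normal-beat
#' template falls below 0.9. Q/T indices of abnormal beats are cleared.
#'
#' @param bs a [beat_series()] from [detect_beats()].
#' @param rec the [ecg_record()] the series was detected on (for morphology).
#' @return the series with `labels` assigned.
#' @export
classify_beats <- function(bs, rec) {
  stopifnot(inherits(bs, "beat_series"), inherits(rec, "ecg_record"))
  nb <- n_beats(bs)
  if (nb == 0) return(bs)
  fs <- bs$fs_hz
  x <- rec$signals[[bs$lead]]
  bp <- .bandpass_qrs(x, fs)
  widths <- .qrs_widths(bp, bs$r_idx, fs)

  hw <- round(0.100 * fs)
  seg_of <- function(r) {
    a <- r - hw; b <- r + hw
    if (a < 1 || b > length(x)) return(NULL)
    x[a:b]
  }

  labels <- rep("N", nb)
  rr <- c(NA, diff(bs$r_idx)) / fs
  init_w <- stats::median(widths[seq_len(min(nb, 8L))])
  norm_w <- rep(init_w, 0)      # widths of accepted normal beats
  norm_rr <- numeric(0)         # normal-to-normal RR history
  tmpl <- NULL; tmpl_n <- 0
  prev_normal <- TRUE

  for (b in seq_len(nb)) {
    abn <- FALSE
    med_w <- if (length(norm_w) >= 3) stats::median(tail(norm_w, 8)) else init_w
    if (widths[b] > 1.5 * med_w) abn <- TRUE
    if (!abn && length(norm_rr) >= 4 && !is.na(rr[b]) && prev_normal) {
      med_rr <- stats::median(tail(norm_rr, 8))
      if (rr[b] < 0.8 * med_rr || rr[b] > 1.2 * med_rr) abn <- TRUE
    }
    seg <- seg_of(bs$r_idx[b])
    if (!abn && !is.null(tmpl) && !is.null(seg) && tmpl_n >= 4) {
      r <- suppressWarnings(stats::cor(seg, tmpl))
      if (!is.na(r) && r < 0.9) abn <- TRUE
    }
    if (abn) {
      labels[b] <- "A"
      prev_normal <- FALSE
    } else {
      if (!is.na(rr[b]) && prev_normal) norm_rr <- c(norm_rr, rr[b])
      norm_w <- c(norm_w, widths[b])
      if (!is.null(seg)) {
        if (is.null(tmpl)) tmpl <- seg else tmpl <- tmpl + (seg - tmpl) / min(tmpl_n + 1, 8)
        tmpl_n <- tmpl_n + 1
      }
      prev_normal <- TRUE
    }
  }
  bs$labels <- labels
  bs$q_idx[labels == "A"] <- NA_real_
  bs$t_idx[labels == "A"] <- NA_real_
  bs
}

#' Flag ST-segment deviation on normal beats
#'
#' The ST level of a beat is the mean amplitude over `[R+60 ms, R+80 ms]`
#' minus the PQ baseline (mean over `[R-120 ms, R-80 ms]`); the beat is
#' flagged when the absolute level reaches `threshold_uV`. This documented
#' simple operator stands in for proprietary Holter-software ST analysis.
#'
#' @param rec the [ecg_record()].
#' @param bs a classified [beat_series()].
#' @param threshold_uV flagging threshold in uV (default 100).
#' @return the series with `st_dev` filled (NA for abnormal beats).
#' @export
flag_st_deviation <- function(rec, bs, threshold_uV = 100) {
  stopifnot(inherits(bs, "beat_series"), inherits(rec, "ecg_record"))
  x <- rec$signals[[bs$lead]]
  fs <- bs$fs_hz
  n <- length(x)
  st <- rep(NA, n_beats(bs))
  for (b in seq_len(n_beats(bs))) {
    if (bs$labels[b] != "N") next
    r <- bs$r_idx[b]
    a1 <- r - round(0.120 * fs); z1 <- r - round(0.080 * fs)
    a2 <- r + round(0.060 * fs); z2 <- r + round(0.080 * fs)
    if (a1 < 1 || z2 > n) next
    st[b] <- abs(mean(x[a2:z2]) - mean(x[a1:z1])) >= threshold_uV
  }
  bs$st_dev <- st
  bs
}

#' Select the analysis lead
#'
#' Among candidate per-lead beat series, picks the lead with the highest
#' number of detected heartbeats, breaking ties by the lowest number of
#' abnormal heartbeats and then by a fixed priority order (II, I, V6, then
#' the remaining candidates in their given order).
#'
#' @param candidates named list of classified [beat_series()] (names are lead
#'   names; unnamed lists use each series' `lead` field).
#' @return the selected lead name.
#' @export
select_lead <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  leads <- names(candidates)
  if (is.null(leads)) leads <- vapply(candidates, function(b) b$lead, "")
  n_det <- vapply(candidates, n_beats, integer(1))
  n_abn <- vapply(candidates, function(b) sum(b$labels == "A"), integer(1))
  prio <- match(leads, c("II", "I", "V6"))
  prio[is.na(prio)] <- 3 + seq_len(sum(is.na(prio)))
  ord <- order(-n_det, n_abn, prio)
  leads[ord[1]]
}

#' Summarize beat and ST counts for one record
#'
#' Abnormal percentage uses all beats as denominator, `100 A / (N + A)`;
#' ST percentage uses normal beats only, `100 ST / N`. Percentages are
#' rounded to three decimals.
#'
#' @param bs a classified, ST-flagged [beat_series()].
#' @return list with `n_normal`, `n_abnormal`, `pct_abnormal`, `n_st`,
#'   `pct_st`.
#' @export
summarize_beats <- function(bs) {
  if (inherits(bs, "beat_series")) {
    n_n <- sum(bs$labels == "N")
    n_a <- sum(bs$labels == "A")
    n_st <- sum(bs$st_dev %in% TRUE)
  } else stop("summarize_beats needs a beat_series", call. = FALSE)
  beat_summary(n_n, n_a, n_st)
}

#' Beat summary from raw counts
#'
#' The percentage conventions of [summarize_beats()] applied to explicit
#' counts (useful when tabulating externally reported counts).
#'
#' @param n_normal,n_abnormal,n_st counts of normal beats, abnormal beats and
#'   ST-deviating (normal) beats.
#' @return list with `n_normal`, `n_abnormal`, `pct_abnormal`, `n_st`,
#'   `pct_st`.
#' @export
beat_summary <- function(n_normal, n_abnormal, n_st) {
  total <- n_normal + n_abnormal
  if (total == 0) stop("zero beats: nothing to summarize", call. = FALSE)
  list(n_normal = n_normal, n_abnormal = n_abnormal,
       pct_abnormal = round(100 * n_abnormal / total, 3),
       n_st = n_st,
       pct_st = if (n_normal > 0) round(100 * n_st / n_normal, 3) else NA_real_)
}

#' Override a detected series with ground-truth annotations
#'
#' Models the study's manual verification/editing step as a non-interactive
#' hook: detected R/Q/T locations and labels are replaced by the reference
#' annotation stream.
#'
#' @param bs a [beat_series()] (provides lead, sampling rate, clock).
#' @param truth an `ecg_ground_truth` (see [generate_ecg()]).
#' @return a [beat_series()] carrying the reference annotations.
#' @export
apply_ground_truth <- function(bs, truth) {
  stopifnot(inherits(bs, "beat_series"), inherits(truth, "ecg_ground_truth"))
  fs <- bs$fs_hz
  beat_series(bs$lead,
              r_idx = round(truth$r_times_s * fs) + 1,
              q_idx = round(truth$q_times_s * fs) + 1,
              t_idx = round(truth$t_times_s * fs) + 1,
              labels = truth$labels,
              st_dev = ifelse(truth$labels == "N", truth$st_flags, NA),
              fs_hz = fs, start_clock = bs$start_clock)
}

#' Write beat annotations to CSV
#'
#' Columns: `sample_idx` (0-based), `clock_time`, `label`, `st_flag`.
#'
#' @param bs a [beat_series()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_annotations_csv <- function(bs, path) {
  stopifnot(inherits(bs, "beat_series"))
  df <- data.frame(sample_idx = bs$r_idx - 1,
                   clock_time = format_clock(bs$start_clock + beat_times(bs)),
                   label = bs$labels,
                   st_flag = as.integer(bs$st_dev))
  data.table::fwrite(df, path)
  invisible(path)
}
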