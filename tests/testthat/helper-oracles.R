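# Independent oracles used across the suite. These deliberately use the most
# direct (brute-force / enumeration) formulation so they stay independent of
# the implementation paths they check.

# Exhaustive subsegment selector: every candidate start at 1-s resolution,
# every threshold, straight counting over the beat times.
brute_force_select <- function(times, labels, duration_s,
                               segment_s = 1200, subsegment_s = 300,
                               gap_s = 600, max_thr = 5) {
  n_seg <- floor(duration_s / segment_s)
  prev_end <- -Inf
  out <- data.frame()
  for (k in seq_len(n_seg) - 1) {
    seg_start <- k * segment_s
    starts <- seq(seg_start, seg_start + segment_s - subsegment_s, by = 1)
    # abnormal fraction for every start (0 when the window holds no beats)
    fr <- vapply(starts, function(s) {
      inw <- times >= s & times < s + subsegment_s
      if (!any(inw)) 0 else mean(labels[inw] == "A")
    }, numeric(1))
    sel <- NULL
    for (thr in seq_len(max_thr)) {
      ok <- fr < thr / 100 & starts >= prev_end + gap_s
      if (any(ok)) { sel <- list(s = starts[which(ok)[1]], thr = thr); break }
    }
    if (is.null(sel)) {
      out <- rbind(out, data.frame(segment_index = k, start_s = NA,
                                   threshold_used = NA, accepted = FALSE))
    } else {
      out <- rbind(out, data.frame(segment_index = k, start_s = sel$s,
                                   threshold_used = sel$thr, accepted = TRUE))
      prev_end <- sel$s + subsegment_s
    }
  }
  out
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns.
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- as.matrix(patterns) %*% r
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# pNN50 by explicit pair loop.
pnn50_brute <- function(nn) {
  cnt <- 0
  for (i in seq_len(length(nn) - 1))
    if (abs(nn[i + 1] - nn[i]) > 50) cnt <- cnt + 1
  100 * cnt / length(nn)
}

# Match detected R times to truth within a tolerance; returns sensitivity
# and positive predictive value.
detector_performance <- function(detected_s, truth_s, tol_s = 0.05) {
  if (!length(detected_s)) return(list(sens = 0, ppv = NA_real_))
  hit <- vapply(truth_s, function(t) any(abs(detected_s - t) <= tol_s), logical(1))
  used <- vapply(detected_s, function(t) any(abs(truth_s - t) <= tol_s), logical(1))
  list(sens = mean(hit), ppv = mean(used))
}

# Random annotation stream (beat times + N/A labels) for selector tests.
random_annotation_stream <- function(duration_s, mean_rr_s = 0.8,
                                     rate = 0.02, cluster = NULL) {
  t <- cumsum(stats::rexp(ceiling(duration_s / mean_rr_s * 1.6), 1 / mean_rr_s))
  t <- t[t < duration_s]
  lab <- ifelse(stats::runif(length(t)) < rate, "A", "N")
  if (!is.null(cluster)) {
    inc <- t >= cluster[1] & t <= cluster[2]
    lab[inc] <- ifelse(stats::runif(sum(inc)) < cluster[3], "A", lab[inc])
  }
  list(times = t, labels = lab)
}

# beat_series from plain times/labels at a given sampling rate
bs_from_times <- function(times, labels, fs = 200, start_clock = 0) {
  idx <- round(times * fs) + 1
  keep <- !duplicated(idx)
  beat_series("II", idx[keep], labels = labels[keep], fs_hz = fs,
              start_clock = start_clock)
}
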