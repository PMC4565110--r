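# Night-window extraction and selection of twelve 5-min subsegments.
#
# The analysis window is defined in clock time (default 00:00-04:00). Each
# 20-min segment of the window contributes one 5-min subsegment: the earliest
# window (1 s scan step) whose abnormal-beat fraction is below an escalating
# threshold (1%..5%) and which starts at least 10 min after the end of the
# previously accepted subsegment. All windows are half-open [start, end).

#' Restrict a beat series to the night-time analysis window
#'
#' @param bs a [beat_series()] whose `start_clock` matches the record.
#' @param rec the parent [ecg_record()] (defines coverage).
#' @param window_clock length-2 vector of window bounds, clock times
#'   (default `c("00:00", "04:00")`).
#' @return a [beat_series()] containing only beats whose R peak lies in the
#'   window, with sample indices re-based so sample 1 falls at the window
#'   start and `start_clock` set to the window start.
#' @export
extract_night_window <- function(bs, rec, window_clock = c("00:00", "04:00")) {
  stopifnot(inherits(bs, "beat_series"), inherits(rec, "ecg_record"))
  w0 <- parse_clock(window_clock[1])
  w1 <- parse_clock(window_clock[2])
  wlen <- (w1 - w0) %% 86400
  if (wlen == 0) wlen <- 86400
  dur <- ecg_duration(rec)
  offset <- (w0 - rec$start_clock) %% 86400   # record time at which the window opens
  if (offset + wlen > dur + 1e-9)
    stop(sprintf(paste0("record does not cover the analysis window %s-%s: ",
                        "window opens %.0f s into the record but the record ",
                        "ends at %.0f s"),
                 format_clock(w0), format_clock(w1), offset, dur), call. = FALSE)
  t <- beat_times(bs)
  keep <- t >= offset & t < offset + wlen
  shift <- round(offset * bs$fs_hz)
  beat_series(bs$lead,
              r_idx = bs$r_idx[keep] - shift,
              q_idx = bs$q_idx[keep] - shift,
              t_idx = bs$t_idx[keep] - shift,
              labels = bs$labels[keep], st_dev = bs$st_dev[keep],
              fs_hz = bs$fs_hz, start_clock = w0)
}

# beats with R peak in [s, e), half-open, from a sorted time vector
.count_in <- function(times, s, e) {
  findInterval(e - 1e-9, times) - findInterval(s - 1e-9, times)
}

#' Select one 5-min subsegment from each 20-min segment
#'
#' Scans each 20-min segment from its beginning in 1 s steps for the first
#' 5-min window with an abnormal-heartbeat fraction strictly below the
#' threshold (starting at 1%) that also starts at least 10 min after the end
#' of the previously accepted subsegment; if a segment yields nothing the
#' threshold is raised in 1% increments up to 5%, and a segment infeasible
#' even at 5% is returned with `accepted = FALSE`.
#'
#' @param bs a [beat_series()] re-based to the analysis window (see
#'   [extract_night_window()]).
#' @param duration_s length of the analysis window in seconds (default 4 h).
#' @param segment_s,subsegment_s,gap_s segment length, subsegment length and
#'   required gap between accepted subsegments, in seconds.
#' @param max_threshold_pct escalation cap in percent (default 5).
#' @param scan_step_s scan resolution in seconds (default 1).
#' @return data.frame with one row per segment: `segment_index` (0-based),
#'   `start_s`, `end_s` (window-relative), `start_clock`, `end_clock`,
#'   `threshold_used` (percent, NA when not accepted), `n_beats`,
#'   `n_abnormal`, `accepted`.
#' @export
select_subsegments <- function(bs, duration_s = 14400,
                               segment_s = 1200, subsegment_s = 300,
                               gap_s = 600, max_threshold_pct = 5,
                               scan_step_s = 1) {
  stopifnot(inherits(bs, "beat_series"))
  times <- beat_times(bs)
  abn_times <- times[bs$labels == "A"]
  n_seg <- floor(duration_s / segment_s)
  prev_end <- -Inf
  rows <- vector("list", n_seg)
  for (k in seq_len(n_seg) - 1L) {
    seg_start <- k * segment_s
    starts <- seq(seg_start, seg_start + segment_s - subsegment_s,
                  by = scan_step_s)
    found <- FALSE
    for (thr in seq_len(max_threshold_pct)) {
      for (s in starts) {
        if (s < prev_end + gap_s) next
        nb <- .count_in(times, s, s + subsegment_s)
        na_ <- .count_in(abn_times, s, s + subsegment_s)
        frac <- if (nb > 0) na_ / nb else 0
        if (frac < thr / 100) {
          rows[[k + 1L]] <- data.frame(
            segment_index = k, start_s = s, end_s = s + subsegment_s,
            start_clock = format_clock(bs$start_clock + s),
            end_clock = format_clock(bs$start_clock + s + subsegment_s),
            threshold_used = thr, n_beats = nb, n_abnormal = na_,
            accepted = TRUE)
          prev_end <- s + subsegment_s
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) {
      rows[[k + 1L]] <- data.frame(
        segment_index = k, start_s = NA_real_, end_s = NA_real_,
        start_clock = NA_character_, end_clock = NA_character_,
        threshold_used = NA_integer_,
        n_beats = .count_in(times, seg_start, seg_start + segment_s),
        n_abnormal = .count_in(abn_times, seg_start, seg_start + segment_s),
        accepted = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract the beats of one selected subsegment
#'
#' @param bs the window-based [beat_series()].
#' @param selection one row of the [select_subsegments()] data.frame.
#' @return a [beat_series()] of the beats whose R peak lies in the
#'   subsegment (indices kept window-relative).
#' @export
subsegment_beats <- function(bs, selection) {
  stopifnot(inherits(bs, "beat_series"), isTRUE(selection$accepted))
  t <- beat_times(bs)
  keep <- t >= selection$start_s & t < selection$end_s
  beat_series(bs$lead, bs$r_idx[keep], bs$q_idx[keep], bs$t_idx[keep],
              bs$labels[keep], bs$st_dev[keep], fs_hz = bs$fs_hz,
              start_clock = bs$start_clock)
}
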