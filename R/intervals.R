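# Peak-to-peak QT intervals and their rate-corrected values.
#
# ppQT is the Q-peak to T-peak interval of a normal beat; ppQTc divides it by
# the square root of the preceding normal-to-normal RR interval in seconds
# (the Bazett convention applied to peak-to-peak intervals), so a ppQT in ms
# yields a ppQTc numerically in ms.

#' Compute per-beat ppQT and ppQTc intervals
#'
#' A beat is eligible when it is normal, has located Q and T peaks, and its
#' preceding beat is also normal (so the preceding RR is a true NN interval).
#' Ineligible beats are skipped and counted.
#'
#' @param bs a classified [beat_series()].
#' @return object of class `qt_series`: data.frame with `t_s` (R-peak time),
#'   `ppqt_ms`, `rr_s`, `ppqtc_ms`; attribute `n_skipped`. An empty result
#'   raises a warning (mirrors records too noisy for QT assessment).
#' @export
compute_ppqtc <- function(bs) {
  stopifnot(inherits(bs, "beat_series"))
  nb <- n_beats(bs)
  fs <- bs$fs_hz
  if (nb >= 2) {
    i <- 2:nb
    ok <- bs$labels[i] == "N" & bs$labels[i - 1] == "N" &
      !is.na(bs$q_idx[i]) & !is.na(bs$t_idx[i])
    i <- i[ok]
  } else i <- integer(0)
  df <- data.frame(t_s = (bs$r_idx[i] - 1) / fs,
                   ppqt_ms = (bs$t_idx[i] - bs$q_idx[i]) / fs * 1000,
                   rr_s = (bs$r_idx[i] - bs$r_idx[i - 1]) / fs)
  df$ppqtc_ms <- df$ppqt_ms / sqrt(df$rr_s)
  attr(df, "n_skipped") <- nb - nrow(df)
  class(df) <- c("qt_series", "data.frame")
  if (nrow(df) == 0)
    warning("no eligible beats for ppQTc (noisy or all-abnormal segment)")
  df
}

#' Median ppQTc over a set of beats
#'
#' The per-patient summary statistic: the median ppQTc over all eligible
#' beats of the selected subsegments (even-count medians are the mean of the
#' middle two values).
#'
#' @param qs a `qt_series` from [compute_ppqtc()], or several row-bound ones.
#' @return median ppQTc in ms.
#' @export
summarize_ppqtc <- function(qs) {
  if (nrow(qs) == 0) stop("empty QT series: no eligible beats", call. = FALSE)
  median_mid(qs$ppqtc_ms)
}

#' ppQTc over the selected subsegments of a record
#'
#' @param bs the window-based [beat_series()].
#' @param selections the [select_subsegments()] table.
#' @return a `qt_series` combining all accepted subsegments.
#' @export
ppqtc_for_selections <- function(bs, selections) {
  acc <- selections[selections$accepted, , drop = FALSE]
  parts <- lapply(seq_len(nrow(acc)), function(i)
    suppressWarnings(compute_ppqtc(subsegment_beats(bs, acc[i, ]))))
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- compute_ppqtc(beat_series(bs$lead, numeric(0),
                                                     fs_hz = bs$fs_hz))
  n_sk <- sum(vapply(parts, function(p) attr(p, "n_skipped"), numeric(1)))
  attr(out, "n_skipped") <- n_sk
  class(out) <- c("qt_series", "data.frame")
  out
}
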