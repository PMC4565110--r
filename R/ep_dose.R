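# Electroporation pulse dose quantification.
#
# From recorded V/I waveforms: pulses are detected by amplitude thresholding;
# the representative voltage/current of a train is the median over its pulses
# of the within-pulse plateau mean; a tumor's average is the median of its
# train medians; energy is the integral of instantaneous power V(t) I(t) over
# all detected pulses. Per patient: energies sum over tumors, voltage and
# current take the per-tumor maxima.

#' Detect pulse boundaries in a waveform
#'
#' Maximal runs of samples where `|V|` is at least `v_threshold_frac` of the
#' waveform's peak `|V|`; runs separated by less than `merge_gap_us` are
#' merged.
#'
#' @param rec a [pulse_train_record()].
#' @param v_threshold_frac detection threshold as a fraction of peak voltage
#'   (default 0.1).
#' @param merge_gap_us gap below which adjacent runs merge, in microseconds.
#' @return data.frame with `start_idx`, `end_idx` (1-based, inclusive); empty
#'   with a warning when no pulses are present.
#' @export
pulse_boundaries <- function(rec, v_threshold_frac = 0.1, merge_gap_us = 10) {
  stopifnot(inherits(rec, "pulse_train_record"))
  v <- abs(rec$voltage_v)
  pk <- max(v)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0))
  if (pk == 0) {
    warning("no pulses found: zero waveform")
    return(empty)
  }
  on <- v >= v_threshold_frac * pk
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_idx = starts[r$values], end_idx = ends[r$values])
  if (nrow(runs) == 0) {
    warning("no pulses found above threshold")
    return(empty)
  }
  # merge runs separated by less than merge_gap_us
  gap_s <- merge_gap_us * 1e-6
  out <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      prev_end_t <- rec$time_s[out$end_idx[nrow(out)]]
      if (rec$time_s[runs$start_idx[i]] - prev_end_t < gap_s) {
        out$end_idx[nrow(out)] <- runs$end_idx[i]
      } else {
        out <- rbind(out, runs[i, ])
      }
    }
  }
  rownames(out) <- NULL
  out
}

# per-pulse plateau means and trapezoidal pulse energies for one train
.train_pulse_stats <- function(rec, v_threshold_frac = 0.1) {
  b <- pulse_boundaries(rec, v_threshold_frac)
  if (nrow(b) == 0) return(NULL)
  v_mean <- numeric(nrow(b)); i_mean <- numeric(nrow(b)); e <- numeric(nrow(b))
  for (p in seq_len(nrow(b))) {
    idx <- b$start_idx[p]:b$end_idx[p]
    v_mean[p] <- mean(rec$voltage_v[idx])
    i_mean[p] <- mean(rec$current_a[idx])
    e[p] <- trapz(rec$time_s[idx], rec$voltage_v[idx] * rec$current_a[idx])
  }
  list(n_pulses = nrow(b), v_mean = v_mean, i_mean = i_mean, energy_j = sum(e))
}

#' Dose delivered to one tumor
#'
#' @param trains list of [pulse_train_record()] for one tumor.
#' @param v_threshold_frac pulse-detection threshold fraction.
#' @return object of class `tumor_dose`: `tumor_id`, `n_pulses`,
#'   `avg_voltage_v`, `avg_current_a` (median over trains of the per-train
#'   median of within-pulse means), `energy_j`.
#' @export
tumor_dose <- function(trains, v_threshold_frac = 0.1) {
  if (!length(trains)) stop("need at least one pulse train", call. = FALSE)
  stats_list <- lapply(trains, .train_pulse_stats, v_threshold_frac = v_threshold_frac)
  bad <- vapply(stats_list, is.null, logical(1))
  if (any(bad)) {
    warning(sprintf("%d train(s) with no detectable pulses excluded", sum(bad)))
    stats_list <- stats_list[!bad]
  }
  if (!length(stats_list)) stop("no trains with detectable pulses", call. = FALSE)
  train_med_v <- vapply(stats_list, function(s) median_mid(s$v_mean), numeric(1))
  train_med_i <- vapply(stats_list, function(s) median_mid(s$i_mean), numeric(1))
  structure(list(tumor_id = trains[[which(!bad)[1]]]$tumor_id,
                 n_pulses = sum(vapply(stats_list, `[[`, numeric(1), "n_pulses")),
                 avg_voltage_v = median_mid(train_med_v),
                 avg_current_a = median_mid(train_med_i),
                 energy_j = sum(vapply(stats_list, `[[`, numeric(1), "energy_j"))),
            class = "tumor_dose")
}

#' Tumor dose from pre-computed summary values
#'
#' For tabulating externally reported per-tumor values (e.g. device logs)
#' without waveforms.
#'
#' @param tumor_id identifier.
#' @param n_pulses,avg_voltage_v,avg_current_a,energy_j summary values.
#' @return a `tumor_dose`.
#' @export
tumor_dose_from_summary <- function(tumor_id, n_pulses = NA_real_,
                                    avg_voltage_v = NA_real_,
                                    avg_current_a = NA_real_, energy_j) {
  structure(list(tumor_id = tumor_id, n_pulses = n_pulses,
                 avg_voltage_v = avg_voltage_v, avg_current_a = avg_current_a,
                 energy_j = energy_j), class = "tumor_dose")
}

#' @export
print.tumor_dose <- function(x, ...) {
  cat(sprintf("Tumor %s: %s pulses, %.0f V / %.2f A (avg), %.1f J\n",
              x$tumor_id, format(x$n_pulses), x$avg_voltage_v,
              x$avg_current_a, x$energy_j))
  invisible(x)
}

#' Dose delivered to one patient
#'
#' Total energy is the sum over tumors; the representative voltage and
#' current are the largest per-tumor averages (the values carried into the
#' dose-response statistics when several tumors were treated).
#'
#' @param tumors list of `tumor_dose`.
#' @param patient_id identifier.
#' @return object of class `patient_dose`: `patient_id`, `tumors`,
#'   `total_pulses`, `max_avg_voltage_v`, `max_avg_current_a`,
#'   `total_energy_j`.
#' @export
patient_dose <- function(tumors, patient_id = NA_character_) {
  if (!length(tumors)) stop("need at least one tumor", call. = FALSE)
  stopifnot(all(vapply(tumors, inherits, logical(1), "tumor_dose")))
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  structure(list(patient_id = patient_id, tumors = tumors,
                 total_pulses = sum(vapply(tumors, `[[`, numeric(1), "n_pulses")),
                 max_avg_voltage_v = max_or_na(vapply(tumors, `[[`, numeric(1),
                                                      "avg_voltage_v")),
                 max_avg_current_a = max_or_na(vapply(tumors, `[[`, numeric(1),
                                                      "avg_current_a")),
                 total_energy_j = sum(vapply(tumors, `[[`, numeric(1),
                                             "energy_j"))),
            class = "patient_dose")
}

#' @export
print.patient_dose <- function(x, ...) {
  cat(sprintf("Patient %s dose: %d tumor(s), %s pulses, max %.0f V / %.2f A, total %.1f J\n",
              x$patient_id, length(x$tumors), format(x$total_pulses),
              x$max_avg_voltage_v, x$max_avg_current_a, x$total_energy_j))
  invisible(x)
}

#' Per-patient dose from grouped pulse-train records
#'
#' Groups a flat list of [pulse_train_record()] by tumor and computes the
#' [patient_dose()].
#'
#' @param trains list of [pulse_train_record()] sharing one `patient_id`.
#' @param v_threshold_frac pulse-detection threshold fraction.
#' @return a `patient_dose`.
#' @export
patient_dose_from_trains <- function(trains, v_threshold_frac = 0.1) {
  if (!length(trains)) stop("need at least one pulse train", call. = FALSE)
  pid <- trains[[1]]$patient_id
  tum <- split(trains, vapply(trains, `[[`, "", "tumor_id"))
  patient_dose(lapply(tum, tumor_dose, v_threshold_frac = v_threshold_frac),
               patient_id = pid)
}

#' Dose report table
#'
#' @param doses list of `patient_dose`.
#' @return data.frame with one row per tumor plus per-patient totals columns.
#' @export
dose_report <- function(doses) {
  rows <- lapply(doses, function(pd) {
    do.call(rbind, lapply(pd$tumors, function(td)
      data.frame(patient_id = pd$patient_id, tumor_id = td$tumor_id,
                 n_pulses = td$n_pulses, avg_voltage_v = td$avg_voltage_v,
                 avg_current_a = td$avg_current_a, energy_j = td$energy_j,
                 total_pulses = pd$total_pulses,
                 max_avg_voltage_v = pd$max_avg_voltage_v,
                 max_avg_current_a = pd$max_avg_current_a,
                 total_energy_j = pd$total_energy_j)))
  })
  do.call(rbind, rows)
}
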