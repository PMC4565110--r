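# Cohort-level summary simulator.
#
# Draws per-patient summary measures (median ppQTc + the 13 HRV measures)
# for paired before/after sessions, for calibrating the statistical stage
# (type-I rate and power of the change table) without re-synthesizing raw
# ECG for every replicate. Between-patient and within-patient (night-to-
# night) variabilities are set to magnitudes typical of post-operative
# night-time recordings; derived measures (SD1/SD2 ratio, normalized band
# powers, LF/HF) are computed from the drawn primaries so their identities
# hold exactly.

# name: c(population mean, between-patient SD, within-patient change SD)
.cohort_priors <- list(
  mean_ppqtc_ms = c(410, 30, 15),
  mean_nn_ms    = c(850, 120, 60),
  sdnn_ms       = c(50, 15, 8),
  sdsd_ms       = c(30, 10, 6),
  rmssd_ms      = c(31, 10, 6),
  pnn50_pct     = c(8, 5, 3),
  sd1_ms        = c(22, 7, 4),
  sd2_ms        = c(65, 20, 10),
  lf_ms2        = c(400, 150, 80),
  hf_ms2        = c(200, 80, 50)
)

#' Simulate per-patient paired summary measures for a cohort
#'
#' Each patient's "before" value of a primary measure is drawn from the
#' population distribution; the "after" value adds within-patient night-to-
#' night noise plus any configured treatment effect (so with no effect the
#' cohort is an exact null for the paired comparison). Derived measures
#' (`sd1_sd2`, `nlf_nu`, `nhf_nu`, `lf_hf`) are computed from the primaries.
#'
#' @param n_patients cohort size.
#' @param effect named list of additive shifts applied to "after" primary
#'   measures (e.g. `list(mean_nn_ms = -150)`); empty for a null cohort.
#' @param seed RNG seed.
#' @return list of per-patient entries in the format [build_tables()]
#'   expects (without `beat_summary`/`dose` components).
#' @export
simulate_cohort_measures <- function(n_patients = 10, effect = list(),
                                     seed = 1L) {
  bad <- setdiff(names(effect), names(.cohort_priors))
  if (length(bad))
    stop("unknown effect measure(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pr <- .cohort_priors
  nms <- names(pr)
  floors <- vapply(pr, function(x) 0.05 * x[1], numeric(1))
  session_of <- function(v) {
    hrv <- c(v[c("mean_nn_ms", "sdnn_ms", "sdsd_ms", "rmssd_ms",
                 "pnn50_pct", "sd1_ms", "sd2_ms")],
             sd1_sd2 = unname(v["sd1_ms"] / v["sd2_ms"]),
             lf_ms2 = unname(v["lf_ms2"]), hf_ms2 = unname(v["hf_ms2"]))
    nlf <- unname(100 * v["lf_ms2"] / (v["lf_ms2"] + v["hf_ms2"]))
    hrv <- c(hrv, nlf_nu = nlf, nhf_nu = 100 - nlf,
             lf_hf = unname(v["lf_ms2"] / v["hf_ms2"]))
    list(ppqtc_median = unname(v["mean_ppqtc_ms"]), hrv = hrv)
  }
  with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      base <- vapply(nms, function(nm) stats::rnorm(1, pr[[nm]][1],
                                                    pr[[nm]][2]), numeric(1))
      base <- pmax(base, floors)
      within <- vapply(nms, function(nm) stats::rnorm(1, 0, pr[[nm]][3]),
                       numeric(1))
      eff <- vapply(nms, function(nm)
        if (!is.null(effect[[nm]])) effect[[nm]] else 0, numeric(1))
      aft <- pmax(base + within + eff, floors)
      list(patient_id = sprintf("P%02d", i),
           before = session_of(base), after = session_of(aft))
    })
  })
}
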