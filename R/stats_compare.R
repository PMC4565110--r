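# Before/after comparison statistics.
#
# Per-patient paired changes are tested with an exact two-sided Wilcoxon
# signed-rank test (zero differences dropped, tied absolute differences get
# average ranks; the exact null distribution is computed by convolution over
# doubled ranks, so ties stay exact). Associations between changes and EP
# pulse-delivery parameters use ordinary least-squares regression.

#' Paired Wilcoxon signed-rank comparison
#'
#' Changes are `after - before` per patient. Zero differences are dropped
#' (Wilcoxon's original treatment); tied absolute differences receive average
#' ranks. The two-sided p-value is exact: the null distribution of the
#' positive-rank sum is built by convolution over the doubled ranks, which
#' keeps average ranks integral. Quartiles of the changes use linear
#' interpolation between order statistics.
#'
#' @param before,after equal-length per-patient value vectors.
#' @param exact_max largest n for which the exact distribution is used
#'   (beyond it a normal approximation with tie correction applies).
#' @return list with `median_change`, `pct25`, `pct75`, `p_value`,
#'   `w_statistic`, `n_used` (pairs after dropping zeros) and `note`.
#' @export
paired_wilcoxon <- function(before, after, exact_max = 50) {
  if (length(before) != length(after))
    stop("before and after must be paired (equal length)", call. = FALSE)
  keep <- !(is.na(before) | is.na(after))
  d_all <- (after - before)[keep]
  if (!length(d_all)) stop("no complete pairs", call. = FALSE)
  q <- stats::quantile(d_all, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  d <- d_all[d_all != 0]
  n <- length(d)
  if (n == 0) {
    return(list(median_change = q[2], pct25 = q[1], pct75 = q[3], p_value = 1,
                w_statistic = 0, n_used = 0L,
                note = "all differences zero; p set to 1"))
  }
  if (n < 5)
    stop(sprintf(paste0("need at least 5 non-zero paired differences for the ",
                        "signed-rank test (have %d)"), n), call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))        # doubled ranks are exact integers
  if (n <= exact_max) {
    # P(W2 = s) by convolution: each rank enters the sum with prob 1/2
    s_max <- sum(r2)
    f <- c(1, numeric(s_max))
    for (rk in r2) {
      g <- f / 2
      g[(rk + 1):(s_max + 1)] <- g[(rk + 1):(s_max + 1)] + f[1:(s_max + 1 - rk)] / 2
      f <- g
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(s_max + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    note <- NA_character_
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum((table(r2)^3 - table(r2)) / 48)
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    note <- "normal approximation (n beyond exact limit)"
  }
  list(median_change = q[2], pct25 = q[1], pct75 = q[3], p_value = p,
       w_statistic = w, n_used = n, note = note)
}

#' Regression of per-patient changes on a dose parameter
#'
#' Ordinary least squares of `delta` on `dose`, reporting the slope, the
#' Pearson correlation and the two-sided t-test p-value on the slope.
#'
#' @param delta per-patient changes.
#' @param dose per-patient EP pulse-delivery parameter.
#' @return list with `slope`, `r`, `p_value`, `n`.
#' @export
regress_changes <- function(delta, dose) {
  keep <- !(is.na(delta) | is.na(dose))
  delta <- delta[keep]; dose <- dose[keep]
  n <- length(delta)
  if (n < 3) stop("need at least 3 complete pairs for regression", call. = FALSE)
  if (stats::var(dose) == 0) stop("zero variance in dose parameter", call. = FALSE)
  fit <- stats::lm(delta ~ dose)
  sm <- summary(fit)$coefficients
  slope <- sm["dose", "Estimate"]
  se <- sm["dose", "Std. Error"]
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, r = stats::cor(delta, dose), p_value = p, n = n)
}

#' Build the three study report tables
#'
#' From per-patient analysis results, produces: the per-patient beat/ST
#' summary (normal and abnormal counts with the `100 A/(N+A)` and `100 ST/N`
#' percentage conventions, plus a column-sum summary row); the table of
#' median before/after changes with quartiles and exact signed-rank p-values
#' for mean ppQTc and the 13 HRV measures; and the regression grid of
#' {change in mean NN, LF, nLF, nHF} against {number of delivered pulses,
#' largest average voltage, largest average current, total energy}.
#'
#' @param patients list of per-patient entries, each a list with
#'   `patient_id`, `before`, `after` (each a session result: `beat_summary`,
#'   `ppqtc_median`, `hrv` named vector of the 13 measures) and optionally
#'   `dose` (a `patient_dose`). Patients missing a session are excluded with
#'   a warning.
#' @return list of data.frames `beat_table`, `change_table`, `dose_table`.
#' @export
build_tables <- function(patients) {
  has_both <- vapply(patients, function(p)
    !is.null(p$before) && !is.null(p$after), logical(1))
  if (any(!has_both)) {
    warning(sprintf("excluded patient(s) missing a session: %s",
                    paste(vapply(patients[!has_both], `[[`, "", "patient_id"),
                          collapse = ", ")))
    patients <- patients[has_both]
  }
  if (!length(patients)) stop("no patients with both sessions", call. = FALSE)

  # --- beat/ST summary (Table-3-like) ---
  beat_row <- function(p) {
    b <- p$before$beat_summary; a <- p$after$beat_summary
    data.frame(patient_id = p$patient_id,
               n_before = b$n_normal, a_before = b$n_abnormal,
               pct_a_before = b$pct_abnormal, st_before = b$n_st,
               pct_st_before = b$pct_st,
               n_after = a$n_normal, a_after = a$n_abnormal,
               pct_a_after = a$pct_abnormal, st_after = a$n_st,
               pct_st_after = a$pct_st)
  }
  with_counts <- vapply(patients, function(p)
    !is.null(p$before$beat_summary) && !is.null(p$after$beat_summary),
    logical(1))
  beat_table <- do.call(rbind, lapply(patients[with_counts], beat_row))
  if (is.null(beat_table))
    beat_table <- data.frame()
  if (nrow(beat_table) > 0) {
  sb <- beat_summary(sum(beat_table$n_before), sum(beat_table$a_before),
                     sum(beat_table$st_before))
  sa <- beat_summary(sum(beat_table$n_after), sum(beat_table$a_after),
                     sum(beat_table$st_after))
  beat_table <- rbind(beat_table, data.frame(
    patient_id = "summary",
    n_before = sb$n_normal, a_before = sb$n_abnormal,
    pct_a_before = sb$pct_abnormal, st_before = sb$n_st,
    pct_st_before = sb$pct_st,
    n_after = sa$n_normal, a_after = sa$n_abnormal,
    pct_a_after = sa$pct_abnormal, st_after = sa$n_st,
    pct_st_after = sa$pct_st))
  }

  # --- before/after change table (Table-4-like) ---
  params <- c("mean_ppqtc_ms", hrv_measure_names())
  get_param <- function(p, session, nm) {
    s <- p[[session]]
    if (nm == "mean_ppqtc_ms") s$ppqtc_median else unname(s$hrv[nm])
  }
  change_rows <- lapply(params, function(nm) {
    bef <- vapply(patients, get_param, numeric(1), session = "before", nm = nm)
    aft <- vapply(patients, get_param, numeric(1), session = "after", nm = nm)
    res <- tryCatch(paired_wilcoxon(bef, aft), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("change table row '%s': %s", nm, conditionMessage(res)))
      return(data.frame(parameter = nm, median_change = NA_real_,
                        pct25 = NA_real_, pct75 = NA_real_, p_value = NA_real_,
                        significant = NA, note = conditionMessage(res)))
    }
    data.frame(parameter = nm, median_change = res$median_change,
               pct25 = res$pct25, pct75 = res$pct75, p_value = res$p_value,
               significant = !is.na(res$p_value) && res$p_value < 0.05,
               note = res$note)
  })
  change_table <- do.call(rbind, change_rows)

  # --- dose-response regression grid (Table-5-like) ---
  dose_table <- NULL
  has_dose <- vapply(patients, function(p) !is.null(p$dose), logical(1))
  if (all(has_dose)) {
    delta_params <- c(mean_nn_ms = "mean_nn_ms", lf_ms2 = "lf_ms2",
                      nlf_nu = "nlf_nu", nhf_nu = "nhf_nu")
    dose_params <- c(n_pulses = "total_pulses",
                     avg_voltage_v = "max_avg_voltage_v",
                     avg_current_a = "max_avg_current_a",
                     total_energy_j = "total_energy_j")
    rows <- list()
    for (dp in names(delta_params)) {
      bef <- vapply(patients, get_param, numeric(1), "before", delta_params[[dp]])
      aft <- vapply(patients, get_param, numeric(1), "after", delta_params[[dp]])
      delta <- aft - bef
      for (ep in names(dose_params)) {
        dose <- vapply(patients, function(p) p$dose[[dose_params[[ep]]]], numeric(1))
        res <- tryCatch(regress_changes(delta, dose), error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(delta_parameter = dp, dose_parameter = ep,
                     slope = NA_real_, r = NA_real_, p_value = NA_real_,
                     note = conditionMessage(res))
        } else {
          data.frame(delta_parameter = dp, dose_parameter = ep,
                     slope = res$slope, r = res$r, p_value = res$p_value,
                     note = NA_character_)
        }
      }
    }
    dose_table <- do.call(rbind, rows)
  }

  list(beat_table = beat_table, change_table = change_table,
       dose_table = dose_table)
}
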