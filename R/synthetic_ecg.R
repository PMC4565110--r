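# Synthetic Holter-like ECG with analytically known beat locations.
#
# Each heartbeat is a sum-of-Gaussians PQRST template, so the true Q, R and T
# peak times are known exactly and serve as the oracle for the detector and
# classifier. Heart-rate modulation is injected as two sinusoids on the RR
# series (one in the LF band, one in the HF band), premature ventricular-like
# ectopic beats perturb both rhythm and morphology, and ST-level shifts and
# broadband noise are optional.

# PQRST template: per-wave (center_s, sigma_s, relative amplitude). The R
# amplitude per lead comes from .lead_amp_uv; all other waves scale with it.
.pqrst_normal <- list(
  P = c(-0.180, 0.025,  0.15),
  Q = c(-0.040, 0.010, -0.12),
  R = c( 0.000, 0.012,  1.00),
  S = c( 0.035, 0.010, -0.25),
  T = c( 0.280, 0.050,  0.35)
)

# Premature ventricular-like beat: widened QRS (x2.5), inverted T, no P wave.
.pqrst_ectopic <- list(
  Q = c(-0.040, 0.025, -0.20),
  R = c( 0.000, 0.030,  1.10),
  S = c( 0.035, 0.025, -0.45),
  T = c( 0.280, 0.050, -0.35)
)

# R-peak amplitude (uV) by lead; values chosen so that I, II and V6 have the
# high R amplitude the detector's lead-selection rule expects.
.lead_amp_uv <- c(I = 800, II = 1200, III = 600, aVR = 400, aVL = 500,
                  aVF = 700, V1 = 500, V3 = 1000, V6 = 900)

# Evaluate code with a private seeded RNG stream, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic ECG generator
#'
#' @param duration_s record duration in seconds.
#' @param fs_hz sampling rate in Hz (the study's Holter recorder used 200).
#' @param leads character vector of lead names to synthesize; must be a
#'   subset of the built-in 9-lead set (I, II, III, aVR, aVL, aVF, V1, V3, V6).
#' @param start_clock time of day of sample 0 ("HH:MM:SS" or seconds since
#'   midnight).
#' @param mean_rr_ms mean RR interval in milliseconds.
#' @param lf_mod `c(freq_hz, amp_ms)` sinusoidal RR modulation in the low
#'   frequency band (0.04-0.15 Hz); amplitude 0 disables it.
#' @param hf_mod `c(freq_hz, amp_ms)` modulation in the high frequency band
#'   (0.15-0.4 Hz).
#' @param rr_jitter_ms standard deviation of white RR jitter in ms.
#' @param ectopic_rate probability per beat of a premature ventricular-like
#'   abnormal beat.
#' @param ectopic_pattern `"uniform"` or `list(type = "clustered", start_s,
#'   end_s)` restricting ectopy to a time window.
#' @param noise_uV RMS of additive broadband white noise per lead, in uV.
#' @param st_offset_uV constant ST-level shift (uV) added over the ST segment
#'   of affected beats.
#' @param st_fraction fraction of beats receiving the ST shift.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return an object of class `ecg_sim_config`.
#' @export
ecg_sim_config <- function(duration_s,
                           fs_hz = 200,
                           leads = names(.lead_amp_uv),
                           start_clock = "00:00:00",
                           mean_rr_ms = 800,
                           lf_mod = c(0.1, 0),
                           hf_mod = c(0.25, 0),
                           rr_jitter_ms = 0,
                           ectopic_rate = 0,
                           ectopic_pattern = "uniform",
                           noise_uV = 0,
                           st_offset_uV = 0,
                           st_fraction = 1,
                           seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) cfg_stop("duration_s", "must be > 0")
  if (!is.numeric(fs_hz) || fs_hz <= 0) cfg_stop("fs_hz", "must be > 0")
  if (!all(leads %in% names(.lead_amp_uv)))
    cfg_stop("leads", paste("unknown lead(s):",
                            paste(setdiff(leads, names(.lead_amp_uv)), collapse = ", ")))
  if (anyDuplicated(leads)) cfg_stop("leads", "duplicated lead names")
  if (length(lf_mod) != 2 || lf_mod[2] < 0) cfg_stop("lf_mod", "need c(freq_hz, amp_ms >= 0)")
  if (length(hf_mod) != 2 || hf_mod[2] < 0) cfg_stop("hf_mod", "need c(freq_hz, amp_ms >= 0)")
  if (lf_mod[2] > 0 && (lf_mod[1] < 0.04 || lf_mod[1] > 0.15))
    cfg_stop("lf_mod", "frequency outside the LF band 0.04-0.15 Hz")
  if (hf_mod[2] > 0 && (hf_mod[1] < 0.15 || hf_mod[1] > 0.4))
    cfg_stop("hf_mod", "frequency outside the HF band 0.15-0.4 Hz")
  if (ectopic_rate < 0 || ectopic_rate > 1) cfg_stop("ectopic_rate", "must be in [0, 1]")
  if (noise_uV < 0) cfg_stop("noise_uV", "must be >= 0")
  if (rr_jitter_ms < 0) cfg_stop("rr_jitter_ms", "must be >= 0")
  if (st_fraction < 0 || st_fraction > 1) cfg_stop("st_fraction", "must be in [0, 1]")
  if (mean_rr_ms <= 2 * max(lf_mod[2], hf_mod[2]))
    cfg_stop("mean_rr_ms", "must exceed twice the largest modulation amplitude")
  if (is.list(ectopic_pattern)) {
    if (!identical(ectopic_pattern$type, "clustered") ||
        is.null(ectopic_pattern$start_s) || is.null(ectopic_pattern$end_s))
      cfg_stop("ectopic_pattern", "list form needs type='clustered', start_s, end_s")
  } else if (!identical(ectopic_pattern, "uniform")) {
    cfg_stop("ectopic_pattern", "must be 'uniform' or a clustered() list")
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz, leads = leads,
                 start_clock = parse_clock(start_clock), mean_rr_ms = mean_rr_ms,
                 lf_mod = as.numeric(lf_mod), hf_mod = as.numeric(hf_mod),
                 rr_jitter_ms = rr_jitter_ms, ectopic_rate = ectopic_rate,
                 ectopic_pattern = ectopic_pattern, noise_uV = noise_uV,
                 st_offset_uV = st_offset_uV, st_fraction = st_fraction,
                 seed = as.integer(seed)),
            class = "ecg_sim_config")
}

#' Generate a synthetic ECG record with ground truth
#'
#' Builds the RR series (mean + LF sinusoid + HF sinusoid + white jitter),
#' injects ectopic beats (preceding RR shortened by 20-40%, following RR
#' lengthened to a compensatory pause), renders one sum-of-Gaussians PQRST
#' complex per beat on every requested lead, then adds ST offsets and noise.
#'
#' @param cfg an [ecg_sim_config()].
#' @return a list with components `record` (an [ecg_record()]) and `truth`
#'   (class `ecg_ground_truth`: `r_times_s`, `q_times_s`, `t_times_s`,
#'   `labels` in `{"N","A"}`, `st_flags`).
#' @export
generate_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "ecg_sim_config"))
  with_seed(cfg$seed, {
    mean_rr_s <- cfg$mean_rr_ms / 1000

    # Base RR sequence evaluated at nominal beat times (modulation phase is
    # taken at the accumulated beat time, as a cardiac oscillator would see it).
    n_max <- ceiling(cfg$duration_s / mean_rr_s * 1.6) + 8
    r_times <- numeric(n_max); rr <- numeric(n_max)
    t_cur <- mean_rr_s   # first beat not at 0 so the full template fits
    i <- 0L
    while (t_cur <= cfg$duration_s - 0.45 && i < n_max) {
      i <- i + 1L
      r_times[i] <- t_cur
      rr_i <- cfg$mean_rr_ms +
        cfg$lf_mod[2] * sin(2 * pi * cfg$lf_mod[1] * t_cur) +
        cfg$hf_mod[2] * sin(2 * pi * cfg$hf_mod[1] * t_cur) +
        (if (cfg$rr_jitter_ms > 0) stats::rnorm(1, 0, cfg$rr_jitter_ms) else 0)
      rr[i] <- rr_i / 1000
      t_cur <- t_cur + rr[i]
    }
    n <- i
    r_times <- r_times[seq_len(n)]

    # Ectopic placement: Bernoulli per beat, optionally restricted to a
    # cluster window; never on the first/last two beats and never adjacent.
    labels <- rep("N", n)
    if (cfg$ectopic_rate > 0 && n > 4) {
      eligible <- seq(3L, n - 2L)
      if (is.list(cfg$ectopic_pattern)) {
        eligible <- eligible[r_times[eligible] >= cfg$ectopic_pattern$start_s &
                             r_times[eligible] <= cfg$ectopic_pattern$end_s]
      }
      draw <- stats::runif(length(eligible)) < cfg$ectopic_rate
      ect <- eligible[draw]
      ect <- ect[c(TRUE, diff(ect) > 1)]          # no adjacent ectopics
      labels[ect] <- "A"
      # Premature timing: shift the ectopic R earlier by 20-40% of the local
      # RR; the following beat stays put, giving a compensatory pause.
      if (length(ect)) {
        prem <- stats::runif(length(ect), 0.20, 0.40)
        r_times[ect] <- r_times[ect] - prem * (r_times[ect] - r_times[ect - 1L])
      }
    }

    st_flags <- rep(FALSE, n)
    if (cfg$st_offset_uV != 0 && cfg$st_fraction > 0) {
      st_flags <- stats::runif(n) < cfg$st_fraction
    }

    q_times <- r_times + .pqrst_normal$Q[1]
    t_times <- r_times + .pqrst_normal$T[1]
    q_times[labels == "A"] <- NA_real_
    t_times[labels == "A"] <- NA_real_

    # Render the waveform once as a unit-amplitude trace, then scale per lead.
    n_samp <- floor(cfg$duration_s * cfg$fs_hz)
    tt <- seq_len(n_samp) / cfg$fs_hz - 1 / cfg$fs_hz
    unit <- numeric(n_samp)
    st_trace <- numeric(n_samp)
    half_w <- 0.45
    for (b in seq_len(n)) {
      tmpl <- if (labels[b] == "N") .pqrst_normal else .pqrst_ectopic
      i0 <- max(1L, ceiling((r_times[b] - half_w) * cfg$fs_hz))
      i1 <- min(n_samp, floor((r_times[b] + half_w) * cfg$fs_hz))
      if (i1 < i0) next
      dt <- tt[i0:i1] - r_times[b]
      seg <- 0
      for (w in tmpl) seg <- seg + w[3] * exp(-((dt - w[1])^2) / (2 * w[2]^2))
      unit[i0:i1] <- unit[i0:i1] + seg
      if (st_flags[b]) {
        j <- i0:i1
        st_trace[j[dt >= 0.040 & dt <= 0.120]] <-
          st_trace[j[dt >= 0.040 & dt <= 0.120]] + 1
      }
    }

    signals <- vector("list", length(cfg$leads))
    names(signals) <- cfg$leads
    for (ld in cfg$leads) {
      x <- .lead_amp_uv[[ld]] * unit + cfg$st_offset_uV * st_trace
      if (cfg$noise_uV > 0) x <- x + stats::rnorm(n_samp, 0, cfg$noise_uV)
      signals[[ld]] <- x
    }

    rec <- ecg_record(signals, fs_hz = cfg$fs_hz, start_clock = cfg$start_clock)
    truth <- structure(list(r_times_s = r_times, q_times_s = q_times,
                            t_times_s = t_times, labels = labels,
                            st_flags = st_flags),
                       class = "ecg_ground_truth")
    list(record = rec, truth = truth)
  })
}

#' @export
print.ecg_ground_truth <- function(x, ...) {
  cat(sprintf("ECG ground truth: %d beats (%d abnormal), %d ST-shifted\n",
              length(x$r_times_s), sum(x$labels == "A"), sum(x$st_flags)))
  invisible(x)
}

#' Write ground truth to CSV
#'
#' Columns: `time_s` (R peak), `label` (N/A), `q_s`, `t_s`, `st_flag`.
#'
#' @param truth an `ecg_ground_truth`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ecg_ground_truth"))
  df <- data.frame(time_s = truth$r_times_s, label = truth$labels,
                   q_s = truth$q_times_s, t_s = truth$t_times_s,
                   st_flag = as.integer(truth$st_flags))
  data.table::fwrite(df, path)
  invisible(path)
}
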