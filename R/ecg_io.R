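# ECG and EP waveform containers and file I/O.
#
# Conventions used throughout the package: samples are in uV, voltage in V,
# current in A, time in seconds; indices are 0-based in files and 1-based in
# R vectors; analysis windows are half-open [start, end).

#' Multi-lead ECG record
#'
#' @param signals named list of equal-length numeric vectors, one per lead,
#'   amplitudes in uV.
#' @param fs_hz sampling rate in Hz.
#' @param start_clock time of day of sample 1 ("HH:MM:SS" or seconds since
#'   midnight).
#' @param patient_id,session optional metadata; `session` is `"before"` or
#'   `"after"` (relative to the treatment) when used in a paired study.
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs_hz, start_clock = 0,
                       patient_id = NA_character_, session = NA_character_) {
  if (!is.list(signals) || is.null(names(signals)) || any(names(signals) == ""))
    stop("'signals' must be a named list of per-lead sample vectors", call. = FALSE)
  if (anyDuplicated(names(signals))) stop("lead names must be unique", call. = FALSE)
  len <- vapply(signals, length, integer(1))
  if (length(unique(len)) != 1L) stop("all leads must have the same length", call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be > 0", call. = FALSE)
  if (!is.na(session) && !session %in% c("before", "after"))
    stop("session must be 'before' or 'after'", call. = FALSE)
  structure(list(signals = lapply(signals, as.numeric), fs_hz = fs_hz,
                 lead_names = names(signals), start_clock = parse_clock(start_clock),
                 patient_id = patient_id, session = session),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat(sprintf("ECG record: %d leads (%s), %.1f s at %g Hz, start %s\n",
              length(x$lead_names), paste(x$lead_names, collapse = ", "),
              n / x$fs_hz, x$fs_hz, format_clock(x$start_clock)))
  if (!is.na(x$patient_id))
    cat(sprintf("  patient %s, session %s\n", x$patient_id, x$session))
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param rec an `ecg_record`.
#' @return numeric seconds.
#' @export
ecg_duration <- function(rec) length(rec$signals[[1]]) / rec$fs_hz

#' Write an ECG record to CSV
#'
#' Columns: `time_s` then one column per lead (uV). Samples are written with
#' three decimals (1 nV resolution relative to uV units), which is the
#' round-trip precision contract of [read_ecg()].
#'
#' @param rec an [ecg_record()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ecg <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- length(rec$signals[[1]])
  df <- data.frame(time_s = round((seq_len(n) - 1) / rec$fs_hz, 6))
  for (ld in rec$lead_names) df[[ld]] <- round(rec$signals[[ld]], 3)
  # header comment carries the metadata CSV cannot
  con <- file(path, "w")
  writeLines(sprintf("# fs_hz=%g start_clock=%s patient_id=%s session=%s",
                     rec$fs_hz, format_clock(rec$start_clock),
                     rec$patient_id, rec$session), con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an ECG record
#'
#' @param path file path; for `format = "wfdb"` the path of the `.hea` header
#'   (or its basename without extension).
#' @param format `"csv"` (as written by [write_ecg()]) or `"wfdb"` (format-16
#'   signal pair as written by [write_ecg_wfdb()]).
#' @param leads optional character vector of leads that must be present; a
#'   missing lead raises an error naming it.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), leads = NULL) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_ecg_wfdb(path, leads = leads))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    stop(sprintf("%s:1: missing '#' metadata header line", path), call. = FALSE)
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  for (k in c("fs_hz", "start_clock"))
    if (!k %in% names(meta))
      stop(sprintf("%s:1: header lacks '%s'", path, k), call. = FALSE)
  df <- data.table::fread(path, skip = 1L, data.table = FALSE)
  if (!"time_s" %in% names(df))
    stop(sprintf("%s:2: missing 'time_s' column", path), call. = FALSE)
  lead_cols <- setdiff(names(df), "time_s")
  if (!is.null(leads)) {
    miss <- setdiff(leads, lead_cols)
    if (length(miss))
      stop(sprintf("%s: missing lead column(s): %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  fs <- as.numeric(meta[["fs_hz"]])
  dt <- diff(df$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6)
    stop(sprintf("%s: non-uniform sampling detected", path), call. = FALSE)
  pid <- if ("patient_id" %in% names(meta)) meta[["patient_id"]] else NA_character_
  ses <- if ("session" %in% names(meta)) meta[["session"]] else NA_character_
  if (identical(pid, "NA")) pid <- NA_character_
  if (identical(ses, "NA")) ses <- NA_character_
  ecg_record(as.list(df[lead_cols]), fs_hz = fs,
             start_clock = meta[["start_clock"]], patient_id = pid, session = ses)
}

# ---- minimal WFDB (format 16) signal support -------------------------------
# Header (.hea) + interleaved little-endian int16 samples (.dat), gain in
# adu/mV with a fixed baseline of 0 and ADC resolution 16 bits. Covers what
# this package emits; it is not a general WFDB implementation.

#' Write an ECG record as a WFDB format-16 signal pair
#'
#' @param rec an [ecg_record()].
#' @param record_path path without extension; `.hea` and `.dat` are created.
#' @param gain adu per mV (default 200, i.e. 5 uV per adu).
#' @return `record_path`, invisibly.
#' @export
write_ecg_wfdb <- function(rec, record_path, gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  base <- sub("\\.hea$", "", record_path)
  rname <- basename(base)
  n <- length(rec$signals[[1]])
  hea <- c(sprintf("%s %d %g %d 00:00:00 01/01/2000", rname,
                   length(rec$lead_names), rec$fs_hz, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s", rname, gain, rec$lead_names),
           sprintf("# start_clock %s", format_clock(rec$start_clock)))
  writeLines(hea, paste0(base, ".hea"))
  # uV -> mV -> adu
  m <- vapply(rec$signals, function(x) as.integer(round(x / 1000 * gain)),
              integer(n))
  if (any(abs(m) > 32767)) stop("signal exceeds int16 range at this gain", call. = FALSE)
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(as.integer(t(m)), con, size = 2L, endian = "little")
  close(con)
  invisible(base)
}

#' @rdname read_ecg
#' @export
read_ecg_wfdb <- function(path, leads = NULL) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path, call. = FALSE)
  lines <- readLines(hea_path)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4)
    stop(sprintf("%s:1: unparseable WFDB header", hea_path), call. = FALSE)
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_lines <- lines[2:(1 + nsig)]
  parts <- strsplit(trimws(sig_lines), "\\s+")
  fmt <- vapply(parts, `[`, "", 2)
  if (any(fmt != "16"))
    stop(sprintf("%s: only WFDB format 16 is supported", hea_path), call. = FALSE)
  gain <- as.numeric(sub("\\(.*$", "", vapply(parts, `[`, "", 3)))
  lead_names <- vapply(parts, function(p) p[length(p)], "")
  start_clock <- 0
  cm <- grep("^# start_clock ", lines, value = TRUE)
  if (length(cm)) start_clock <- parse_clock(sub("^# start_clock ", "", cm[1]))
  if (!is.null(leads)) {
    miss <- setdiff(leads, lead_names)
    if (length(miss))
      stop(sprintf("%s: missing lead(s): %s", hea_path,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  con <- file(paste0(base, ".dat"), "rb")
  raw <- readBin(con, "integer", n = n * nsig, size = 2L, endian = "little")
  close(con)
  m <- matrix(raw, nrow = nsig)          # interleaved sample-major
  signals <- lapply(seq_len(nsig), function(i) m[i, ] / gain[i] * 1000)
  names(signals) <- lead_names
  ecg_record(signals, fs_hz = fs, start_clock = start_clock)
}

# ---- EP pulse waveform records ---------------------------------------------

#' Electroporation pulse-train waveform record
#'
#' @param time_s,voltage_v,current_a equal-length numeric vectors; time must
#'   be strictly increasing.
#' @param train_id,tumor_id,patient_id identifiers.
#' @return object of class `pulse_train_record`.
#' @export
pulse_train_record <- function(time_s, voltage_v, current_a,
                               train_id = 1L, tumor_id = "T1",
                               patient_id = NA_character_) {
  if (length(time_s) != length(voltage_v) || length(time_s) != length(current_a))
    stop("time, voltage and current must have equal length", call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time must be strictly increasing within a train", call. = FALSE)
  structure(list(time_s = as.numeric(time_s), voltage_v = as.numeric(voltage_v),
                 current_a = as.numeric(current_a), train_id = train_id,
                 tumor_id = tumor_id, patient_id = patient_id),
            class = "pulse_train_record")
}

#' @export
print.pulse_train_record <- function(x, ...) {
  cat(sprintf("EP pulse train %s/%s/%s: %d samples, %.0f V peak\n",
              x$patient_id, x$tumor_id, x$train_id, length(x$time_s),
              max(abs(x$voltage_v))))
  invisible(x)
}

#' Write EP pulse trains to CSV
#'
#' Columns: `time_s, voltage_v, current_a, train_id, tumor_id, patient_id`.
#'
#' @param trains list of [pulse_train_record()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pulse_records <- function(trains, path) {
  dfs <- lapply(trains, function(tr)
    data.frame(time_s = tr$time_s, voltage_v = tr$voltage_v,
               current_a = tr$current_a, train_id = tr$train_id,
               tumor_id = tr$tumor_id, patient_id = tr$patient_id))
  data.table::fwrite(do.call(rbind, dfs), path)
  invisible(path)
}

#' Read EP pulse trains from CSV
#'
#' Rows are grouped by `(patient_id, tumor_id, train_id)` and sorted by time
#' within each train, so row order in the file does not matter. An empty file
#' yields an empty list.
#'
#' @param path CSV as written by [write_pulse_records()].
#' @return list of [pulse_train_record()].
#' @export
read_pulse_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  if (nrow(df) == 0) return(list())
  need <- c("time_s", "voltage_v", "current_a", "train_id", "tumor_id", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  key <- interaction(df$patient_id, df$tumor_id, df$train_id, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    if (anyDuplicated(g$time_s))
      stop(sprintf("%s: non-monotone (duplicated) time within train %s/%s/%s",
                   path, g$patient_id[1], g$tumor_id[1], g$train_id[1]),
           call. = FALSE)
    pulse_train_record(g$time_s, g$voltage_v, g$current_a,
                       train_id = g$train_id[1], tumor_id = g$tumor_id[1],
                       patient_id = g$patient_id[1])
  })
  names(out) <- NULL
  # stable order: patient, tumor, train
  ord <- order(vapply(out, function(x) paste(x$patient_id, x$tumor_id,
                                             sprintf("%09d", as.integer(x$train_id))), ""))
  out[ord]
}
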