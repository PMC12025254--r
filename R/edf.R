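# European Data Format (EDF) I/O: fixed 256-byte header, one 256-byte
# header block per signal, then 16-bit little-endian integer data records.
# One data record per second (samples_per_record = sample_rate).

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

#' Write a recording to an EDF file
#'
#' Standard-conformant EDF with physical dimension uV, the canonical
#' channel order, and a fixed header timestamp so identical recordings
#' produce identical bytes. Signals are quantized to the 16-bit digital
#' range over a symmetric physical range covering the data.
#'
#' @param recording An `eeg_recording` with finite samples and an integer
#'   number of seconds per record boundary (trailing partial seconds are
#'   dropped with a warning).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  if (any(!is.finite(data))) {
    stop("cannot write non-finite samples to EDF", call. = FALSE)
  }
  fs <- recording$sample_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sample rate",
                            call. = FALSE)
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec * fs < ncol(data)) {
    warning("trailing partial second dropped when writing EDF")
    data <- data[, seq_len(n_rec * fs), drop = FALSE]
  }
  # the physical range is stored in an 8-char header field (6 significant
  # digits), so round it up to 6 digits first and encode against the
  # rounded value; reader and writer then share the exact same gain
  phys_max <- max(abs(data), 1e-6)
  phys_max <- signif(phys_max, 6)
  while (phys_max < max(abs(data))) {
    phys_max <- signif(phys_max * (1 + 1e-5), 6)
  }
  dig_max <- 32767
  gain <- 2 * phys_max / 65535            # same convention as the reader
  offset <- phys_max - gain * dig_max
  scaled <- pmin(pmax(round((data - offset) / gain), -32768), dig_max)
  storage.mode(scaled) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("subject", recording$subject_id), 80),
    pad_field(paste("session", recording$session), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    c16 <- vapply(recording$channel_names, pad_field, "", width = 16),
    rep(pad_field("AgAgCl electrode", 80), ns),
    rep(pad_field("uV", 8), ns),
    rep(pad_field(sprintf("%-.6g", -phys_max), 8), ns),
    rep(pad_field(sprintf("%-.6g", phys_max), 8), ns),
    rep(pad_field(-32768, 8), ns),
    rep(pad_field(dig_max, 8), ns),
    rep(pad_field("BP 0.5-50Hz", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * fs + seq_len(fs)
    block <- t(scaled[, cols, drop = FALSE])  # per signal contiguous
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trimws(rd(8))
  patient <- trimws(rd(80))
  recording_id <- trimws(rd(80))
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- per(16)
  transducer <- per(80)
  phys_dim <- per(8)
  phys_min <- as.numeric(per(8))
  phys_max <- as.numeric(per(8))
  dig_min <- as.numeric(per(8))
  dig_max <- as.numeric(per(8))
  prefilter <- per(80)
  spr <- as.integer(per(8))
  per(32)
  list(version = version, patient = patient, recording_id = recording_id,
       n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max, dig_min = dig_min,
       dig_max = dig_max, spr = spr, header_bytes = header_bytes)
}

#' Read an EDF file into a recording
#'
#' Data are returned in microvolts with channel names canonicalized
#' (case-insensitively) against the 16-label montage; the sampling rate is
#' taken from the header. By default the file must contain exactly the 16
#' montage channels.
#'
#' @param path EDF file path.
#' @param validate_montage Require the full 16-channel montage (default
#'   TRUE; the error names any missing labels).
#' @return An `eeg_recording` (subject/session parsed from the header
#'   identification fields when present).
#' @export
read_edf <- function(path, validate_montage = TRUE) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- h$spr[1] / h$rec_dur
  data <- matrix(0, h$ns, h$n_rec * h$spr[1])
  for (r in seq_len(h$n_rec)) {
    raw <- readBin(con, "integer", n = h$ns * h$spr[1], size = 2,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = h$spr[1], ncol = h$ns)
    data[, (r - 1) * h$spr[1] + seq_len(h$spr[1])] <- t(block)
  }
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  offset <- h$phys_max - gain * h$dig_max
  data <- data * gain + offset

  labels <- h$labels
  if (validate_montage) {
    canon <- eeg_montage()$label
    hit <- match(toupper(canon), toupper(labels))
    if (anyNA(hit)) {
      stop("EDF file is missing montage channel(s): ",
           paste(canon[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    data <- data[hit, , drop = FALSE]
    labels <- canon
  }
  subject <- sub("^subject ", "", h$patient)
  session <- sub("^session ", "", h$recording_id)
  eeg_recording(data, labels, fs, subject_id = subject, session = session)
}

#' Write a synthetic dataset as EDF files plus a label manifest
#'
#' One EDF file per subject/session named `<subject>_<session>.edf`, and a
#' `labels.csv` manifest (subject_id, session, class).
#'
#' @param dataset As produced by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset_edf <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset$recordings) {
    write_edf(rec, file.path(dir, sprintf("%s_%s.edf", rec$subject_id,
                                          rec$session)))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dataset$manifest)
}

#' Read a dataset directory written by [write_dataset_edf()]
#'
#' @param dir Directory containing EDF files and `labels.csv`.
#' @return List with `recordings` and `manifest`.
#' @export
read_dataset_edf <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "labels.csv"),
                              stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    nm <- sprintf("%s_%s", manifest$subject_id[i], manifest$session[i])
    recs[[nm]] <- read_edf(file.path(dir, paste0(nm, ".edf")))
  }
  list(recordings = recs, manifest = manifest)
}
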