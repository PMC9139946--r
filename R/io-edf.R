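# Minimal EDF / BDF (BioSemi 24-bit) support. Only the fields needed to
# recover the signal matrix and sampling rate are interpreted; annotations
# and discontinuous files are not supported. All signals in a file must
# share one sampling rate (true of the recordings this package targets).

edf_field <- function(raw, off, len) trimws(rawToChar(raw[(off + 1):(off + len)]))

#' Read an EDF or BDF recording
#'
#' Parses the fixed-layout EDF header (or the BioSemi BDF variant with
#' 24-bit samples), applies the per-signal digital-to-physical calibration,
#' and optionally drops auxiliary channels (e.g. EXG electrodes or
#' accelerometers) by label before constructing the recording. Surviving
#' channels keep file order. The sampling rate is taken from the header
#' (samples per record / record duration).
#'
#' @param path path to a `.edf` or `.bdf` file.
#' @param group,eyes,subject_id metadata for the recording; `subject_id`
#'   defaults to the file's local patient identification field (or the file
#'   name if blank).
#' @param drop_channels character vector of channel labels to discard.
#' @return An `eeg_recording`.
#' @export
read_edf_recording <- function(path, group = "HC", eyes = "UNKNOWN",
                               subject_id = NULL, drop_channels = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  if (length(hdr) < 256) stop("truncated EDF/BDF header (format error)")
  is_bdf <- hdr[1] == as.raw(255)
  version <- edf_field(hdr, 1, 7)
  if (is_bdf && !identical(version, "BIOSEMI"))
    stop("unrecognized BDF version field (format error)")
  if (!is_bdf && !identical(edf_field(hdr, 0, 8), "0"))
    stop("unrecognized EDF version field (format error)")
  patient <- edf_field(hdr, 8, 80)
  n_records <- as.integer(edf_field(hdr, 236, 8))
  rec_dur <- as.numeric(edf_field(hdr, 244, 8))
  ns <- as.integer(edf_field(hdr, 252, 4))
  if (is.na(ns) || ns < 1 || is.na(n_records) || n_records < 1 ||
      is.na(rec_dur) || rec_dur <= 0)
    stop("invalid EDF/BDF header counts (format error)")

  sig_hdr <- readBin(con, "raw", ns * 256)
  # cumulative per-signal byte offsets within the signal header block:
  # label16 transducer80 dim8 pmin8 pmax8 dmin8 dmax8 prefilter80 nsamp8
  offsets <- c(label = 0, pmin = 104, pmax = 112, dmin = 120, dmax = 128,
               nsamp = 216)
  field_at <- function(name, len) {
    vapply(seq_len(ns) - 1L, function(i)
      edf_field(sig_hdr, offsets[[name]] * ns + i * len, len), character(1))
  }
  labels <- field_at("label", 16)
  pmin <- as.numeric(field_at("pmin", 8))
  pmax <- as.numeric(field_at("pmax", 8))
  dmin <- as.numeric(field_at("dmin", 8))
  dmax <- as.numeric(field_at("dmax", 8))
  nsamp <- as.integer(field_at("nsamp", 8))
  if (length(unique(nsamp)) != 1)
    stop("signals with differing sampling rates are not supported")
  nsamp <- nsamp[1]
  fs <- nsamp / rec_dur

  bps <- if (is_bdf) 3L else 2L
  total <- ns * nsamp * n_records
  raw_data <- readBin(con, "raw", total * bps)
  if (length(raw_data) < total * bps)
    stop("truncated EDF/BDF data section (format error)")
  if (is_bdf) {
    b <- matrix(as.integer(raw_data), nrow = 3)
    dig <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
  } else {
    dig <- readBin(raw_data, "integer", n = total, size = 2, signed = TRUE,
                   endian = "little")
  }
  # records are blocks of (signal-major) nsamp runs
  dig <- array(dig, dim = c(nsamp, ns, n_records))
  gain <- (pmax - pmin) / (dmax - dmin)
  mat <- matrix(0, ns, nsamp * n_records)
  for (s in seq_len(ns))
    mat[s, ] <- as.vector(dig[, s, ]) * gain[s] + pmin[s] - dmin[s] * gain[s]

  keep <- !(labels %in% drop_channels)
  if (sum(keep) < 2)
    stop("dropping these channels leaves fewer than 2 (shape error)")
  if (is.null(subject_id))
    subject_id <- if (nzchar(patient)) patient else basename(path)
  recording(mat[keep, , drop = FALSE], fs,
            channel_names = make.unique(labels[keep]),
            subject_id = subject_id, group = group, eyes = eyes)
}

edf_pad <- function(x, len) {
  x <- substr(as.character(x), 1, len)
  formatC(x, width = len, flag = "-")
}

# format a number so it fits an 8-char ASCII header field without truncation
edf_num <- function(v) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, v)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", v, " in an 8-character EDF field")
}

#' Write a recording as EDF or BDF
#'
#' One data record per second; samples are quantized to the 16-bit (EDF) or
#' 24-bit (BDF) digital range spanning each channel's observed amplitude
#' range, so the round-trip is exact only up to quantization. Trailing
#' samples that do not fill a whole record are dropped. Intended mainly for
#' generating test files and interoperability checks.
#'
#' @param rec an `eeg_recording`; `rec$fs` must be a whole number.
#' @param path destination path; a `.bdf` extension selects BDF.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  is_bdf <- grepl("\\.bdf$", path, ignore.case = TRUE)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_records <- ncol(rec$data) %/% fs
  if (n_records < 1) stop("recording shorter than one 1-s record")
  x <- rec$data[, seq_len(n_records * fs), drop = FALSE]

  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  phys_min <- phys_min - ifelse(phys_max == phys_min, 1, 0)  # zero span guard
  # quantize against the values as they will be stored in the ASCII header
  phys_min <- vapply(phys_min, function(v) as.numeric(edf_num(v)), numeric(1))
  phys_max <- vapply(phys_max, function(v) as.numeric(edf_num(v)), numeric(1))
  phys_min <- phys_min - ifelse(phys_max <= phys_min, 1, 0)
  dmax <- if (is_bdf) 8388607 else 32767
  dmin <- if (is_bdf) -8388608L else -32768L
  gain <- (phys_max - phys_min) / (dmax - dmin)
  dig <- round(sweep(sweep(x, 1, phys_min), 1, gain, "/")) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  if (is_bdf) {
    writeBin(as.raw(255), con)
    put(edf_pad("BIOSEMI", 7))
  } else put(edf_pad("0", 8))
  put(edf_pad(rec$subject_id, 80))
  put(edf_pad(paste("Startdate 01-JAN-2026", rec$group, rec$eyes), 80))
  put(edf_pad("01.01.26", 8)); put(edf_pad("00.00.00", 8))
  put(edf_pad(256 * (ns + 1), 8))
  put(edf_pad(if (is_bdf) "24BIT" else "", 44))
  put(edf_pad(n_records, 8)); put(edf_pad(1, 8)); put(edf_pad(ns, 4))
  for (lab in rec$channel_names) put(edf_pad(lab, 16))
  for (i in seq_len(ns)) put(edf_pad("unknown", 80))
  for (i in seq_len(ns)) put(edf_pad("uV", 8))
  for (v in phys_min) put(edf_pad(edf_num(v), 8))
  for (v in phys_max) put(edf_pad(edf_num(v), 8))
  for (i in seq_len(ns)) put(edf_pad(dmin, 8))
  for (i in seq_len(ns)) put(edf_pad(dmax, 8))
  for (i in seq_len(ns)) put(edf_pad("", 80))
  for (i in seq_len(ns)) put(edf_pad(fs, 8))
  for (i in seq_len(ns)) put(edf_pad("", 32))

  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      d <- as.integer(dig[s, cols])
      if (is_bdf) {
        u <- ifelse(d < 0, d + 16777216, d)
        bytes <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
        writeBin(as.raw(bytes), con)
      } else {
        writeBin(d, con, size = 2, endian = "little")
      }
    }
  }
  invisible(path)
}
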