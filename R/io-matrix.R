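#' Read a recording from a plain numeric matrix file
#'
#' Reads a delimited text matrix (rows = channels, columns = samples) or the
#' package's simple binary matrix format (see [write_matrix_recording]).
#' Values are taken exactly as stored; no unit conversion or rescaling is
#' applied.
#'
#' @param path file path. Files ending in `.bin` are read as binary, all
#'   others as whitespace/comma-delimited text.
#' @param fs sampling rate in Hz.
#' @param group,eyes,subject_id metadata passed to [recording()].
#' @param channel_names optional channel labels.
#' @return An `eeg_recording`.
#' @seealso [write_matrix_recording()], [load_dataset()]
#' @export
read_matrix_recording <- function(path, fs, group = "HC", eyes = "UNKNOWN",
                                  subject_id = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.bin$", path)) {
    mat <- read_matrix_bin(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
      if (anyNA(v)) stop("non-numeric content in ", path, " (format error)")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged rows in ", path, " (format error)")
    mat <- do.call(rbind, rows)
  }
  if (nrow(mat) < 2)
    stop("matrix file has fewer than 2 rows/channels (shape error)")
  recording(mat, fs, channel_names = channel_names, subject_id = subject_id,
            group = group, eyes = eyes)
}

#' Write a recording's data matrix to disk
#'
#' Text output is one row per channel, space-delimited, full `%.17g`
#' precision so that a write/read round-trip is bitwise exact. The `.bin`
#' format is a small header (magic, nrow, ncol as integers) followed by the
#' column-major doubles, little-endian.
#'
#' @param rec an `eeg_recording`.
#' @param path destination; `.bin` selects the binary format.
#' @return `path`, invisibly.
#' @export
write_matrix_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.bin$", path)) {
    write_matrix_bin(rec$data, path)
  } else {
    lines <- apply(rec$data, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

read_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "EEGM")) stop("bad binary matrix header (format error)")
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  x <- readBin(con, "double", dims[1] * dims[2], size = 8, endian = "little")
  if (length(x) != dims[1] * dims[2]) stop("truncated binary matrix (format error)")
  matrix(x, dims[1], dims[2])
}

write_matrix_bin <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("EEGM", con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(dim(mat)), con, size = 4, endian = "little")
  writeBin(as.numeric(mat), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a dataset described by a CSV manifest
#'
#' The manifest is a CSV with header `file,subject_id,group,eyes,fs`. Paths
#' are resolved relative to the manifest's directory unless absolute. One
#' recording is returned per row, in row order.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A list of `eeg_recording` objects.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("file", "subject_id", "group", "eyes", "fs")
  if (!all(required %in% names(man)))
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  if (nrow(man) == 0) return(list())
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    e <- man[i, ]
    if (!e$group %in% GROUP_LEVELS)
      stop("manifest row ", i, ": unknown group token '", e$group, "'")
    if (!e$eyes %in% EYES_LEVELS)
      stop("manifest row ", i, ": unknown eyes token '", e$eyes, "'")
    p <- if (grepl("^(/|[A-Za-z]:)", e$file)) e$file else file.path(base, e$file)
    if (!file.exists(p))
      stop("manifest row ", i, " (", e$subject_id, "): missing file ", p)
    if (grepl("\\.(edf|bdf)$", p, ignore.case = TRUE))
      read_edf_recording(p, group = e$group, eyes = e$eyes,
                         subject_id = e$subject_id)
    else
      read_matrix_recording(p, fs = e$fs, group = e$group, eyes = e$eyes,
                            subject_id = e$subject_id)
  })
}

#' Write a list of recordings as matrix files plus a manifest
#'
#' @param recordings list of `eeg_recording` objects.
#' @param dir output directory (created if needed).
#' @param name dataset name; the manifest is written to `<dir>/<name>.csv`.
#' @param binary write `.bin` matrices instead of text.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(recordings, dir, name = "dataset", binary = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (binary) ".bin" else ".txt"
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    fname <- sprintf("%s_%03d_%s%s", name, i, rec$subject_id, ext)
    write_matrix_recording(rec, file.path(dir, fname))
    data.frame(file = fname, subject_id = rec$subject_id, group = rec$group,
               eyes = rec$eyes, fs = rec$fs, stringsAsFactors = FALSE)
  })
  man_path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(do.call(rbind, rows), man_path, row.names = FALSE,
                   quote = FALSE)
  invisible(man_path)
}
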