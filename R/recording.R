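#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("PD_OFF", "PD_ON", "HC")
EYES_LEVELS <- c("OPEN", "CLOSED", "UNKNOWN")

#' Construct an EEG recording object
#'
#' A recording holds one subject/session as a channels-by-samples numeric
#' matrix together with its sampling rate and class metadata. Rows are
#' channels throughout the package; columns are samples.
#'
#' @param data numeric matrix, `ch` channels x total samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of `ch` unique channel labels;
#'   defaults to `"ch1"..."chN"`.
#' @param subject_id subject identifier string.
#' @param group class label, one of `"PD_OFF"`, `"PD_ON"`, `"HC"`.
#' @param eyes eyes state, one of `"OPEN"`, `"CLOSED"`, `"UNKNOWN"`.
#' @return An object of class `eeg_recording`.
#' @examples
#' r <- recording(matrix(rnorm(2 * 100), 2), fs = 100, group = "HC")
#' n_channels(r)
#' @export
recording <- function(data, fs, channel_names = NULL, subject_id = "s1",
                      group = "HC", eyes = "UNKNOWN") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 2)
    stop("recording must have at least 2 channels (shape error)")
  if (ncol(data) < 1)
    stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  group <- match.arg(group, GROUP_LEVELS)
  eyes <- match.arg(eyes, EYES_LEVELS)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data) || anyDuplicated(channel_names))
    stop("`channel_names` must contain exactly ", nrow(data), " unique labels")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = as.character(subject_id), group = group, eyes = eyes),
    class = "eeg_recording")
}

#' @rdname recording
#' @param x an `eeg_recording`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "eeg_recording"))
  nrow(x$data)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s | group %s | eyes %s | %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, x$eyes, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs))
  invisible(x)
}

#' Drop channels from a recording by name
#'
#' Surviving channels keep their original order. Dropping names not present
#' is a no-op for those names.
#'
#' @param rec an `eeg_recording`.
#' @param drop character vector of channel labels to remove.
#' @return The recording with the remaining channels.
#' @export
drop_channels <- function(rec, drop) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(rec$channel_names %in% drop)
  if (sum(keep) < 2)
    stop("dropping these channels would leave fewer than 2 (shape error)")
  recording(rec$data[keep, , drop = FALSE], rec$fs,
            channel_names = rec$channel_names[keep],
            subject_id = rec$subject_id, group = rec$group, eyes = rec$eyes)
}
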