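#' Band-pass specification
#'
#' Describes the Butterworth band-pass applied before segmentation. The
#' default band, 10--30 Hz, covers the upper alpha and beta rhythms where
#' resting-state discriminative activity is concentrated; `order` is the
#' order of the designed one-pass filter (applied forward--backward, so the
#' effective attenuation is doubled).
#'
#' @param low_hz lower passband edge in Hz (> 0).
#' @param high_hz upper passband edge in Hz (> `low_hz`; must stay below the
#'   Nyquist frequency of the data it is applied to).
#' @param order Butterworth order, default 5.
#' @return A `band_spec` object.
#' @export
band_spec <- function(low_hz = 10, high_hz = 30, order = 5) {
  if (!is.numeric(low_hz) || low_hz <= 0) stop("`low_hz` must be > 0")
  if (!is.numeric(high_hz) || high_hz <= low_hz)
    stop("`high_hz` must exceed `low_hz`")
  if (order < 1) stop("`order` must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %g-%g Hz Butterworth order %d (zero-phase)\n",
              x$low_hz, x$high_hz, x$order))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the designed band-pass to every channel forward and backward
#' (`signal::filtfilt`), which cancels phase distortion and squares the
#' magnitude response. Output has the same shape as the input.
#'
#' @param rec an `eeg_recording`.
#' @param band a [band_spec()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass <- function(rec, band = band_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  nyq <- rec$fs / 2
  if (band$high_hz >= nyq)
    stop(sprintf("band edge %g Hz is not below Nyquist (%g Hz)",
                 band$high_hz, nyq))
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(filt, rec$fs, channel_names = rec$channel_names,
            subject_id = rec$subject_id, group = rec$group, eyes = rec$eyes)
}

#' Split recordings into fixed-length non-overlapping segments
#'
#' Each recording is cut into consecutive windows of `N = floor(T * fs)`
#' samples; the trailing remainder of each recording is dropped. Every
#' segment inherits its recording's group label and subject id, so the
#' result carries everything the cross-validation stage needs.
#'
#' @param recordings an `eeg_recording` or list of them (all with equal
#'   channel count and sampling rate).
#' @param T_s segment duration in seconds (default 2).
#' @param band optional `band_spec` recorded as provenance (set by
#'   [run_pipeline()]; not applied here).
#' @return A `segment_set`: list with `segments` (list of ch x N matrices),
#'   `labels` (group per segment), `subjects`, `T_s`, `fs`, `band`.
#' @export
segment_recordings <- function(recordings, T_s = 2, band = NULL) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1, T_s > 0)
  fs <- recordings[[1]]$fs
  ch <- nrow(recordings[[1]]$data)
  N <- floor(T_s * fs)
  if (N < 2) stop("segment length floor(T*fs) must be >= 2 samples")
  segments <- list(); labels <- character(); subjects <- character()
  for (rec in recordings) {
    stopifnot(inherits(rec, "eeg_recording"))
    if (rec$fs != fs || nrow(rec$data) != ch)
      stop("all recordings must share channel count and sampling rate")
    n_seg <- ncol(rec$data) %/% N
    if (n_seg == 0) next
    for (i in seq_len(n_seg)) {
      segments[[length(segments) + 1L]] <-
        rec$data[, ((i - 1) * N + 1):(i * N), drop = FALSE]
    }
    labels <- c(labels, rep(rec$group, n_seg))
    subjects <- c(subjects, rep(rec$subject_id, n_seg))
  }
  structure(list(segments = segments, labels = labels, subjects = subjects,
                 T_s = T_s, fs = fs, N = N, ch = ch, band = band),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> M=%d segments of %d ch x %d samples (T=%g s @ %g Hz)\n",
              length(x$segments), x$ch, x$N, x$T_s, x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Subset a segment set by index
#' @param set a `segment_set`.
#' @param idx integer indices of segments to keep.
#' @return A `segment_set` with the selected segments.
#' @export
subset_segments <- function(set, idx) {
  stopifnot(inherits(set, "segment_set"))
  out <- set
  out$segments <- set$segments[idx]
  out$labels <- set$labels[idx]
  out$subjects <- set$subjects[idx]
  out
}
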