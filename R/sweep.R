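# Sweep drivers over the three pipeline knobs that dominate performance:
# analysis frequency band, CSP reduction number d = 2m, segment length.

#' Named EEG sub-band presets
#'
#' Standard clinical sub-bands usable as sweep values or `band_spec`
#' arguments: delta 0.5--4, theta 4--8, alpha 8--13, beta 13--30 Hz (gamma
#' is deliberately absent; it is usually dominated by muscle artifact in
#' resting recordings). Combined presets alpha_beta (8--30) and the 10--30
#' default are included.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
band_presets <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), alpha_beta = c(8, 30), default = c(10, 30))
}

#' Sweep one pipeline parameter, all else fixed
#'
#' Runs the full band-pass / segment / CSP / feature / classifier pipeline
#' once per swept value and collects the cross-validated metric summaries
#' into a long-format table. A failing value records its error message and
#' the sweep continues.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param axis `"BAND"`, `"REDUCTION"` or `"SEGMENT_LENGTH"`.
#' @param values for `BAND`: list of `c(low, high)` Hz pairs (or names from
#'   [band_presets()]); for `REDUCTION`: even reduction numbers `d`; for
#'   `SEGMENT_LENGTH`: durations in seconds.
#' @param band,T_s,m fixed values for the axes not being swept.
#' @param feature,classifier,k,seed,... passed to [run_cv()].
#' @return A data.frame with one row per swept value: `axis`, `value`,
#'   mean and sd of each metric, and an `error` column (`NA` on success).
#' @export
run_sweep <- function(recordings, axis = c("BAND", "REDUCTION",
                                           "SEGMENT_LENGTH"),
                      values, band = band_spec(), T_s = 2, m = NULL,
                      feature = feature_config(), classifier = classifier_spec(),
                      k = 10, seed = 1, ...) {
  axis <- match.arg(axis)
  rows <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    cfg <- list(band = band, T_s = T_s, m = m)
    label <- NULL
    if (axis == "BAND") {
      if (is.character(v)) {
        label <- v
        v <- band_presets()[[v]]
        if (is.null(v)) return(sweep_row(axis, label, err = "unknown band preset"))
      }
      cfg$band <- band_spec(v[1], v[2], band$order)
      if (is.null(label)) label <- sprintf("%g-%g", v[1], v[2])
    } else if (axis == "REDUCTION") {
      if (v %% 2 != 0) return(sweep_row(axis, as.character(v),
                                        err = "reduction number d must be even"))
      cfg$m <- v / 2
      label <- as.character(v)
    } else {
      cfg$T_s <- v
      label <- as.character(v)
    }
    res <- tryCatch(
      run_pipeline(recordings, band = cfg$band, T_s = cfg$T_s, m = cfg$m,
                   feature = feature, classifier = classifier, k = k,
                   seed = seed, ...),
      error = function(e) conditionMessage(e))
    if (is.character(res)) return(sweep_row(axis, label, err = res))
    sweep_row(axis, label, summary = res$summary)
  })
  do.call(rbind, rows)
}

sweep_row <- function(axis, value, summary = NULL, err = NA_character_) {
  base <- data.frame(axis = axis, value = value, stringsAsFactors = FALSE)
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "f_score", "auc")
  for (mname in metrics) {
    base[[paste0(mname, "_mean")]] <-
      if (is.null(summary)) NA_real_ else unname(summary[[mname]]["mean"])
    base[[paste0(mname, "_sd")]] <-
      if (is.null(summary)) NA_real_ else unname(summary[[mname]]["sd"])
  }
  base$error <- err
  base
}
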