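# Segment-level feature functionals applied to the rows of a spatially
# filtered segment. All entropies follow the wavelet-entropy convention:
# they are evaluated on the N raw samples of each component, natural logs,
# and log(0) terms contribute 0.

FEATURE_METRICS <- c("VAR", "BP", "ENG", "THEN", "NOEN", "SUEN", "LOGEN", "SHEN")

#' Feature configuration
#'
#' @param metric one of `"VAR"` (log normalized variance), `"BP"` (log band
#'   power), `"ENG"` (energy), `"THEN"` (threshold entropy), `"NOEN"` (norm
#'   entropy), `"SUEN"` (sure entropy), `"LOGEN"` (log-energy entropy),
#'   `"SHEN"` (Shannon entropy).
#' @param alpha threshold-entropy amplitude threshold (default 0.2). Note
#'   the threshold is applied on whatever amplitude scale the input uses;
#'   no unit conversion happens upstream.
#' @param p norm-entropy power, must be >= 1 (default 1.1).
#' @param q sure-entropy threshold (default 3); values <= 2 trigger a
#'   warning as the statistic then degenerates toward a count.
#' @return A `feature_config`.
#' @export
feature_config <- function(metric = "VAR", alpha = 0.2, p = 1.1, q = 3) {
  metric <- match.arg(toupper(metric), FEATURE_METRICS)
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (p < 1) stop("norm-entropy power `p` must be >= 1")
  if (q <= 2) warning("sure-entropy threshold q <= 2 is not recommended")
  structure(list(metric = metric, alpha = alpha, p = p, q = q),
            class = "feature_config")
}

xlogx2 <- function(s) {
  # s^2 * log(s^2) with 0*log(0) := 0
  s2 <- s^2
  out <- numeric(length(s2))
  nz <- s2 > 0
  out[nz] <- s2[nz] * log(s2[nz])
  out
}

#' Feature functionals on a filtered segment
#'
#' Each takes a d x N matrix `S` whose rows are CSP components and returns a
#' length-d numeric vector, one value per component.
#'
#' * `feat_variance`: log of each row's population variance (divide by N,
#'   mean removed) normalized by the summed variance over rows, so
#'   `sum(exp(f)) == 1`.
#' * `feat_bandpower`: log of the mean squared amplitude.
#' * `feat_energy`: sum of squared amplitudes.
#' * `feat_threshold_entropy`: count of samples with `|s| > alpha`.
#' * `feat_norm_entropy`: `sum(|s|^p)`.
#' * `feat_sure_entropy`: `N - #{|s| <= q} + sum(min(s^2, q^2))`.
#' * `feat_log_energy_entropy`: `sum(log(s^2))`, zero samples contributing 0.
#' * `feat_shannon_entropy`: `sum(s^2 * log(s^2))`, zero samples
#'   contributing 0 (sign as defined, no leading minus).
#'
#' @param S numeric d x N matrix of spatially filtered components.
#' @param alpha,p,q metric parameters, see [feature_config()].
#' @return Numeric vector of length `nrow(S)`.
#' @name features
NULL

#' @rdname features
#' @export
feat_variance <- function(S) {
  stopifnot(is.matrix(S), ncol(S) >= 2)
  v <- apply(S, 1, function(r) mean((r - mean(r))^2))
  tot <- sum(v)
  if (tot <= 0) stop("degenerate segment: all components have zero variance")
  log(v / tot)
}

#' @rdname features
#' @export
feat_bandpower <- function(S) {
  stopifnot(is.matrix(S))
  log(rowMeans(S^2))
}

#' @rdname features
#' @export
feat_energy <- function(S) {
  stopifnot(is.matrix(S))
  rowSums(S^2)
}

#' @rdname features
#' @export
feat_threshold_entropy <- function(S, alpha = 0.2) {
  stopifnot(is.matrix(S), alpha >= 0)
  rowSums(abs(S) > alpha)
}

#' @rdname features
#' @export
feat_norm_entropy <- function(S, p = 1.1) {
  stopifnot(is.matrix(S), p >= 1)
  rowSums(abs(S)^p)
}

#' @rdname features
#' @export
feat_sure_entropy <- function(S, q = 3) {
  stopifnot(is.matrix(S))
  N <- ncol(S)
  N - rowSums(abs(S) <= q) + rowSums(pmin(S^2, q^2))
}

#' @rdname features
#' @export
feat_log_energy_entropy <- function(S) {
  stopifnot(is.matrix(S))
  apply(S, 1, function(r) {
    r2 <- r^2
    sum(log(r2[r2 > 0]))
  })
}

#' @rdname features
#' @export
feat_shannon_entropy <- function(S) {
  stopifnot(is.matrix(S))
  apply(S, 1, function(r) sum(xlogx2(r)))
}

apply_metric <- function(S, config) {
  switch(config$metric,
         VAR = feat_variance(S),
         BP = feat_bandpower(S),
         ENG = feat_energy(S),
         THEN = feat_threshold_entropy(S, config$alpha),
         NOEN = feat_norm_entropy(S, config$p),
         SUEN = feat_sure_entropy(S, config$q),
         LOGEN = feat_log_energy_entropy(S),
         SHEN = feat_shannon_entropy(S))
}

#' Extract the feature matrix from a segment set
#'
#' Applies the model's reduced spatial projection to every segment and then
#' the configured feature functional, yielding the M x d matrix that feeds
#' the classifiers.
#'
#' @param model a fitted (and reduced) `csp_model`.
#' @param segment_set a `segment_set` with matching channel count.
#' @param config a [feature_config()].
#' @return A `feature_matrix`: list with `values` (M x d), `labels`,
#'   `subjects`, `metric` (the config), `d`.
#' @export
extract_features <- function(model, segment_set, config = feature_config()) {
  stopifnot(inherits(model, "csp_model"), inherits(segment_set, "segment_set"),
            inherits(config, "feature_config"))
  M <- length(segment_set$segments)
  vals <- matrix(NA_real_, M, model$d)
  for (i in seq_len(M)) {
    f <- tryCatch(apply_metric(spatial_filter(model, segment_set$segments[[i]]),
                               config),
                  error = function(e) stop("segment ", i, ": ",
                                           conditionMessage(e)))
    vals[i, ] <- f
  }
  if (any(!is.finite(vals)))
    stop("feature matrix contains non-finite entries")
  colnames(vals) <- paste0(tolower(config$metric), seq_len(model$d))
  structure(list(values = vals, labels = segment_set$labels,
                 subjects = segment_set$subjects, metric = config,
                 d = model$d),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (%s)\n",
              nrow(x$values), x$d, x$metric$metric))
  invisible(x)
}

#' Export a feature matrix as CSV (label column last)
#' @param fm a `feature_matrix`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
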