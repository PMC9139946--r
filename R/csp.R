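# Common spatial pattern fitting by whitening + simultaneous
# diagonalization of the two class covariance matrices.

#' Trace-normalized spatial covariance of one segment
#'
#' For a ch x N segment E, returns E E' / trace(E E'), after (by default)
#' removing each channel's mean within the segment. The result is symmetric
#' positive semi-definite with unit trace, so segments contribute to the
#' class average independently of their overall amplitude.
#'
#' @param segment numeric ch x N matrix, N >= 2.
#' @param center subtract the per-channel mean first (default TRUE).
#' @return A ch x ch covariance matrix with trace 1.
#' @export
normalized_covariance <- function(segment, center = TRUE) {
  if (!is.matrix(segment) || ncol(segment) < 2)
    stop("segment must be a matrix with at least 2 samples per channel")
  if (center) segment <- segment - rowMeans(segment)
  cc <- tcrossprod(segment)
  tr <- sum(diag(cc))
  if (tr <= 0) stop("degenerate segment: zero total power")
  cc / tr
}

csp_class_mean_cov <- function(segments, center) {
  covs <- lapply(segments, normalized_covariance, center = center)
  Reduce(`+`, covs) / length(covs)
}

canonical_row_signs <- function(W) {
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  W
}

#' Common spatial pattern from averaged class covariances
#'
#' Core decomposition used by [fit_csp()], exposed so a model can be built
#' directly from known covariance matrices (useful for analytic checks).
#' The composite covariance `C_C = C_A + C_B` is eigendecomposed, a
#' whitening transform `P = diag(1/sqrt(lambda)) U'` is formed so that
#' `P C_C P' = I`, the whitened class-A covariance is diagonalized by an
#' orthonormal basis B with eigenvalues sorted descending, and the spatial
#' filters are the rows of `W = B' P`. Because the whitened class
#' covariances sum to the identity, the class-A and class-B eigenvalues
#' satisfy `lambda_A + lambda_B = 1` componentwise: the first filter
#' maximizes class-A variance and the last maximizes class-B variance.
#'
#' @param C_A,C_B symmetric ch x ch averaged normalized covariances for the
#'   two classes.
#' @param class_A,class_B class tags stored in the model.
#' @param reg ridge added to the composite eigenvalues relative to their
#'   maximum (default 0: rank deficiency below `1e-10 * max(lambda)` is an
#'   error; set e.g. `1e-10` to floor instead).
#' @return A `csp_model` with fields `W_full` (ch x ch, rows are filters in
#'   descending class-A eigenvalue order, signs canonicalized so each row's
#'   largest-magnitude entry is positive), `eigvals_A`, `m`, `d`,
#'   `W_reduced`, `class_A`, `class_B`, and the whitening details.
#' @export
csp_from_covariances <- function(C_A, C_B, class_A = "A", class_B = "B",
                                 reg = 0) {
  stopifnot(is.matrix(C_A), is.matrix(C_B),
            all(dim(C_A) == dim(C_B)), nrow(C_A) == ncol(C_A))
  ch <- nrow(C_A)
  C_C <- C_A + C_B
  ec <- eigen((C_C + t(C_C)) / 2, symmetric = TRUE)   # descending eigenvalues
  lam <- ec$values
  if (reg > 0) lam <- lam + reg * max(lam)
  if (any(lam < 1e-10 * max(lam)))
    stop("composite covariance is rank deficient; supply more data or set `reg`")
  P <- diag(1 / sqrt(lam), ch) %*% t(ec$vectors)
  S_A <- P %*% C_A %*% t(P)
  eb <- eigen((S_A + t(S_A)) / 2, symmetric = TRUE)   # descending lambda_A
  W_full <- canonical_row_signs(t(eb$vectors) %*% P)
  model <- structure(
    list(W_full = W_full, eigvals_A = eb$values, m = ch %/% 2, d = NA_integer_,
         W_reduced = NULL, class_A = class_A, class_B = class_B,
         C_A_bar = C_A, C_B_bar = C_B, P = P, ch = ch),
    class = "csp_model")
  csp_reduce(model, ch %/% 2)
}

#' Fit a CSP projection from labeled training segments
#'
#' Averages the trace-normalized covariance of every training segment
#' within each class (arithmetic mean) and runs the whitening /
#' simultaneous-diagonalization decomposition of [csp_from_covariances()].
#' The model is fit once on training data and reused unchanged on test
#' segments; never refit it on data you intend to evaluate on.
#'
#' @param segments list of ch x N matrices, or a `segment_set`.
#' @param labels class tag per segment (ignored when `segments` is a
#'   `segment_set`, whose labels are used).
#' @param class_A,class_B the two class tags; `class_A` is the "positive"
#'   class whose variance the leading filters maximize. Defaults to the
#'   first two distinct labels in sorted order.
#' @param center per-channel mean removal inside each segment (default TRUE).
#' @param reg see [csp_from_covariances()].
#' @return A `csp_model` (initially with m = ch/2, i.e. all filters kept).
#' @export
fit_csp <- function(segments, labels = NULL, class_A = NULL, class_B = NULL,
                    center = TRUE, reg = 0) {
  if (inherits(segments, "segment_set")) {
    labels <- segments$labels
    segments <- segments$segments
  }
  stopifnot(length(segments) == length(labels), length(segments) >= 2)
  ch <- nrow(segments[[1]])
  if (!all(vapply(segments, nrow, 1L) == ch))
    stop("all segments must have the same channel count")
  classes <- sort(unique(labels))
  if (is.null(class_A)) class_A <- classes[1]
  if (is.null(class_B)) class_B <- setdiff(classes, class_A)[1]
  if (is.na(class_B)) stop("need two distinct classes to fit CSP")
  idx_A <- labels == class_A
  idx_B <- labels == class_B
  if (!any(idx_A) || !any(idx_B))
    stop("each class needs at least one training segment")
  C_A <- csp_class_mean_cov(segments[idx_A], center)
  C_B <- csp_class_mean_cov(segments[idx_B], center)
  model <- csp_from_covariances(C_A, C_B, class_A, class_B, reg = reg)
  model$center <- center
  model
}

#' Retain the m most discriminative filter pairs
#'
#' Keeps rows 1..m (maximal class-A variance) and ch-m+1..ch (maximal
#' class-B variance) of the full projection, giving the reduced d x ch
#' projection with reduction number d = 2m.
#'
#' @param model a `csp_model`.
#' @param m number of filter pairs, 1 <= m <= ch/2.
#' @return The model with `W_reduced`, `m` and `d` updated.
#' @export
csp_reduce <- function(model, m) {
  stopifnot(inherits(model, "csp_model"))
  ch <- model$ch
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > ch / 2)
    stop("`m` must satisfy 1 <= m <= ch/2 = ", ch / 2)
  m <- as.integer(m)
  rows <- c(seq_len(m), (ch - m + 1):ch)
  model$m <- m
  model$d <- 2L * m
  model$W_reduced <- model$W_full[rows, , drop = FALSE]
  model
}

#' Spatially filter a segment with a fitted CSP model
#'
#' @param model a `csp_model` with a reduced projection.
#' @param segment ch x N matrix with the model's channel count.
#' @return The d x N matrix of surrogate components `W_reduced %*% segment`.
#' @export
spatial_filter <- function(model, segment) {
  stopifnot(inherits(model, "csp_model"))
  if (!is.matrix(segment) || nrow(segment) != model$ch)
    stop("segment has ", nrow(segment), " channels; model expects ", model$ch)
  model$W_reduced %*% segment
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, d = %d (m = %d), classes %s vs %s\n",
              x$ch, x$d, x$m, x$class_A, x$class_B))
  cat("class-A eigenvalues:", paste(sprintf("%.3f", x$eigvals_A), collapse = " "),
      "\n")
  invisible(x)
}

#' Serialize a CSP model to a portable JSON file
#'
#' Stores the projection matrices, eigenvalues and metadata so a trained
#' spatial filter can be archived and reapplied to new recordings.
#'
#' @param model a `csp_model`.
#' @param path destination `.json` path.
#' @return `path`, invisibly.
#' @export
write_csp_model <- function(model, path) {
  stopifnot(inherits(model, "csp_model"))
  obj <- list(ch = model$ch, m = model$m, d = model$d,
              class_A = model$class_A, class_B = model$class_B,
              center = isTRUE(model$center),
              eigvals_A = model$eigvals_A,
              W_full = model$W_full)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a CSP model written by [write_csp_model()]
#' @param path path to the JSON file.
#' @return A `csp_model`.
#' @export
read_csp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$W_full
  if (!is.matrix(W)) W <- do.call(rbind, lapply(W, as.numeric))
  model <- structure(
    list(W_full = W,
         eigvals_A = as.numeric(obj$eigvals_A), m = obj$m, d = obj$d,
         W_reduced = NULL, class_A = obj$class_A, class_B = obj$class_B,
         center = obj$center, ch = obj$ch),
    class = "csp_model")
  csp_reduce(model, obj$m)
}
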