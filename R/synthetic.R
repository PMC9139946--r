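# Synthetic two-class multichannel generator with a known discriminative
# spatial structure: latent band-limited Gaussian sources, unit variance
# except for one source pair whose variances swap between classes, mixed
# through a random orthogonal matrix. Under this model CSP is exactly the
# right detector, and the class covariances are available in closed form.

#' Specification of a synthetic two-class EEG-like dataset
#'
#' Classes differ only in the variance of two latent sources: class A has
#' source 1 variance scaled by `1 + separation` and source `ch` scaled by
#' `1 / (1 + separation)`; class B is mirrored. `separation = 0` makes the
#' class distributions identical. Sources are Gaussian noise band-limited
#' to `band_hz` (default 10--30 Hz, matching the default analysis band) and
#' standardized to their target variances; independent white sensor noise
#' of standard deviation `noise_sd` (relative to the unit source scale) is
#' added after mixing.
#'
#' @param ch channels (>= 2, default 8).
#' @param fs sampling rate Hz (default 256).
#' @param duration_s seconds per recording (default 40).
#' @param n_recordings recordings per class (default 10).
#' @param separation variance ratio offset (>= 0, default 4).
#' @param band_hz length-2 source band in Hz.
#' @param noise_sd sensor noise sd (default 0.1).
#' @param mixing_seed,noise_seed integer seeds for the mixing matrix and
#'   the source/noise draws.
#' @param orthogonal use a random orthogonal mixing matrix (default TRUE);
#'   `FALSE` draws a general well-conditioned invertible matrix.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(ch = 8, fs = 256, duration_s = 40, n_recordings = 10,
                       separation = 4, band_hz = c(10, 30), noise_sd = 0.1,
                       mixing_seed = 101, noise_seed = 202,
                       orthogonal = TRUE) {
  stopifnot(ch >= 2, fs > 0, duration_s > 0, n_recordings >= 1,
            separation >= 0, length(band_hz) == 2, band_hz[1] > 0,
            band_hz[2] > band_hz[1], band_hz[2] < fs / 2, noise_sd >= 0)
  structure(list(ch = as.integer(ch), fs = fs, duration_s = duration_s,
                 n_recordings = as.integer(n_recordings),
                 separation = separation, band_hz = band_hz,
                 noise_sd = noise_sd, mixing_seed = as.integer(mixing_seed),
                 noise_seed = as.integer(noise_seed),
                 orthogonal = isTRUE(orthogonal)),
            class = "synth_spec")
}

synth_mixing <- function(spec) {
  set.seed(spec$mixing_seed)
  G <- matrix(stats::rnorm(spec$ch^2), spec$ch)
  if (spec$orthogonal) {
    qr_ <- qr(G)
    A <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), spec$ch)
  } else {
    # push singular values away from zero for a well-conditioned mixture
    sv <- svd(G)
    A <- sv$u %*% diag(sv$d / max(sv$d) * 0.8 + 0.2, spec$ch) %*% t(sv$v)
  }
  A
}

synth_source_vars <- function(spec, class) {
  v <- rep(1, spec$ch)
  s <- 1 + spec$separation
  if (class == "A") {
    v[1] <- s
    v[spec$ch] <- 1 / s
  } else {
    v[1] <- 1 / s
    v[spec$ch] <- s
  }
  v
}

#' Generate a labeled synthetic dataset
#'
#' Class A recordings are labeled `PD_OFF` and class B `HC`. Each recording
#' draws fresh sources and noise; everything is reproducible from the two
#' seeds in the spec.
#'
#' @param spec a [synth_spec()].
#' @return List of `2 * n_recordings` `eeg_recording` objects (class A
#'   first).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  A <- synth_mixing(spec)
  n <- round(spec$duration_s * spec$fs)
  bf <- signal::butter(4, spec$band_hz / (spec$fs / 2), type = "pass")
  set.seed(spec$noise_seed)
  recs <- list()
  for (class in c("A", "B")) {
    vars <- synth_source_vars(spec, class)
    for (r in seq_len(spec$n_recordings)) {
      src <- matrix(0, spec$ch, n)
      for (j in seq_len(spec$ch)) {
        w <- signal::filtfilt(bf, stats::rnorm(n))
        src[j, ] <- w / stats::sd(w) * sqrt(vars[j])
      }
      x <- A %*% src
      if (spec$noise_sd > 0)
        x <- x + matrix(stats::rnorm(spec$ch * n, sd = spec$noise_sd),
                        spec$ch, n)
      recs[[length(recs) + 1L]] <- recording(
        x, spec$fs,
        subject_id = sprintf("synth_%s%02d", class, r),
        group = if (class == "A") "PD_OFF" else "HC",
        eyes = "CLOSED")
    }
  }
  recs
}

#' Closed-form class covariances of the synthetic model
#'
#' Returns the theoretical spatial covariances
#' `A diag(v_class) A' + noise_sd^2 I`, trace-normalized, for use as ground
#' truth in CSP recovery checks.
#'
#' @param spec a [synth_spec()].
#' @param A optional mixing matrix; defaults to the one the spec generates.
#' @return List with `C_A`, `C_B` (unit-trace matrices) and `A`.
#' @export
theoretical_covariances <- function(spec, A = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(A)) A <- synth_mixing(spec)
  mk <- function(class) {
    C <- A %*% diag(synth_source_vars(spec, class), spec$ch) %*% t(A) +
      spec$noise_sd^2 * diag(spec$ch)
    C / sum(diag(C))
  }
  list(C_A = mk("A"), C_B = mk("B"), A = A)
}
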