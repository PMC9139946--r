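# Shared fixtures and independent reference implementations used to
# cross-check the package's own code paths.

# random symmetric positive-definite matrix with unit trace
rand_spd <- function(ch) {
  G <- matrix(rnorm(ch * ch), ch)
  C <- crossprod(G) + diag(ch) * 0.1
  C / sum(diag(C))
}

# draw zero-mean segments whose population covariance is exactly C (up to
# sampling noise), via the Cholesky factor
segments_from_cov <- function(C, n_segments, N) {
  L <- t(chol(C))
  lapply(seq_len(n_segments), function(i)
    L %*% matrix(rnorm(nrow(C) * N), nrow(C), N))
}

# generalized-eigendecomposition oracle for CSP: solves C_A v = lambda
# (C_A + C_B) v directly; returns eigenvalues descending and unit-norm
# filter directions as rows
csp_oracle <- function(C_A, C_B) {
  M <- solve(C_A + C_B) %*% C_A
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  W <- t(apply(t(vecs), 1, function(r) r / sqrt(sum(r^2))))
  list(values = vals, W = W)
}

# Mann-Whitney pair-counting AUC oracle (ties count one half)
auc_pair_oracle <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# naive double-loop feature references (deliberately slow and literal)
ref_features <- function(S, metric, alpha = 0.2, p = 1.1, q = 3) {
  d <- nrow(S); N <- ncol(S)
  f <- numeric(d)
  vars <- numeric(d)
  for (j in seq_len(d)) {
    mu <- sum(S[j, ]) / N
    vars[j] <- sum((S[j, ] - mu)^2) / N
  }
  for (j in seq_len(d)) {
    s <- S[j, ]
    f[j] <- switch(metric,
      VAR = log(vars[j] / sum(vars)),
      BP = log(sum(s^2) / N),
      ENG = sum(s^2),
      THEN = { cnt <- 0; for (x in s) if (abs(x) > alpha) cnt <- cnt + 1; cnt },
      NOEN = { acc <- 0; for (x in s) acc <- acc + abs(x)^p; acc },
      SUEN = {
        cnt <- 0; acc <- 0
        for (x in s) {
          if (abs(x) <= q) cnt <- cnt + 1
          acc <- acc + min(x^2, q^2)
        }
        N - cnt + acc
      },
      LOGEN = { acc <- 0; for (x in s) if (x != 0) acc <- acc + log(x^2); acc },
      SHEN = { acc <- 0; for (x in s) if (x != 0) acc <- acc + x^2 * log(x^2); acc })
  }
  f
}

# small ready-made two-class segment set built from fixed covariances
toy_segment_set <- function(ch = 4, n_per_class = 30, N = 64, seed = 42,
                            spread = 3) {
  set.seed(seed)
  d_A <- seq(spread, 1, length.out = ch)
  d_B <- rev(d_A)
  segs_A <- segments_from_cov(diag(d_A / sum(d_A)), n_per_class, N)
  segs_B <- segments_from_cov(diag(d_B / sum(d_B)), n_per_class, N)
  structure(list(
    segments = c(segs_A, segs_B),
    labels = rep(c("PD_OFF", "HC"), each = n_per_class),
    subjects = rep(sprintf("s%d", 1:6), length.out = 2 * n_per_class),
    T_s = N / 128, fs = 128, N = N, ch = ch, band = NULL),
    class = "segment_set")
}

sine_recording <- function(freq, fs = 512, secs = 6, ch = 2, amp = 1) {
  t <- seq(0, secs - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  recording(rbind(x, x), fs, group = "HC")
}
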