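test_that("worked feature examples evaluate to their hand-derived values", {
  # variance: equal-variance rows split the normalization evenly
  S <- rbind(c(1, -1, 1, -1), c(1, -1, 1, -1))
  expect_equal(feat_variance(S), c(log(0.5), log(0.5)))
  # population-variance convention: rows [1,-1,...] and [2,-2,...]
  S2 <- rbind(c(1, -1, 1, -1), c(2, -2, 2, -2))
  expect_equal(feat_variance(S2), c(log(1 / 5), log(4 / 5)))

  expect_equal(feat_bandpower(rbind(rep(1, 7))), 0)
  expect_equal(feat_bandpower(rbind(c(1, 2, 3))), log(14 / 3))

  expect_equal(feat_energy(rbind(c(1, 2, 3))), 14)
  expect_equal(feat_energy(rbind(rep(0, 5))), 0)

  expect_equal(feat_threshold_entropy(rbind(c(0.1, 0.3, -0.5)), alpha = 0.2), 2)
  expect_equal(feat_threshold_entropy(rbind(c(0.1, 0.3, -0.5)), alpha = 9), 0)
  expect_equal(feat_threshold_entropy(rbind(c(0.1, 0.3, -0.5)), alpha = 0), 3)

  expect_equal(feat_norm_entropy(rbind(c(1, -1, 0)), p = 1.1), 2)
  expect_equal(feat_norm_entropy(rbind(c(2)), p = 1.1), 2^1.1)

  expect_equal(feat_sure_entropy(rbind(c(1, 2, 4)), q = 3), 3 - 2 + (1 + 4 + 9))
  expect_equal(feat_sure_entropy(rbind(c(1, 2)), q = 3), 5)         # = energy
  expect_equal(feat_sure_entropy(rbind(c(4, -5)), q = 3), 2 + 2 * 9)

  expect_equal(feat_log_energy_entropy(rbind(c(1, exp(1)))), 2)
  expect_equal(feat_log_energy_entropy(rbind(c(1, 1, 1))), 0)
  expect_equal(feat_log_energy_entropy(rbind(c(0, 1))), 0)

  expect_equal(feat_shannon_entropy(rbind(c(1, 1))), 0)
  expect_equal(feat_shannon_entropy(rbind(c(0, 0))), 0)
  expect_equal(feat_shannon_entropy(rbind(c(2))), 4 * log(4))
})

test_that("all eight metrics match the naive double-loop reference", {
  set.seed(30)
  for (rep in 1:5) {
    S <- matrix(rnorm(4 * 50), 4)
    expect_equal(feat_variance(S), ref_features(S, "VAR"), tolerance = 1e-10)
    expect_equal(feat_bandpower(S), ref_features(S, "BP"), tolerance = 1e-10)
    expect_equal(feat_energy(S), ref_features(S, "ENG"), tolerance = 1e-10)
    expect_equal(feat_threshold_entropy(S, 0.2), ref_features(S, "THEN"),
                 tolerance = 1e-10)
    expect_equal(feat_norm_entropy(S, 1.1), ref_features(S, "NOEN"),
                 tolerance = 1e-10)
    expect_equal(feat_sure_entropy(S, 3), ref_features(S, "SUEN"),
                 tolerance = 1e-10)
    expect_equal(feat_log_energy_entropy(S), ref_features(S, "LOGEN"),
                 tolerance = 1e-10)
    expect_equal(feat_shannon_entropy(S), ref_features(S, "SHEN"),
                 tolerance = 1e-10)
  }
})

test_that("metric identities and monotonicity properties hold", {
  set.seed(31)
  S <- matrix(rnorm(6 * 80), 6)
  # variance features are normalized log proportions
  expect_equal(sum(exp(feat_variance(S))), 1)
  # energy = N * exp(band power)
  expect_equal(feat_energy(S), ncol(S) * exp(feat_bandpower(S)))
  # norm entropy at p = 2 equals energy
  expect_equal(feat_norm_entropy(S, p = 2), feat_energy(S))
  # nonnegative functionals
  expect_true(all(feat_energy(S) >= 0))
  expect_true(all(feat_norm_entropy(S, 1.1) >= 0))
  expect_true(all(feat_threshold_entropy(S, 0.2) >= 0))
  expect_true(all(feat_sure_entropy(S, 3) >= 0))
  # threshold entropy nonincreasing in alpha; sure entropy nondecreasing in q
  alphas <- c(0.1, 0.5, 1, 2)
  th <- sapply(alphas, function(a) feat_threshold_entropy(S, a))
  expect_true(all(apply(th, 1, function(r) all(diff(r) <= 0))))
  # sure entropy limit cases: below every amplitude it is the count-plus-
  # N*q^2 form (increasing in q); above every amplitude it equals energy
  qmax <- max(abs(S))
  expect_equal(feat_sure_entropy(S, qmax + 1), feat_energy(S))
  tiny <- min(abs(S)) / 2
  expect_equal(feat_sure_entropy(S, tiny),
               rep(ncol(S) + ncol(S) * tiny^2, nrow(S)))
  # scaling by c adds 2 log c to band power
  expect_equal(feat_bandpower(3 * S), feat_bandpower(S) + 2 * log(3))
})

test_that("extract_features composes spatial filtering with the metric", {
  set.seed(32)
  segs <- toy_segment_set(ch = 4, n_per_class = 10, N = 64)
  model <- csp_reduce(fit_csp(segs, class_A = "PD_OFF", class_B = "HC"), 2)
  fm <- extract_features(model, segs, feature_config("ENG"))
  expect_equal(dim(fm$values), c(20, 4))
  expect_equal(fm$labels, segs$labels)
  i <- 7
  expect_equal(fm$values[i, ],
               unname(feat_energy(spatial_filter(model, segs$segments[[i]]))),
               ignore_attr = TRUE)

  # identical segments give identical rows
  segs2 <- segs
  segs2$segments <- rep(segs$segments[1], 4)
  segs2$labels <- segs$labels[1:4]
  segs2$subjects <- segs$subjects[1:4]
  fm2 <- extract_features(model, segs2, feature_config("VAR"))
  expect_true(all(apply(fm2$values, 2, function(col) all(col == col[1]))))

  # every metric stays finite on Gaussian segments
  for (met in c("VAR", "BP", "ENG", "THEN", "NOEN", "SUEN", "LOGEN", "SHEN")) {
    fm3 <- extract_features(model, segs, feature_config(met))
    expect_true(all(is.finite(fm3$values)), info = met)
  }
})

test_that("feature matrices export to CSV with the label column last", {
  set.seed(33)
  segs <- toy_segment_set(ch = 4, n_per_class = 5, N = 32)
  model <- fit_csp(segs, class_A = "PD_OFF", class_B = "HC")
  fm <- extract_features(model, segs, feature_config("BP"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, p)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(names(back)[ncol(back)], "label")
  expect_equal(back$label, fm$labels)
  expect_equal(as.matrix(back[, -ncol(back)]), fm$values,
               ignore_attr = TRUE, tolerance = 1e-6)
})
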