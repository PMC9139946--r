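---
title: "Common spatial patterns for two-class EEG discrimination: model, features, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common spatial patterns for two-class EEG discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspeeg)
```

## The model

CSP assumes that the two classes — here PD patients (off or on
medication) and healthy controls — differ in the *spatial covariance* of
their band-limited EEG: some linear combination of channels has
systematically higher variance in one class than the other. The
decomposition finds those combinations directly. Writing the averaged
trace-normalized class covariances as $\bar C_{PD}$ and $\bar C_{HC}$,
the composite $C_C = \bar C_{PD} + \bar C_{HC}$ is whitened by
$P = \lambda^{-1/2} U'$ (from $C_C = U \lambda U'$), and the whitened
class covariances $S_{PD} = P \bar C_{PD} P'$ and
$S_{HC} = P \bar C_{HC} P'$ then share eigenvectors and satisfy
$S_{PD} + S_{HC} = I$. Diagonalizing $S_{PD} = B \lambda_{PD} B'$ with
$\lambda_{PD}$ descending gives the projection $W = B'P$ whose first row
maximizes, and last row minimizes, the PD-to-total variance ratio.

The $-1/2$ exponent in the whitening transform is essential: it is the
unique choice that makes $P C_C P' = I$, which in turn forces the
complementary eigenvalue identity $\lambda_{PD} + \lambda_{HC} = 1$ the
rest of the construction (and our test suite) relies on. The identity,
the simultaneous diagonalization of both class covariances, and the
equivalence with a generalized eigendecomposition of
$(\bar C_{PD}, C_C)$ are all asserted to $10^{-8}$ on random
symmetric-positive-definite instances up to 16 channels.

Assumptions worth keeping in mind: covariance stationarity within a
segment, a common mixing geometry across subjects within a class (CSP is
fit on pooled segments), and exactly two classes. Trace normalization
makes the decomposition invariant to overall amplitude scaling, which the
tests check explicitly.

## Numerical choices

* **Eigenvalue ordering and signs.** Both eigendecompositions sort
  descending; each filter row is flipped so its largest-magnitude entry
  is positive. CSP is sign-invariant downstream, so this is purely a
  determinism device — identical input gives bitwise-identical models.
  Exactly repeated eigenvalues make the corresponding filters non-unique;
  the package makes no attempt to disambiguate them and the tests avoid
  constructed ties.
* **Segment centering.** Each channel's mean is removed within each
  segment before the covariance (configurable via `center = FALSE`),
  making the estimate a true covariance rather than a second moment.
* **Rank deficiency.** If the composite covariance has an eigenvalue
  below $10^{-10}$ of its largest, fitting stops with an error by
  default; an explicit ridge (`reg`) floors the spectrum instead when the
  user opts in. Silent regularization can hide broken inputs (e.g. a
  dead channel), so it is never automatic.
* **Filtering.** The band-pass is a fifth-order Butterworth applied
  forward–backward (`signal::filtfilt`): zero phase across channels at
  the cost of doubling the effective order. Whether to filter causally
  instead is a genuine design fork in offline EEG work; zero-phase is the
  standard choice for non-causal analysis and is what we commit to.
  Segment remainders shorter than one window are dropped.

## Features and their parameters

Each of the $d = 2m$ retained components of a filtered segment is reduced
to one number. `VAR` is the classical log normalized variance; `BP` and
`ENG` are log mean power and total energy. The five entropies follow the
wavelet-entropy convention: they are evaluated on the *raw component
samples*, not on a probability histogram, because their parameters are
amplitude thresholds — the threshold entropy counts samples with
$|s| > \alpha$ (default $\alpha = 0.2$), the sure entropy uses the
amplitude threshold $q$ (default 3, values $\le 2$ warn), and the norm
entropy a power $p \ge 1$ (default 1.1). Natural logarithms throughout;
$\log(0)$ terms contribute zero so exact-zero samples are harmless. The
Shannon-type functional is implemented as $\sum s^2 \log s^2$ with no
leading minus — a global sign flip is irrelevant to every classifier
downstream. One caveat follows from the definitions: $\alpha$ and $q$
are on the data's amplitude scale, and the package never rescales input
data, so these two features (unlike everything else in the pipeline) are
not invariant to the units of the recording.

A note on the sure entropy: it is *not* globally monotone in $q$ — the
count term drops by one every time $q$ crosses a sample amplitude even
as the clipped-energy term grows. The tests therefore pin down its two
limit identities (it equals the energy once $q$ exceeds every amplitude,
and $N(1 + q^2)$ once $q$ is below every amplitude) rather than a
monotonicity that does not hold.

## Evaluation protocol

Folds are stratified by class label: within each class, indices are
shuffled by the run's seed and dealt round-robin, so per-class test
counts differ by at most one. The CSP model is fit per fold on training
segments only and reused on the fold's test segments; a sentinel test
(corrupting test segments by six orders of magnitude and checking the
projection is bit-identical) guards this in the suite. Metrics are on
the percent scale; a zero-denominator metric is reported as `NA`, never
silently as zero. The ROC sweeps every distinct score as a threshold and
the trapezoidal AUC is verified against a Mann–Whitney pair-count oracle
to $10^{-12}$.

Segment-level cross-validation matches common practice for this problem
but lets segments of one subject appear in both training and test folds,
which inflates accuracy relative to true subject generalization;
`cv_mode = "subject"` holds out whole subjects instead. Neither mode is
claimed to reproduce any external study's split. Classifier defaults
(KNN $k_n = 3$, 100 forest trees, SVM cost 1 with a degree-2 polynomial
kernel) are stated in `classifier_spec()` and configurable.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws `ch` latent Gaussian sources band-limited to
10–30 Hz, gives class A source 1 a variance of $1 + s$ and source `ch` a
variance of $1/(1+s)$ (class B mirrored), mixes through a random
orthogonal matrix, and adds white sensor noise (sd 0.1 against
unit-variance sources). This is exactly the covariance-difference model
under which CSP is the right detector, and the closed-form class
covariances (`theoretical_covariances()`) make parameter recovery
checkable: with separation 4 the theoretical top eigenvalue is
$5/5.2 \approx 0.962$, and the fitted leading filter aligns with the
true unmixing direction to cosine $\ge 0.95$.

The default sizes — 8 channels at 256 Hz, ten 40-second recordings per
class, 2-second segments, hence 200 segments per class — are the
conditions every end-to-end check runs under; the sweep checks use a
lighter 128 Hz, five-recording variant. What the generator deliberately
omits: $1/f$ spectra, artifacts, nonstationarity, inter-subject
variability, and volume-conduction structure. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers planted
covariance structure and stays at chance when none exists — not that any
particular accuracy will be achieved on clinical recordings.

With a single boosted/attenuated source pair, two CSP components already
carry all class information, so the reduction-number sweep on synthetic
data plateaus from $d = 2$; on real recordings, where discriminative
variance is spread over many components, the same sweep rises before it
plateaus. The band sweep contrast is sharper: sources planted at
10–30 Hz give an in-band versus delta-band accuracy gap of 50 points on
the default dataset.

## Known limitations

Two-class only (no multi-class CSP joint diagonalization); no artifact
rejection or re-referencing — inputs are assumed pre-cleaned; no
regularized or shrinkage CSP variants; EDF/BDF support covers
continuous single-rate recordings, not annotations or discontinuous
files; and entropy thresholds are unit-dependent as noted above.
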