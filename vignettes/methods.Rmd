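---
title: "Methods: homotopy-based channel selection for block-design fNIRS decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homotopy-based channel selection for block-design fNIRS decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the signal model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and design
choices made where the problem left them open.

## 1. Signal model and pipeline

fNIRS measures cortical hemodynamics optically: light attenuation changes
at two near-infrared wavelengths are converted into oxy- and
deoxyhemoglobin concentration changes (HbO/HbR, in uM) by the modified
Beer-Lambert law (MBLL),

$$\begin{bmatrix}\Delta C_{HbO}\\ \Delta C_{HbR}\end{bmatrix}
 = E^{-1}\begin{bmatrix}\Delta A(\lambda_1)\\ \Delta A(\lambda_2)\end{bmatrix}
 \frac{1}{d\,l},$$

with $E$ the 2x2 extinction matrix (uM$^{-1}$cm$^{-1}$), $l$ the
source-detector separation and $d$ the differential path-length factor.
`mbll_params()` accepts a scalar $d$ (the printed relation carries a single
factor) or a per-wavelength pair, since path length is in reality weakly
wavelength-dependent. A default extinction table for 760/830 nm from a
standard literature compilation ships as a text resource; every
correctness test uses synthetic matrices, so nothing depends on those
defaults.

The decoding paradigm is a block design: 30 s quiet rest, ten trials of
10 s treadmill walking + 20 s standing rest, and a closing 30 s rest used
for baseline correction. The stated trial arithmetic sums to 360 s, which
is the package default (`default_paradigm()`); total duration is fully
configurable. Time is discretised as sample $k$ at $t = k/f_s$ with
half-open block intervals $[on, on+dur)$, so a sample at exactly a block
onset belongs to the new block — an explicit convention that removes all
boundary ambiguity. Analysis observations come from the trial portion
only (10 task + 10 rest blocks): the lead-in rest and the baseline block
are excluded, keeping the two classes balanced.

Preprocessing mirrors standard fNIRS practice: a band-pass of
0.01–0.5 Hz, Gaussian temporal smoothing, discrete-cosine detrending and
baseline subtraction. The band-pass is an order-4 Butterworth, applied
forward–backward (zero phase) — the filter family and order are
conventional choices, made here because a monotone passband and zero lag
matter for feature extraction; the effective magnitude response is the
squared single-pass response, which the tests verify directly at the
acquisition rate (DC gain below $10^{-3}$, 0.1 Hz within 10% of unity,
0.8 Hz below 0.2). Gaussian smoothing with FWHM 4 s stands in for the
hemodynamic-response smoothing of the usual SPM-style toolchain: it is a
functional equivalent, not a re-implementation. DCT detrending removes
the constant term plus every cosine basis function with period longer
than 128 s (the common SPM cutoff), and leaves the series orthogonal to
the removed basis.

## 2. The homotopy solver

Channel selection and sparse coding both reduce to the LASSO problem

$$\min_\beta \; \frac{1}{2N}\lVert y - X\beta\rVert_2^2
  + \lambda \sum_j |\beta_j|.$$

`solve_path()` traces the exact solution path in $\lambda$ by LARS-style
homotopy. At $\lambda_{max} = \max_j |X_j^\top y|/N$ the solution is
identically zero; as $\lambda$ decreases, coefficients move linearly
along the direction solving the active-set normal equations with the
active sign vector, and at each breakpoint a predictor either enters
(its residual correlation reaches $\lambda$) or leaves (its coefficient
crosses zero). The path is returned as breakpoints + coefficient
matrix; any interior solution is an exact linear interpolation.

Numerical contract, in full:

* **KKT certificate.** Every breakpoint satisfies
  $X_j^\top(y - X\beta)/N = \lambda\,\mathrm{sign}(\beta_j)$ for active
  $j$ and $|X_j^\top(y-X\beta)/N| \le \lambda$ for inactive $j$, within
  1e-8 (measured values are ~1e-15). `kkt_residual()` exposes the check.
* **Ties.** Two predictors reaching the entry condition within 1e-12 of
  the same $\lambda$: the smaller column index enters. A removal at the
  same $\lambda$ as an entry is processed first. This makes the solver
  bit-deterministic.
* **Degeneracy.** A numerically singular active Gram matrix falls back
  to a ridge-stabilised solve ($\epsilon = 10^{-10}$) with a warning.
  Exactly duplicated predictors never co-enter the active set (the
  duplicate's entry condition is unreachable), so collinear designs
  degrade gracefully.
* **Termination.** The path stops at
  $\lambda_{min} = r \cdot \lambda_{max}$ with $r$ =
  `lambda_min_ratio` (default 1e-4, i.e. "approximately zero"); at the
  end of the path on full-rank problems the solution coincides with
  least squares up to $O(\lambda_{min})$, which the endpoint tests
  verify with $r = 10^{-10}$.
* **Standardisation.** By default $y$ is centred and the columns of $X$
  z-scored, because the l1 penalty is scale-sensitive;
  `unstandardize_coefs()` maps back. Sparse coding over a dictionary
  sets `standardize = FALSE`: atoms are unit-normalised at construction
  instead, which is what makes class-wise reconstruction residuals
  comparable.

The solver is cross-checked in the test suite against two independent
oracles — the closed-form soft-threshold path on orthonormal designs,
and a from-scratch cyclic coordinate-descent minimiser run to 1e-10 —
plus the least-squares endpoint.

Sparse representation classification (`src_classify()`) codes a test
signal over labelled training atoms with the same path solver and
assigns the class minimising
$r_c = \lVert b - A\,\delta_c(x)\rVert_2$, where $\delta_c$ keeps the
class-$c$ coefficients. The error term of the dictionary model is kept
as documented metadata (`noise_tolerance`); the implemented coding is
the penalised form, with the penalty as the sparsity knob, because the
constrained ($\epsilon$-form) variant is never pinned down by the method
description. A code that is identically zero abstains rather than
guessing.

## 3. Channel selection design

`build_design()` regresses the per-sample labels ($+1$ walk, $-1$ rest)
on the preprocessed HbO channels — the most direct reading of "channels
as predictors of the output variable". Two design choices deserve
explicit justification:

* **Hemodynamic lag compensation (default `label_shift_s = 6`).** The
  evoked response peaks ~6 s after block onset and decays well into the
  following rest. Labelling samples by the *instantaneous* block makes
  the response nearly orthogonal to the labels: measured on simulated
  data, informative channels correlate with unshifted labels at ~0.09,
  *below* the chance correlation of noise channels, and no method can
  select channels from that design. Shifting the labels by the canonical
  time-to-peak restores correlations of ~0.75. The shift is a parameter;
  0 recovers strictly instantaneous labelling.
* **Trial-level CV folds.** The penalty is chosen by minimising 5-fold
  cross-validated prediction MSE on a 50-point log-spaced grid spanning
  $[\lambda_{min}, \lambda_{max}]$. Folds hold out whole trials
  (stratified over task and rest blocks), not individual samples:
  consecutive samples are strongly autocorrelated after smoothing, so
  sample-level folds would place near-identical neighbours in training
  and test sets. Chance alignments of a channel's slow noise with the
  block structure would then "validate", and the CV minimum slides to
  dense supports. With trial-level folds the CV minimum sits where
  held-out trials are genuinely predicted. The plain CV-minimum rule is
  used (no one-standard-error rule) as the least-assuming choice; the
  full CV curve is returned for inspection.

Channels with standardised coefficient magnitude above 1e-8 at the
chosen penalty are selected; if that set is empty the result falls back
to the largest penalty with a nonzero coefficient and carries a
`fallback` flag. Selection is per subject, matching the subject-wise
channel lists the approach is known for.

## 4. Features and classifiers

Block-wise statistical features are the comparison arm: signal mean,
peak (maximum), variance and skewness of each channel within each
analysis block, channel-major. Variance uses denominator $n-1$, exactly
as the source relation prints. The printed skewness relation
(squared deviations over $N\sigma$) is dimensionally not a skewness; the
standard third standardised moment with divisor $N$ is implemented and
the discrepancy treated as an erratum rather than reproduced.

The classifier trio: diagonal-covariance LDA (pooled per-feature
variances, floored at 1e-9 so degenerate features cannot produce
infinities), logistic regression (IRLS with a weak L2 penalty of 1e-4 on
the slopes — a deliberate, documented deviation from unpenalised
logistic regression purely so separable data cannot diverge), and a
Gaussian-kernel soft-margin SVM with $C = 1$ and
$\gamma = 1/(P \cdot \mathrm{var}(X))$. Accuracy is pooled stratified
k-fold CV (default $k = 5$, fold seed 2575), exactly reproduced by a
hand-rolled loop in the tests. Post-selection classification uses the
per-sample HbO vectors of the selected channels by default, consistent
with the selection design; block features remain available. Note that
sample-level CV on within-recording data shares the leakage caveat of
Section 3 — reported per-sample accuracies are internal comparisons
between pipelines, not estimates of out-of-session transfer. Paired
two-tailed t-tests with Bonferroni correction ($\alpha = 0.05/3 =
0.0167$ for the three pairwise comparisons) assess classifier
differences; identical accuracy vectors (zero-variance differences) are
an error, not a p-value.

## 5. What the generator emulates — and what it does not

`sim_config()` defaults encode the target acquisition: 12 channels,
$f_s = 1.81$ Hz, informative channels {2, 5, 9}, the 360 s paradigm, a
double-gamma hemodynamic response (peak 6 s, undershoot 16 s, ratio 1/6
— the SPM-convention shape, chosen because no specific response model is
prescribed), and additive noise: random-phase sinusoids at 0.28 Hz
(respiratory, sd 0.3 uM) and 1.1 Hz (cardiac, aliasing to 0.71 Hz at
this sampling rate), linear drift (ramp sd 0.2 uM) and white noise
(sd 0.5 uM). The published noise-frequency statement is internally
inconsistent (it exceeds the Nyquist rate of the stated sampling
frequency and inverts typical physiology), so the defaults use
physiologically conventional values; the configuration accepts any
frequencies, including the stated ones, verbatim.

The convolved task regressor is normalised to unit peak before scaling,
so `amplitude_uM` is the actual peak response amplitude and
`snr = amplitude_uM / sd(total noise)` means exactly what it says —
without that normalisation a 10 s boxcar convolved with the response
kernel would carry an arbitrary factor of ~10 and the SNR dial would be
mislabelled. The drift and white-noise sds are the package's own
choices (the acquisition description fixes only the sinusoid sds);
0.2/0.5 uM keep the three noise families within a factor of ~2 of one
another, which is the regime where preprocessing has visible work to do.
HbR is generated as $-0.3 \times$ HbO plus independent noise solely to
exercise the optical-density path; no physiological claim attaches to it.

What passing tests on this generator show: the pipeline recovers planted
structure (selection concentrates on the informative set, recovery
improves with SNR, selection beats the all-channel feature baseline, and
permuted labels fall to chance). What they cannot show: behaviour under
motion artifacts, optode-coupling drift, spatially correlated
physiology, inter-subject anatomical variability, or session-to-session
transfer — none of which the generator models. Published accuracies from
the motivating study are shipped as a reference table
(`reported_accuracies()`) for aggregation checks only; they are not
reproducible without the original recordings.

## 6. Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use problem sizes chosen to
exercise every code path at interactive cost: 50 random regression
problems ($N = 30$, $P = 8$) for the solver certificates, 100 random
parameter draws for the MBLL round trip, 20 simulation seeds per SNR
level for channel recovery, and 20 nine-subject cohorts for the
selection-vs-baseline comparison. Every random quantity is driven by an
explicit integer seed, fold assignments are deterministic given theirs,
and the solver itself is seed-free and bit-deterministic, so complete
runs are exactly reproducible.

## 7. Known limitations

* Per-sample post-selection accuracy is an optimistic within-recording
  estimate (Section 4); trial-level evaluation of the *classifiers* (as
  opposed to the selection CV) is intentionally left to the caller via
  the feature workflow.
* The homotopy solver targets the dense small-$P$ regime of this
  application (tens of predictors); it makes no claims for
  high-dimensional sparse designs, where specialised solvers with
  covariance updates would be preferable.
* SNIRF/HDF5 import is not provided; the package reads its own
  delimited-text dialect only.
* Binary classification only, offline only — both inherent to the
  design being modelled.
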