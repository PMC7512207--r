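---
title: "Methods: spectral and nonlinear EEG discrimination of AD, MCI and controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral and nonlinear EEG discrimination of AD, MCI and controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

Resting-state EEG in Alzheimer's disease (AD) shows a characteristic
slowing — power shifts from alpha/beta into delta/theta, the alpha peak
drifts down — together with a loss of signal irregularity. Mild cognitive
impairment (MCI) sits between AD and healthy controls (HC) on both axes.
`eegdx` implements a complete three-class discrimination pipeline built on
those phenomena: 19-channel, 200 Hz recordings are filtered (1–70 Hz FIR
band-pass, 50 Hz notch) and cut into 5-s trials; each trial is summarized
by 14 channel-averaged features; a fast correlation-based filter (FCBF)
prunes redundant features on the training subjects; LDA, QDA and a
single-hidden-layer MLP classify trials; and each subject receives the
majority-vote diagnosis of its trials, evaluated with confusion matrices,
Cohen's kappa and one-vs-all screening metrics.

## Features

All features are computed per channel on each 5-s trial and averaged over
channels.

**Spectral (9).** The per-epoch power spectral density is estimated by
Welch's method (1-s Hamming windows, 50% overlap — 1 Hz resolution at
200 Hz; a raw periodogram with 0.2 Hz resolution is available via
`estimator = "periodogram"`), truncated to 1–70 Hz and normalized to unit
mass (`PSDn`). From it: relative power in delta (1–4 Hz), theta (4–8),
alpha (8–13), beta-1 (13–19), beta-2 (19–30) and gamma (30–70) — bands
treated half-open so they tile the range and their powers sum to exactly 1;
the median frequency MF (smallest grid point where the cumulative mass
reaches one half); the individual alpha frequency IAF (the same rule
restricted to the extended alpha band 4–15 Hz); and the spectral entropy SE
(Shannon entropy of `PSDn` normalized by the log bin count so SE is in
\[0, 1\] — the unnormalized form cannot produce the \[0, 1\]-scale values
reported for real cohorts).

Two conventions deserve a note. The printed IAF definition accumulates mass
from 1 Hz up to half of the 4–15 Hz mass; with realistic delta power that
accumulation saturates below the alpha band and pins IAF at its lower edge,
so the within-band reading (cumulative mass *inside* 4–15 Hz) is
implemented — it is the only reading under which IAF tracks the alpha peak.
The median-frequency rule returns a grid point; on the default 1 Hz grid a
9.5 Hz peak is therefore reported as 9 or 10, which is why sub-bin
recovery checks use the periodogram grid.

**Nonlinear (5).** Lempel–Ziv complexity (median binarization, `x >=
median` mapping to 1; subsequence count normalized by `N / log2(N)`);
the central tendency measure CTM (fraction of successive first-difference
points within radius ρ — computed on the z-scored epoch by default so one
radius is comparable across subjects); sample entropy (m = 1,
r = 0.1·SD, Chebyshev distance, strict `d < r`, self-matches excluded);
fuzzy entropy (m = 1, r = 0.1·SD, n = 3; mean-centred templates and
`exp(-d^n/r)` similarity — the inner normalization follows the standard
Chen convention under which a constant series scores exactly 0; the
printed variant with an `N-m+1` denominator does not have that property
and is treated as a typo); and auto-mutual information over lags 0–0.5 s
from a 16-bin equal-width 2-D histogram, normalized so AMI(0) = 1. The
scalar AMI summary defaults to the mean of the normalized profile over
positive lags; a slope summary (s⁻¹) is provided because the negative AMI
medians reported for real cohorts cannot arise from a mean of non-negative
normalized values — neither summary is asserted against those printed
values. The defaults ρ = 0.075, (m, r) = (1, 0.1·SD) and (m, r, n) =
(1, 0.1·SD, 3) are the stored optima of the Kruskal–Wallis grid search
(`select_nonlinear_params()` re-runs that search: for each grid point the
three-group Kruskal–Wallis p-value over training-trial values, argmin with
lexicographic tie-breaks).

Epochs whose sample entropy is undefined (no template matches) are
excluded from the channel average with a warning. A grid-search caveat:
Kruskal–Wallis is rank-based, so for the soft-kernel FuzzyEn a change of
`r` largely rescales the statistic and barely changes its discriminative
power — its selected grid point is consequently noise-driven in a way the
hard-threshold CTM/SampEn points are not.

## Feature selection, classification, evaluation

FCBF discretizes each feature against the class label (Fayyad–Irani MDL
binning, the method of the original FCBF publication; no relevance
threshold — every feature with positive symmetrical uncertainty enters),
ranks by `SU(X, Y)` and walks the ranking discarding any lower-ranked `Xj`
with `SU(Xi, Xj) >= SU(Xj, Y)` for a surviving `Xi`. SU ties break
lexicographically by feature name, making selection deterministic and
row-order invariant.

LDA and QDA are Gaussian class-conditional models (pooled vs per-class
covariance, empirical priors, ridge `1e-6 · trace/dim` if near-singular)
written in-package; `MASS` serves only as an independent test oracle.
The MLP has one logistic hidden layer, a 3-unit softmax output and a
cross-entropy error with quadratic weight decay `u` on the weights (biases
unpenalized), optimized by BFGS over an analytic gradient (C++), with seeded
deterministic initialization. `nnet` is not available in the target
environment, which is why the network is implemented here. Hyperparameters
(`u`, hidden units) are tuned by leave-one-subject-out CV on the training
subjects, scoring pooled held-out trials with Cohen's kappa averaged over
random restarts; the stored default (u = 45, 11 hidden units) is the
reported full-grid optimum. Features are standardized with training-set
statistics before every fit; test rows reuse those statistics.

Subjects are diagnosed by majority vote over their trials; ties break by
the highest mean posterior over the tied classes (logged). Evaluation
reports 3×3 confusion matrices (fixed order HC, MCI, AD), Cohen's kappa,
overall accuracy and one-vs-all blocks. For HC-vs-all the positive class is
*cognitively impaired* (MCI ∪ AD) — the only convention reproducing the
published sensitivity/PPV pattern and the one matching the screening
question "is this subject not healthy?"; for AD-vs-all the positive class
is AD. Undefined ratios are reported as `NA`, never silently 0.

## The synthetic cohort generator

No public EEG deposit exists for the reference cohort, so every stage is
exercised against a generative stand-in (`generate_cohort()`), which *is*
first-class, tested code. Each trial channel is spectrally shaped Gaussian
noise: six Gaussian band bumps (the alpha bump centred at the group's
alpha peak, FWHM 1.2 Hz) plus band-limited `1/f` noise, random phases,
channels formed as a common source plus independent same-spectrum channel
noise (mixing weight 0.3) — inter-channel structure only needs to be
plausible because features are channel-averaged. Defaults emulate the
reference cohort: 37 subjects/group, Gaussian trial counts (mean 46, SD 9,
clipped at 1), 200 Hz, 5-s epochs, 19 channels; alpha peaks
9.502/9.404/8.811 Hz (HC/MCI/AD); band weights are the groups' published
median relative powers *after pink compensation* — the `1/f` background
itself deposits mass in every band, so oscillator weights are solved as
`(target - nf·pinkshare) / (1 - nf)` (clamped, renormalized) to make the
realized relative powers match the target pattern. Per-subject jitter
(alpha peak SD 0.25 Hz, log-weight SD 0.15, logit-noise SD 0.2; scalable
via `jitter_scale`) keeps groups overlapping so classification is not
trivially perfect.

The irregularity dial is the pink-noise fraction: 0.60/0.45/0.30 for
HC/MCI/AD, chosen once so the published direction pattern (SampEn, FuzzyEn,
LZC, SE higher in HC; CTM higher in AD; IAF and MF lower in AD) emerges
robustly. The `1/f` exponent is kept at β = 1: steeper backgrounds were
evaluated and *invert* the dial, because strongly low-frequency-weighted
noise is itself regular at the sample scale. A consequence worth stating
plainly: with β = 1 the generated signals are considerably more irregular
at short lags than real EEG, so absolute SampEn/CTM magnitudes (≈2.3 /
≈0.01) do not match the published medians (≈1.37 / ≈0.11); only the group
*directions* are asserted anywhere in the tests. What a green direction
test establishes is that the pipeline orders the groups correctly on data
with the published spectral structure — not that the generator reproduces
real EEG dynamics (it is stationary, Gaussian and artifact-free, with no
volume conduction, nonstationarity or nonlinearity).

## A known limitation, stated honestly

One acceptance property is left deliberately failing: on cohorts whose
group signal is planted only in the alpha peak, the delta weight and the
noise fraction, FCBF is expected to select a set containing IAF, RP(δ)
*and SampEn*. IAF and RP(δ) are recovered reliably, but in a
stationary-Gaussian generator every feature is a functional of the
spectrum, and FuzzyEn measures the same irregularity latent as SampEn with
a wider effective kernel (soft threshold ≈0.46·SD vs hard 0.1·SD) and
hence lower estimator variance: across every construction tried
(documented in the test and the decisions ledger) `SU(FuzzyEn, Y)`
exceeds `SU(SampEn, Y)` while their mutual SU exceeds SampEn's relevance,
so FCBF always keeps FuzzyEn and discards SampEn. Reproducing the
published selection would require non-Gaussian or nonstationary dynamics
the generator deliberately does not model.

## Numerical choices

Filtering: order-660 Hamming windowed-sinc FIR (≈1 Hz transition at
200 Hz), applied as a centred symmetric convolution with reflective
padding (exact zero phase); notch as a 2nd-order band-stop biquad (2 Hz
bandwidth) run forward–backward. Continuous data are filtered before
segmentation, so epoch edges carry no filter transients. SampEn uses a
sort-based prefilter on the first template element (identical integer
counts, ~60× faster); FuzzyEn skips `exp` underflow (`z > 746`,
bit-identical). All randomness descends from one root seed through named
substreams (cohort, subject, split, MLP restarts, permutation), so every
cohort, fit and report is exactly reproducible. Tests and the acceptance
script scale cohort sizes (channels, trials per subject) below the
19-channel/46-trial defaults purely for run time, always asserting
medians, orderings or seeded-oracle equalities that the scaling leaves
meaningful; each test states its scaled size.
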