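---
title: "Unsupervised ERP decoding from label proportions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised ERP decoding from label proportions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llpspeller)
```

## The decoding problem

A visual ERP speller presents a grid of symbols and highlights subsets of
them in rapid succession. Each highlighting event evokes a transient EEG
response (an epoch); events that include the symbol the user attends
(*targets*) evoke a different average response than events that do not
(*non-targets*). A linear classifier on epoch features separates the two
classes, and summing classifier outputs per symbol over a trial selects
the spelled character. The standard obstacle is that training the
classifier requires labelled epochs, i.e. a calibration session.

`llpspeller` implements an unsupervised alternative built on *learning
from label proportions* (LLP). The stimulus schedule is arranged into two
kinds of highlighting blocks with different, known target proportions:

* **Sequence 1**: blocks of 8 events in which every selectable symbol is
  highlighted exactly 3 times. Whatever symbol the user attends, exactly
  3 of these 8 events are targets: the target proportion is 3/8.
* **Sequence 2**: blocks of 18 events in which every selectable symbol is
  highlighted exactly twice, with visual blanks (`#`) padding every event
  to the same 12 highlighted symbols. The target proportion is 2/18.

The group-wise mean feature vectors therefore satisfy a known linear
mixture model,

$$
\begin{pmatrix} \mu_1 \\ \mu_2 \end{pmatrix}
 = \Pi \begin{pmatrix} \mu_+ \\ \mu_- \end{pmatrix},
\qquad
\Pi = \begin{pmatrix} 3/8 & 5/8 \\ 2/18 & 16/18 \end{pmatrix},
$$

and inverting $\Pi$ (its Moore–Penrose pseudoinverse for more than two
groups) reconstructs the target and non-target class means from group
means alone — quantities that require no labels. For the study mixing the
inverse is

```{r}
round(pseudoinverse_coefficients(study_mixing()), 2)
```

so $\mu_+ = 3.37\,\mu_1 - 2.37\,\mu_2$ and
$\mu_- = -0.42\,\mu_1 + 1.42\,\mu_2$. (Direct inversion fixes the sign of
the leading target coefficient as $+3.37$; only the magnitudes matter for
the variance analysis below.)

The decoder is then the shrinkage-LDA projection
$w = \Sigma^{-1}(\mu_+ - \mu_-)$, with $\Sigma$ the pooled (global,
class-ignorant) shrinkage covariance of all observed epochs. Because
group means are consistent estimators, the whole decoder converges to its
supervised counterpart as unlabelled data accumulates — the property that
makes calibration-free online spelling possible.

## Noise amplification

Reconstruction through $\Pi^{-1}$ amplifies estimation noise: the
variance of each reconstructed class-mean coordinate is a weighted sum of
group-mean variances with the squared reconstruction coefficients as
weights. Summarized over both classes, with $G$ groups,

$$
\mathrm{NAF} = G \sum_{c \in \{+,-\}} \sum_{k=1}^{G} (\nu_{ck})^2,
$$

the *noise amplification factor*: how many times more data LLP needs than
a supervised mean estimate over the same pool. Pure groups
($\Pi = I$) give the minimum of 4 for two groups; the study mixing gives

```{r}
noise_amplification_factor(study_mixing())
```

The package verifies this calibration empirically (see the acceptance
suite): the ratio of simulated LLP class-mean variance to the variance of
a plain mean over the same total number of IID epochs reproduces the NAF
within a few percent, and learning curves for mixings with ascending NAF
are ordered accordingly at every training size.

## Stimulus scheduling

`generate_trial()` produces one character's schedule: 4 sequence-1 blocks
and 2 sequence-2 blocks (68 events), randomly interleaved at the block
level. Within each block the assignment of symbols to events is a
randomized constrained construction (greedy with forced placements and
restarts, capped at 10 000 restarts) satisfying:

* exactly 12 highlighted symbols per event;
* the per-sequence highlight counts above;
* no *selectable* symbol in two consecutive events, including across
  block boundaries (double-flash avoidance).

Blanks are exempt from the double-flash rule by design: a sequence-2
block has $18 \cdot 12 - 32 \cdot 2 = 152$ highlight slots to fill with
10 blanks, while 10 blanks restricted to alternating events could fill at
most $10 \cdot \lceil 18/2 \rceil = 90$; the constraint set would be
infeasible. Blanks are never attended, so a repeated blank does not
produce the perceptual error the rule exists to prevent. An event-level
interleaving mode (`interleave = "event"`) merges the six blocks
event-by-event under the same cross-boundary constraint. The
spatial-adjacency heuristics of the original sequence-optimization work
are not reproduced; the generator accepts the double-flash predicate
only.

Timing arithmetic is exposed by `spelling_timing()`: at a 250 ms SOA a
trial spans 17 s of highlighting plus 4 s cue and 4 s feedback, capping
the rate at 2.4 characters per minute.

## Preprocessing and features

The study pipeline is reproduced with these defaults (`feature_config()`):

| parameter | default | notes |
|---|---|---|
| band-pass | 0.5–8 Hz, Chebyshev II, order 3 | causal single-pass |
| stopband attenuation | 40 dB | not dictated by the pipeline description; documented constant |
| stopband-edge placement | factor 2 outside the band | see below |
| working rate | 100 Hz | decimation from 1 kHz by 10 |
| epoch window | [-200, 700) ms | half-open on the sample grid, 90 samples |
| baseline | [-200, 0) ms | per channel mean subtraction |
| intervals | [50,120], [121,200], [201,280], [281,380], [381,530], [531,700] ms | inclusive bounds on the 10 ms grid |
| channels | all but Fp1, Fp2 | 29 retained, 174 features |

A Chebyshev type II design is specified by its stopband corners. Handing
it the nominal band edges directly would put 4 Hz — the middle of the ERP
band — in the transition region (gain 0.48); the package therefore places
the stopband corners a factor 2 outside the nominal band, which keeps the
passband flat (gain 0.985 at 4 Hz) while 20 Hz content is attenuated
below 1 %. Filtering is causal by default because the decoder is meant to
run online; `causal = FALSE` gives zero-phase filtering for offline
re-analysis. Decimation keeps every 10th sample with no extra anti-alias
stage — the band-pass has already removed all content near the new
Nyquist frequency.

Millisecond-to-sample conversions are centralized and truncate toward
zero; epoch windows are half-open, interval bounds inclusive. The six
default intervals tile the post-onset samples from 50 ms to the window
edge without overlap at 100 Hz. Peak statistics (`peak_statistics()`)
break latency ties toward the earliest sample.

## The synthetic-data generator

No real EEG ships with the package; two generators stand in for it.

**Continuous synthesis** (`simulate_recording()`) places class-dependent
ERP templates at stimulus onsets and adds noise. The default templates
follow the study's grand-average morphology: an occipital Gaussian trough
of −8 µV at 150 ms (σ = 25 ms) and a central Gaussian bump of +2 µV at
400 ms (σ = 60 ms) for targets, and a zero non-target response. Noise is
AR(1) with ρ = 0.95 at 1 kHz and unit marginal variance, giving the
low-frequency-dominated spectrum typical of EEG without further
machinery. The paper this pipeline models does not define an SNR, so the
package defines it as the scaled template's peak amplitude divided by the
noise standard deviation; `snr = 8` therefore reproduces the raw −8 µV
trough against unit noise, and `snr = 0` removes the evoked signal.

**Feature-level sampling** (`sample_feature_epochs()`,
`simulate_study_epochs()`) draws epoch features directly from
class-conditional Gaussians, either with exact per-block target counts
(the paradigm's deterministic 3-of-8 / 2-of-18 composition) or as
independent Bernoulli draws (the IID setting the convergence theory
assumes). The ensemble experiments in the test suite use this level with
D = 30 features and three informative dimensions at a class separation
chosen so the supervised decoder reaches an AUC near 0.975 — the
supervised ceiling reported for high-quality visual ERP data. Sixty-three
characters per sentence (the bundled study sentence) and 20-seed
ensembles keep the whole suite within a few minutes on one CPU.

What the generator does *not* emulate: volume conduction and realistic
channel covariance (channels are independent up to the shared templates),
eye and muscle artifacts, non-stationarity over a session, and the
target-to-target-interval modulation of the late positivity. Passing
tests therefore demonstrate the estimator's statistical behavior under
its own assumptions, not robustness to real-EEG pathologies.

## Decoder details and numerical choices

* **Shrinkage covariance.** The analytic Ledoit–Wolf estimate shrinks the
  sample covariance (denominator N) toward ν·I with ν the mean diagonal
  entry — the standard target in the BCI literature, which the source of
  the shrinkage formula leaves open. The intensity is the usual ratio of
  the dispersion statistic to the distance from the target, clipped to
  [0, 1]. One degenerate case is handled explicitly: with two centered
  observations the dispersion statistic is identically zero while the
  sample covariance is rank-deficient; the estimator then shrinks fully
  to ν·I so that the result stays positive-definite.
* **Projection.** $w = \Sigma^{-1}(\mu_+ - \mu_-)$ is computed by a
  Cholesky solve, never by explicit inversion; the pseudoinverse of $\Pi$
  by a QR least-squares factorization, never via the normal equations. A
  mixing matrix whose smallest singular value is below $10^{-10}$ of the
  largest is rejected as rank-deficient (non-identifiable classes).
* **Supervised baseline.** Class-wise means with the pooled within-class
  shrinkage covariance, classes weighted by their epoch counts (an
  unweighted average of per-class estimates is available behind
  `pooling = "unweighted"`); the LLP decoder uses the global,
  class-ignorant covariance exactly as the online protocol prescribes.
* **Symbol selection.** Scores are summed per selectable symbol; blanks
  are excluded; ties break toward the lowest grid index so decisions are
  deterministic. Because every selectable symbol is highlighted equally
  often per trial, score offsets cancel and no bias term is needed.
* **AUC.** Rank-based Mann–Whitney statistic, ties counting one half.
* **Online protocol.** After each trial the LLP model is retrained on all
  epochs observed so far, including the current trial (a flag excludes
  it), and the current symbol is selected with that model; the model is
  reset between sentences. Post-hoc re-analysis re-decodes every trial of
  a finished sentence with the final model.

## Evaluation procedures

`learning_curves()` reproduces the mixing-matrix comparison: a labelled
epoch pool in chronological order is truncated to each training size,
epochs are randomly assigned to groups realizing each candidate mixing
(group sizes are rebalanced between the extreme groups so the pool's
class ratio is achievable; the pool ratio must lie within the span of the
mixing's target ratios), and the binary AUC is measured by 5-fold
chronological cross-validation — contiguous folds, no shuffling. The
unsupervised LLP model trains on all epochs of the prefix (the held-out
fold included, since it never sees labels); the supervised baseline
trains on the remaining four folds only.

`homogeneity_bootstrap()` implements the leave-one-out distance test of
the homogeneity assumption: for every epoch of one class in group 1, the
squared L2 distance to the leave-one-out class average of group 1 is
paired with the distance to the class average of group 2, and a two-sided
paired t-test (a two-sample flavor is available) asks whether the
distance populations differ. The paired flavor is the default because
each epoch yields both distances. Distances are intended to be computed
on the preprocessed 100 Hz epochs over the 0–700 ms window on all
channels (`flatten_epochs()`), not on interval features. The test is
mildly anti-conservative because distances share the estimated means;
simulation at 500 epochs per class and group puts the type-I error within
two points of the nominal 5 % level.

## Known limitations

* The IID and homogeneity assumptions are design goals of the paradigm,
  not guarantees; session non-stationarity violates IID in real use, and
  the package offers no adaptive forgetting.
* The EM-based unsupervised comparison decoder is out of scope; any
  object honoring the `score_epochs()` contract can be slotted into the
  evaluation functions in its place.
* Feature extraction assumes integer decimation factors and channel-name
  bookkeeping; vendor EEG formats are not parsed — recordings enter
  through the package's plain binary-plus-JSON container or are
  synthesized.
* The sequence generator enforces the double-flash rule and count
  invariants but not the spatial-adjacency heuristic of the original
  sequence-optimization literature, whose exact criterion is not public.
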