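---
title: "How much EEG is enough? Learning curves and knee points for mTRF encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much EEG is enough? Learning curves and knee points for mTRF encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A forward (encoding) model predicts the EEG at electrode $n$ and time $t$
from time-lagged stimulus features:

$$\mathrm{EEG}(t, n) = \sum_f \sum_\tau w(f, \tau, n)\, s(f, t - \tau) + \varepsilon(t, n),$$

where $s(f, t)$ is the value of stimulus feature $f$ (acoustic envelope,
pitch, or one of 14 binary phonological onset rows) at time $t$, and
$w(f, \tau, n)$ is the multivariate temporal receptive field (mTRF). Delays
$\tau$ run from 0 to 600 ms on the EEG sampling grid; at 128 Hz that is
$\lfloor 0.6 \cdot 128 \rfloor + 1 = 77$ delays per feature. The weights are
estimated per channel by ridge regression,
$\hat w = (X^\top X + \alpha I)^{-1} X^\top y$, where $X$ is the lagged
design matrix. Designs are built *per trial*, with zero stimulus history
before each trial onset, and the per-trial normal equations are summed — so
no information leaks across trial boundaries and refitting on any subset of
trials is cheap.

The ridge penalty $\alpha$ is selected once, on the full training set, by
contiguous-fold cross-validation over 15 log-spaced candidates between
$10^2$ and $10^8$ (`defaultAlphaGrid()`), and the same penalty is reused for
every training-subset fit. Validation correlations are averaged over
channels first, then over folds; ties are broken toward the stronger
penalty. Selecting $\alpha$ anew at every subset size would confound the
learning curve with regularization-path changes.

## The sufficiency question

The quantity of interest is the *learning curve* $f(x)$: test-set prediction
correlation (Pearson $r$ per channel, averaged over channels) as a function
of the training-set size $x$ in trials. The protocol is:

1. Hold out a fixed test set. With a repeated-presentation design the
   neural responses of the repeats are averaged into one test response; with
   a continuous 80/20 split the final fifth of the chunks is the test set.
   The test set never changes with $x$.
2. Starting at $x = 10$ trials and growing by 1 (defaults), draw 10
   bootstrap training subsets per size, refit, and score each one.
   Each bootstrap replicate is a seeded random permutation of the training
   pool; the subset at size $x$ is its first $x$ elements. Training sets
   therefore grow incrementally *within* a replicate (by one random trial at
   a time, without replacement) and vary randomly *across* replicates. A
   with-replacement mode is available behind a flag.
3. The knee of the mean curve is the size at which the curvature magnitude

   $$K_f(x) = \frac{f''(x)}{\left(1 + f'(x)^2\right)^{3/2}}$$

   is maximal: beyond it, additional data buy little additional
   correlation.

### Numerical choices in the knee detector

Two choices here are substantive and worth stating plainly.

**Axis normalization.** Curvature is not scale-invariant. On raw
(trials, correlation) axes a saturating curve $c(1 - e^{-x/\tau})$ has its
$|K|$ maximum at the left end of the grid whenever $c/\tau < 1/\sqrt 2$ —
and since correlations are bounded by 1 while sizes run into the hundreds,
that condition essentially always holds, which would put every "knee" at the
smallest size tested. Knee-detection methods for performance curves
therefore map the curve to the unit square first, and `kneePoint()` does the
same: both axes are normalized to $[0,1]$, curvature is computed there, and
the knee is reported in original units.

**Derivative estimation.** Second differences amplify noise by
$\sim 2\sigma / (w h^2)$ for grid step $h$ and presmoothing width $w$; with
bootstrap scatter of a few percent and a 100-point grid this swamps the true
curvature. `kneePoint()` therefore estimates $f'$ and $f''$ from a cubic
smoothing spline fitted to the normalized curve. The spline's smoothness
adapts to the measured noise: the replicate noise level is estimated from
the median absolute second difference (a quantity that is near zero for any
smooth curve but $\approx \sqrt6 \sigma$ under point noise). When the curve
is effectively noiseless the smoothness is chosen by generalized
cross-validation, so analytic test curves are followed exactly; when noise
is detected the curve is first presmoothed with a centered moving average
(`smoothWindow`, default 5 points) and fitted with a conservative spline
(`noisyDf = 7` equivalent degrees of freedom). With these defaults, planted
plateaus at $\tau = 5, 15, 40$ grid units keep their rank order in at least
18 of 20 noisy replications, while the detected knee still matches a dense
finite-difference curvature oracle to within one grid step on noiseless
quadratic, saturating-exponential, and logistic curves.

**Validity.** A knee is reported as invalid — never silently imputed — when
the curve does not rise, when the curvature is flat (a straight line), or
when the argmax falls within `boundaryMargin` (default 5%) of either end of
the size grid. This operationalizes the situation where no knee can be
computed for a subject; `grandAverageKnee()` averages valid knees and counts
the rest.

### Weight stability

A plateauing score does not by itself show that the receptive field
*structure* has stopped changing. `weightStability()` correlates the
flattened weight arrays of models fitted at consecutive sizes (along the
designated first bootstrap replicate, whose subsets are nested). On
well-behaved data the adjacent correlation rises toward 1; the
stabilization size is the first size after which it stays above a threshold
(default 0.9, reported alongside, never instead of, the full curve).

## The synthetic-data generator

Every stage is testable against ground truth because the package generates
its own data:

* **Receptive fields** (`makeGroundTruthTrf()`): gamma-shaped temporal
  kernels per feature — smooth, causal, single-peaked, confined to
  0–600 ms — parameterized by peak latency, width, amplitude and sign.
  Default latencies are drawn from 60–350 ms with 30–70 ms widths, the
  range where auditory TRF components live. Channels receive scaled copies
  under a smooth sinusoidal gain across channel index: enough channel
  diversity to make per-channel statistics meaningful without modeling
  electrode geometry.
* **Stimuli** (`simulateStimulus()`): a nonnegative low-pass envelope
  (rectified filtered noise), a piecewise voiced/unvoiced pitch track
  (110–220 Hz base, slow drift, zeros in unvoiced spans), and 14 binary
  phonological onset rows driven by a random phoneme sequence (interphoneme
  intervals 50–150 ms) mapped through the shipped ARPAbet table. Trial
  durations are uniform on $[0.75, 1.25] \times$ the 2 s mean, mimicking
  sentence-length variation.
* **EEG** (`simulateEeg()`): the causal convolution of features with the
  ground-truth TRF plus noise. The noise (pink by default, white available)
  is rescaled so the realized per-channel SNR matches the request *exactly*;
  `snrDb = Inf` returns the convolution bit-for-bit, which is what the
  convolution-oracle tests rely on. No SNR default is asserted as
  "realistic" — real-EEG SNR depends on equipment and subject, so it is an
  explicit parameter.
* **Designs** (`assembleTrialSet()`): the repeated-test layout (e.g. 10
  test stimuli presented 10 times each, averaged at scoring time) and the
  continuous 80/20 split.

What the generator does *not* emulate: eye blinks, electrode drift,
movement artifacts, inter-subject variability, adaptation or attention
effects, and the autocorrelation structure of real speech features. Passing
tests on synthetic data therefore demonstrate correctness of the estimation
and knee machinery, not that any particular real dataset will plateau at a
particular size.

## Feature computation and preprocessing for real inputs

For real recordings the package provides the standard conditioning chain:
acoustic envelope as the magnitude of the analytic (Hilbert) signal
low-passed with a zero-phase 3rd-order Butterworth at 25 Hz; pitch ingested
from two-column $f_0$ tracks with sample-and-hold interpolation (unvoiced
spans stay zero); phoneme annotations (Praat TextGrid or 3-column TSV)
coded as binary *onset* impulses through an explicit ARPAbet-to-14-feature
table shipped as CSV (a documented convention, overridable from file; a
sustained-coding mode exists behind a flag). EEG preprocessing notches the
line frequency at the native rate (so the line component cannot alias),
band-passes 1–15 Hz with a Hamming-window zero-phase FIR (53 dB stopband
per pass, doubled by forward–backward application; order set by the
Hamming design rule for a transition of min(low, 2) Hz), then resamples by
zero-phase polyphase rational resampling. Audio-to-EEG alignment uses a
matched filter: normalized cross-correlation with the presented stimulus,
accepted only above a score threshold.

Continuous features can be z-scored over the training set before fitting
(flag-controlled); binary onset rows are left untouched.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale, chosen so the full suite
completes in minutes while still exercising every code path at realistic
dimensionality: the main synthetic study uses 16 features $\times$ 77
delays $\times$ 32 channels with 150 two-second trials at 128 Hz
(noiseless, so parameter recovery has a sharp truth to hit), learning
curves over a 140-trial pool in steps of 10, and a separate 60-trial pool
at unit steps for protocol checks. Analytic knee checks use 41–100-point
grids.

## Known limitations

* The knee is a property of the *mean* bootstrap curve; per-replicate knees
  are not computed.
* Curvature on fewer than ~7 sizes is refused outright; short curves cannot
  support second derivatives.
* `selectAlpha()` partitions trials into contiguous folds; with strong
  slow drifts in real data a randomized fold assignment might be preferred.
* The EDF/BDF import path is not included; EEG enters either from the
  package's own plain-text container or programmatically as matrices.
* Inferential statistics on knee differences (mixed models, rank tests)
  are deliberately out of scope; the package reports estimates and
  uncertainties, not p-values.
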