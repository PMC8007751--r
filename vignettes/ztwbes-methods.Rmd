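---
title: "Epoch selection and adaptive electrode relevance for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch selection and adaptive electrode relevance for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ztwbes)
```

## The problem and the model

Emotion recognition from scalp EEG usually extracts features from a
fixed electrode set and from the whole trial. Both choices ignore two
robust observations: the electrodes that carry emotion-related activity
differ between people (and between emotions and frequency bands), and
the emotional excitation is not uniform over a trial — there are
instants, here called *epochs*, where the deviation from the person's
neutral baseline is maximal. This package implements a subject-adaptive
pipeline built on those two observations:

1. **Epoch selection (ZTWBES).** Every trial is cut into frames of
   length $\kappa$ seconds shifted by $Shift$ seconds
   ($n = \lfloor (T - \kappa)/Shift \rfloor + 1$ frames). Each frame is
   multiplied by the zero-time window
   $$\psi[n] = \frac{1}{4\sin^2(\pi n / 2N)}, \qquad \psi[0] = 0,$$
   and transformed with the *numerator group delay* (NGD) spectrum
   $$NGD[k] = \Re(X[k])\,\Re(Y[k]) + \Im(X[k])\,\Im(Y[k]),$$
   where $X$ is the DFT of the frame and $Y$ the DFT of the
   time-weighted frame $n\,x[n]$. The NGD keeps the formant (peak)
   structure of the group-delay function while avoiding its division by
   near-zero magnitudes. Per electrode, the frame whose band-weighted
   energy $\sum_f \sum_k k\,|S[k]|$ deviates most (in absolute relative
   terms) from the electrode's neutral-baseline energy is *tagged*;
   tags are reduced per electrode by plurality over the subject's
   trials, and the subject's epoch location is elected by majority over
   electrodes. Electrodes that agree with the winner form the *elite*
   set.

2. **Relevant electrodes.** For every emotion $\eta$ and band $f$, an
   elite electrode is *relevant* if the probability
   $\rho = \|\gamma\| / \|\varphi(s,\eta)\|$ of showing an absolute
   baseline-relative energy change $|\Delta| \ge \beta$ reaches
   $\alpha$, where $\Delta = (E - E_{ref})/E_{ref}$ and $E_{ref}$ is
   the mean energy of the subject's neutral trials on the same segment.
   Both thresholds default to 0.5 and both comparisons are inclusive
   ($\ge$); strict comparisons are available (`strict = TRUE`) because
   the two conventions appear side by side in the method's sources.

3. **Classification.** Features are the signed $\Delta$ values at the
   relevant (band, electrode) pairs. Eight one-vs-all classifiers (one
   per non-neutral emotion) vote target/outlier and the votes are fused
   by three rules: all outlier → *neutral*; a minority of targets → the
   target-voting classifier with the highest training accuracy; a
   majority of targets → *reject* (an observable, countable outcome).
   Classifiers are either quadratic discriminants (QDC) or small
   3-3-3 tanh networks trained by Levenberg–Marquardt; an
   "all-together" network with one output per emotion (argmax decision)
   is the third scheme.

The three experiment variants differ only in the spectral stage:
`dft` and `ngd` compute whole-trial band energies over the full
montage (no epoch stage); `proposed` runs ZTWBES and computes energies
on the epoch frame of the elite electrodes.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| $\kappa$, $Shift$ | s | 15, 15 | frame length/shift; the defaults partition a 60-s trial into 4 frames |
| $\alpha$ | – | 0.5 | minimum fraction of an emotion's trials with a significant change |
| $\beta$ | – | 0.5 | minimum absolute relative energy change per trial |
| bands | Hz | θ 4–7, α 8–12, β 12–36, γ 36–42 | analysis rhythms; fs must exceed 84 Hz |
| QDC shrink | – | auto | covariance shrinkage toward $(\mathrm{tr}\,\Sigma/d)\,I$; see below |
| LM damping / factor / iterations | – | 3 / 10 / 5 | Levenberg–Marquardt configuration; error target $10^{-10}$ |
| network init | – | U[−0.5, 0.5] | weight/bias initialization of the 3-3-3 tanh nets |

## Design choices in detail

**Energy definition.** Band energy is the bin-index-weighted sum
$\sum_k k\,|S[k]|$ over the band's bins
(`k = round(f·N/fs)`, inclusive edges). The leading $k$ weight is kept
exactly as the method defines it. The magnitude is used because NGD
values can be negative and an energy should stay non-negative;
`mode = "real"` exposes the raw-real alternative.

**Band-limiting.** Per-band energies are computed on band-pass-filtered
signals (zero-phase forward–backward 4th-order Butterworth, matching
the band-filtering stage of the pipeline) with bin-range summation;
`bandlimit = FALSE` reads all bands off one broadband spectrum. The
filter itself is a compiled matrix-vectorised implementation with
odd-reflection edge padding; its per-pass output matches
`signal::filter` exactly, and coefficients come from
`signal::butter`.

**Baselines.** The ZTWBES reference (per electrode) is the mean
multiband NGD energy of the *whole* neutral trials, no window — the
baseline is a trial-level statistic, while the frame energies it is
compared against are ZTW-windowed (a `windowedBaseline` switch enables
the fully windowed alternative for sensitivity analysis). A zero or
negative reference is a hard error ("degenerate baseline") rather than
a silent NaN.

**Windowing of the relevance/feature energies.** The zero-time window
weights sample $n$ by $\sim 1/n^2$, so a windowed frame's energy is
effectively determined by the first few samples — by design: that is
what makes the spectrum "instantaneous" and the per-frame *argmax*
votes sharp. The same property makes windowed energies a poor basis
for *threshold* statistics: their trial-to-trial relative fluctuation
is of order ±50%, so non-planted electrodes cross $\beta = 0.5$ in a
large fraction of trials and the precision of the recovered sets
degrades substantially relative to the unwindowed frame (the test
suite demonstrates the gap on a simulated subject, and the recovery
study reaches precision ≈ recall ≈ 1 with the default). The relevance
and feature stages therefore use the plain (unwindowed) spectrum of
the epoch frame by default — consistent with the relative-change
equations, which are defined on spectra without any window — and
`ztw = TRUE` restores the fully windowed reading.

**QDC regularization.** A covariance that fails its Cholesky
factorization is repaired with $\varepsilon I$,
$\varepsilon = 10^{-6}\,\mathrm{tr}(\Sigma)/d$ (escalated tenfold as
needed). That floor is the right tool for *numerically* singular fits,
but in the pipeline's small-sample regime (about 9 training trials per
target class against feature dimensions of 20–80) the target-class
covariance is *structurally* rank-deficient, and with a bare
$\varepsilon$ floor the discriminant assigns any test point an
orthogonal-residual Mahalanobis cost of order $(d - r)/10^{-6}$ —
independent of the noise scale — so every trial is rejected by every
one-vs-all member. `qdcFit` therefore also offers shrinkage,
$\Sigma \leftarrow (1 - s)\Sigma + s\,(\mathrm{tr}\,\Sigma/d)I$, and
the pipeline picks $s = d/(d + n_k)$ automatically whenever a class
has $n_k \le d$ samples (0 otherwise, recovering the plain QDC).

**Vote tie-breaks.** All frame-location ties break to the smallest
index (`which.max`/explicit minimum), both in per-trial tagging and in
the plurality/majority votes. A majority vote with no strict >50%
winner falls back to plurality with a warning and a recorded margin
≤ 0.5, keeping the pipeline total. Accuracy ties between target-voting
classifiers break to the first emotion in the canonical order (happy,
pleased, relaxed, excited, calm, distressed, miserable, depressed).

**VAD → emotion grid.** The 9-label mapping from valence/arousal
ratings is not printed by the method's sources; the default used here
is a circumplex-style placement over a 3×3 grid with cutpoints at the
thirds of [1, 9] (3.667, 6.333): low arousal → depressed/calm/relaxed,
mid → miserable/neutral/pleased, high → distressed/excited/happy, with
valence increasing left to right. It is a documented, overridable
configuration (`grid`, `cutpoints` arguments), and "pleasant" is
accepted as an alias of "pleased".

**Cross-validation without leakage.** Folds are stratified by emotion;
when an emotion has fewer trials than folds the run falls back to
leave-one-out with a warning. Within each fold the neutral baselines,
the epoch location, the elite set, the relevance map, the band
references and the classifiers are all re-derived from the training
folds only. Per-trial energies are precomputed once for the whole
store: they involve no cross-trial statistics, so sharing them across
folds leaks nothing.

**Network modes.** With every delay factor at zero the recurrent
formulation collapses to a static feedforward network; that is what is
implemented (three tanh layers of three units, linear output). The
one-vs-all output is thresholded at 0.9, the midpoint of the raw
output range [−0.1, 1.9]; the all-together scheme uses 9 outputs
(neutral included) and argmax. How the raw one-vs-all output is
binarised is not fully specified by the sources; the midpoint is a
documented choice. Note that with the configured 5 LM iterations the
networks are deliberately lightly trained; `nnIter` raises the budget.

## The synthetic generator

`simulateStore()` emulates exactly the statistical structure the
method assumes, with ground truth for every latent quantity:

* each trial is a sum of four band-limited sinusoids (one per rhythm,
  random phase, frequency jittered by a quarter band-width around the
  band centre) plus white noise (1/f pink noise optional);
* per-band amplitudes default to (θ, α, β, γ) = (1.0, 0.9, 0.9, 0.7) —
  a mild high-frequency roll-off that keeps every rhythm detectable;
* `snr` (default 3) is the oscillation-RMS to noise-SD ratio;
* for emotional trials, the amplitude of band $f$ on the planted
  relevant channels $R(s, \eta, f)$ is multiplied by `effectSize`
  (default 2; values below 1 model decreases) *only inside the
  subject's planted epoch frame* $k^\ast$;
* $k^\ast$ and every $R(s,\eta,f)$ are redrawn per subject
  (`relevantFraction` of the montage per emotion and band, default
  0.25 — matching the sparsity of a handful of relevant channels out
  of 32 that per-band scalp relevance tables typically show);
* generation is deterministic given the seed, with per-subject
  substreams so subjects can be generated independently.

What it deliberately does **not** model: volume conduction and
inter-channel correlation, non-stationary rhythms, 1/f background by
default, artifacts (ocular, muscular), rating noise, or any
biophysical forward model. Passing the recovery and accuracy suites
therefore demonstrates the *algorithmic* correctness and the
statistical behaviour of the pipeline under its own assumptions — not
performance on real recordings, which additionally depends on all of
the above.

On this synthetic family the whole-trial NGD baseline can trail the
whole-trial DFT baseline: the time-weighting $n\,x[n]$ makes the NGD
energy of a trial depend on *where* the modulated frame sits (a late
epoch is amplified, an early one discounted), while the DFT magnitude
is position-invariant. The epoch-based pipeline sidesteps this by
analysing the epoch frame directly, and dominates both baselines.

## Numerical notes and problem sizes

* Spectra are validated against $O(N^2)$ brute-force sums to
  $10^{-9}$; the windowed-frame DFT bin-sum identity (forced by
  $\psi[0] = 0$) holds to $10^{-8}$ even at 15-s frames (1920
  samples).
* Seconds→samples conversions use `round()` and half-open sample
  windows; frames are indexed from 1.
* The LM optimizer accepts only strictly decreasing steps, divides the
  damping by 10 on acceptance, multiplies by 10 on rejection (bounded
  rescues), and floors the normal-equation diagonal at $10^{-12}$.
* The test and validation suites use 8-s/60-s trials at 128 Hz with
  8–32 channels; the recovery studies use 50 subjects at the full
  60 s × 32-channel geometry, and the variant comparison 10 paired
  seeds — sizes chosen to give stable rates while keeping a full run
  in the tens of minutes on one core.

## Limitations

* No artifact handling is provided; inputs are assumed pre-cleaned.
* Epoch localization is frame-level; no sub-frame refinement.
* No multiple-testing correction is applied to the relevance
  probabilities (the method applies none).
* Cross-subject (subject-independent) transfer is out of scope; every
  model is per-subject.
* Real-data accuracy claims are out of scope: the bundled DEAP-layout
  adapter (`deapToStore`) ingests the public dataset's per-subject
  arrays, but no attempt is made to reproduce published accuracy
  tables, which would require the access-restricted recordings.
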