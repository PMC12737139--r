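---
title: "Adaptive layer-dependent threshold wavelet denoising: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive layer-dependent threshold wavelet denoising: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldtf)
```

## The problem and the model

Electrocardiograms and fiber-optic cardiorespiratory recordings are
quasi-periodic signals contaminated by baseline wander (slow drift),
electrode-motion transients, broadband muscle artifact and instrument noise.
Clean references are almost never available in ambulatory settings, which
rules out supervised tuning of a denoiser. This package exploits the one
property that separates these signals from their noise: *the signal is
periodic, the noise is not*.

The pipeline is classical wavelet shrinkage with an adaptive twist. The
noisy signal $y_{in}(n)$ is decomposed with the biorthogonal 6.8 discrete
wavelet transform into detail bands $D_1,\dots,D_J$ (finest first) and an
approximation $A_J$. Each detail coefficient $\omega$ of layer $j$ is shrunk
with the tanh threshold function

$$\hat\omega \;=\; \mathrm{sgn}(\omega)\,\frac{|\omega|}{2}\,
\bigl[\tanh\!\bigl(\alpha_j(|\omega| - \lambda_j)\bigr) + 1\bigr],$$

the approximation passes through untouched, and the inverse transform gives
$y_{out}(n)$. The bracket lies in $[0,2]$, so the rule always shrinks; at
$|\omega| = \lambda_j$ the output is exactly $\omega/2$ for every
$\alpha_j$; as $\alpha_j \to \infty$ the rule converges to hard
thresholding, while moderate $\alpha_j$ gives a smooth soft-like transition
that avoids the pseudo-Gibbs ringing hard thresholding causes. The tuning
factor therefore interpolates the soft/hard trade-off *per layer*: fine
layers (broadband noise, small coefficients) tend to benefit from smooth
shrinkage, coarse layers (signal contour, large coefficients) from leaving
survivors untouched.

### The reference-free objective

Quality is measured without a reference through the normalized
autocorrelation (with the per-lag tail normalization)

$$\mathrm{NACF}(k) = \frac{\sum_{n=0}^{N-k-1} y(n)y(n+k)}
{\sqrt{\sum_{n=0}^{N-1} y^2(n)}\sqrt{\sum_{n=0}^{N-k-1} y^2(n+k)}},$$

whose largest value over lags in $[\,\mathrm{round}(T_{min} f_s),\,
\lfloor N/2\rfloor\,]$ — the *non-zero periodic peak* (NZOPP) — is large for
a clean quasi-periodic signal and small for noise. $T_{min}$ defaults to
0.25 s, a 240 bpm ceiling that excludes the zero-lag main lobe while
admitting any physiological beat period. Note two consequences of the tail
normalization: the profile is not the textbook biased autocorrelation, and
the value at the fundamental period is capped near $\sqrt{1 - k/N}$, so
objective values are only comparable across reconstructions of the same
length (which is how the pipeline uses them).

### The tuning-factor search

Each $\alpha_j$ maximizes the NZOPP of the full reconstruction via a
derivative-free five-point bisection: evaluate the objective at the interval
ends, midpoint and quarter points; if the best value sits at `start`/`left`
keep the left half, at `right`/`end` keep the right half, at `mid` keep the
central half `[left, right]`; stop when the interval is narrower than
$10^{-6}$ and return its midpoint. For a unimodal objective the maximizer
always lies between the neighbours of the best evaluated point, so each
contraction retains it; each iteration halves the interval, giving at most
$\lceil \log_2(\mathrm{range}/10^{-6})\rceil$ iterations. We note one
superficially plausible variant that is *not* used: assigning the best-at-`mid`
case to the left branch makes the bracket lossy (an argmax just right of the
midpoint gets discarded, with errors up to an eighth of the current width),
which measurably breaks the search's accuracy guarantee. Objective values
are cached by abscissa; interval endpoints recur across iterations, so a
full search costs roughly two fresh reconstructions per iteration.

Layers are tuned finest to coarsest, one layer at a time with the others
held at their current rules — a coordinate-wise sweep that keeps each search
one-dimensional. An optional `passes` parameter repeats the sweep until the
objective gains less than $10^{-4}$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `wavelet` | bior6.8 | — | symmetric, near-linear phase: preserves QRS/ST morphology |
| `levels` | 4 (`"auto"` tries 3–5) | — | 4 suits ECG-rate signals; 5 suits slower fiber cardiorespiratory recordings; `auto` keeps the max-NZOPP depth |
| `threshold_method` | `"universal"` | — | $\lambda_j = \hat\sigma_j\sqrt{2\ln n}$, $\hat\sigma_j = \mathrm{median}(|D_j|)/0.6745$ |
| `min_period_s` | 0.25 | s | 240 bpm ceiling for the NZOPP exclusion lag |
| `tolerance` | $10^{-6}$ | (α units) | search precision |
| `passes` | 1 | — | extra coordinate sweeps rarely gain $> 10^{-4}$ |

Two design choices deserve their rationale spelled out, because the
obvious alternatives were implemented first and measurably failed:

**The α search interval is $[0, 10/\hat\sigma_j]$, not
$[0, \max|D_j|]$.** The tuning factor has units of inverse amplitude, so an
amplitude-valued ceiling makes the algorithm's behavior depend on the units
of the input. For peak-normalized signals, $\max|D_j|$ is well below 1 and
the tanh argument never leaves its linear region: every layer collapses to
the $\omega/2$ halving rule, the function can reach neither its soft- nor
hard-like regimes, and measured $\Delta$SNR on white-noise ECG drops by
about 2.5 dB. The ceiling $10/\hat\sigma_j$ is scale-invariant (rescaling
the signal by $c$ rescales $\hat\sigma_j$ by $c$ and the chosen $\alpha$ by
$1/c$, leaving the denoiser equivariant) and large enough that the tanh
saturates one noise standard deviation past the threshold — i.e. hard
thresholding is effectively inside the search space. The initial value
before tuning is the scale-matched $1/\hat\sigma_j$.

**The threshold is *not* tuned by the periodicity objective by default.**
An `"nzopp"` threshold mode exists, mirroring the α search with
$\lambda_j \in [0, \max|D_j|]$, but the NZOPP objective is monotone
increasing in $\lambda$: removing detail energy always smooths the signal
and raises its autocorrelation peak, so the search runs to the upper bound
and over-smooths (measured $\Delta$SNR drops for every noise kind, by 3.6 dB
for white noise). Periodicity can arbitrate the *shape* of the shrinkage
(α), but not its *amount* (λ), which needs an independent noise-scale
estimate — hence the universal threshold default.

## What the synthetic generators emulate — and what they don't

`synth_ecg()` builds each beat from five Gaussian bumps (P, Q, R, S, T; R
dominant, amplitudes and widths in one constants table) at RR intervals with
seeded multiplicative jitter, peak-normalized. `synth_noise()` produces the
standard ECG noise taxonomy: baseline wander (2–3 sub-0.5 Hz sinusoids plus
a $1/f^2$ random walk), electrode motion (sparse heavy-tailed steps and
spikes through an exponential decay kernel), muscle artifact (white noise
band-passed to 20–100 Hz), their equal-power mixture, and white Gaussian
noise — all zero-mean, unit-power, pure functions of (parameters, seed).
`mix_at_snr()` scales noise to hit a target input SNR exactly;
the mixing level is an explicit parameter throughout because the real
studies this emulates never report theirs.

These are morphological stand-ins, not physiological models: no heart-rate
variability structure, no PQRST shape variation across beats or leads, no
recording-chain coloration, and the noise records they imitate are real
recordings with broadband content the generators only partially reproduce.
Passing the efficacy study here demonstrates the machinery and its
reference-free adaptation; it does not certify clinical performance on real
records.

One structural consequence is worth stating plainly: synthetic baseline
wander is $>95\%$ sub-hertz by construction, and at 360 Hz with $J = 4$ the
detail bands start near 11 Hz — so nearly all of the wander sits in the
approximation band, which this method (by design) passes through. The
removable fraction of BW power is then smaller than the unavoidable
shrinkage distortion of nearly clean detail bands, and $\Delta$SNR for the
pure-BW condition sits slightly below zero (about $-0.4$ dB) no matter the
tuning. Removing sub-hertz wander requires either much deeper
decompositions or a detrending front-end, both outside this method's scope.
Relatedly, with the signal-to-noise-and-distortion ratio computed from the
printed power definitions ($P_d$ the removed-signal power
$\overline{(y_{out}-y_{in})^2}$), successful denoising leaves
$\Delta$SINAD near or slightly below zero even when $\Delta$SNR gains
7–10 dB; the reported values follow the printed formula.

## Numerical choices

* **Wavelet machinery.** No wavelet package is part of the dependency set,
  so the bior6.8 analysis/synthesis filter bank (18 published taps) and the
  symmetric-extension transform are implemented in `R/wavelet.R`, following
  the indexing conventions of the PyWavelets reference implementation, and
  validated against it during development to $<10^{-10}$ on coefficients
  and round-trips across lengths 10–4096 and depths 1–5 (a frozen reference
  decomposition is kept in the test suite). Per-level input lengths are
  recorded so reconstruction is exact for odd lengths.
* **Depth feasibility.** `dwt_decompose()` requires each level's input to
  be at least the filter length (deeper bands are all boundary);
  `aldtf_denoise()` is stricter — $n \ge 18\cdot 2^J$ — since tuning needs
  bands that are not boundary-dominated. `dwt_max_levels()` reports the
  conventional $\lfloor \log_2(n/(L-1))\rfloor$ recommendation.
* **NACF.** Lagged products via FFT ($O(N\log N)$), tail energies via a
  reversed cumulative sum; equality with direct summation to $10^{-10}$ is
  asserted in the tests. Lag 0 is set to 1 exactly.
* **Ties.** The NZOPP argmax takes the smallest lag; the search takes the
  earliest of the five points and the earliest branch.
* **Degenerate inputs.** All-zero signals are rejected (autocorrelation
  undefined); all-zero detail bands are skipped by the tuner; a perfect
  reconstruction yields an `Inf` SNR sentinel rather than an error so batch
  reports never abort.
* **Determinism.** The pipeline contains no randomness; generators use an
  explicit seed and restore the global RNG state.

## Problem sizes used in the shipped studies

The efficacy study in the test suite runs 20 seeds per noise kind
(WHITE/BW/MA/MIX) of 10 s, 360 Hz ECG at 5 dB input SNR with default
configuration; the acceptance script repeats the same study at 5 seeds per
kind plus deterministic round-trip and mixing checks. A single default
denoise of a 3600-sample signal costs roughly 170 objective evaluations
(about 2 s); these sizes keep a full study in the minutes range while
leaving the stochastic medians stable.

## Known limitations

* Sub-hertz baseline wander is structurally out of reach (see above).
* The coordinate-wise sweep is greedy: layers are not jointly optimal, and
  a single pass is the default.
* The NZOPP objective assumes one dominant periodicity; for signals with
  competing periodicities (e.g. cardiorespiratory mixtures) it locks onto
  the strongest one, and `min_period_s` can only exclude *shorter* periods.
* Only the bior6.8 filter bank ships; the transform code is generic, so
  adding filter banks is a table entry, but none other is exposed.
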