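---
title: "Extracting conformational landscapes from single-molecule FRET trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting conformational landscapes from single-molecule FRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfret)
```

## The problem

A membrane receptor labeled with a donor and an acceptor dye reports its
conformation through FRET: when the labeled helices approach each other,
energy transfer rises and the acceptor brightens at the donor's expense. A
TIRF microscope records both emission channels for hundreds of single
molecules at a fixed frame interval (0.1 s here) until the dyes
photobleach. The analysis task is to turn those noisy two-channel traces
into a conformational landscape: how many discrete states the receptor
visits, where each state sits on the apparent-FRET axis, how the states
are connected, how long the molecule dwells in each, and how ligands shift
the populations.

`smfret` implements that pipeline end to end, together with a synthetic
trace generator that serves as ground truth for validating every stage.
The raw recordings behind published landscapes of this kind are usually
not deposited, so the package treats the generator as a first-class
module: all quantitative claims about the pipeline are statements about
its ability to recover known generative parameters.

## The generative model

A scenario (`scenario_spec()`) is the generative twin of the model used
for inference:

* a discrete Markov chain over K conformational states, advanced once per
  frame by a row-stochastic transition matrix. Dwell times are therefore
  geometric at frame resolution — the discrete-time analogue of the
  exponential dwells expected from barrier crossing;
* a per-frame FRET coordinate `e_t = mu[state_t] + N(0, sigma^2)` with a
  single shared emission SD `sigma` (default 0.08), matching the
  shared-variance Gaussian emission model fitted downstream;
* ideal intensities `donor = I (1 - e_t)`, `acceptor = I e_t` with a
  constant total photon budget `I`, which makes the channels exactly
  anti-correlated and their sum conserved;
* instrument effects (`noise_spec()`): additive Gaussian camera noise per
  channel, donor bleed-through into the acceptor channel, constant
  backgrounds, and single-frame photobleaching — either acceptor-only (the
  donor then recovers the full photon budget) or simultaneous loss of both
  channels.

Placing the emission noise on the FRET coordinate rather than only on the
channels is a deliberate choice: it makes the generated apparent-FRET
trajectories follow exactly the shared-variance hidden Markov model the
fitter assumes, so parameter-recovery tests measure the estimator, not a
model mismatch. Channel noise (default SD 20 at `I = 1000`) adds the
mild ratio distortion real cameras produce. What the generator does *not*
emulate: triplet blinking, spectral crosstalk beyond the single
bleed-through term, gamma-factor asymmetries, Poisson shot noise, or
intensity variation across the field of view. Passing recovery tests on
synthetic data therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artifact of real
recordings.

The photobleach frame is drawn from the per-frame hazards truncated to
leave at least 25 pre-bleach and 10 post-bleach frames. Real datasets are
curated the same way — molecules that bleach immediately or never are
discarded — and the truncation leaves the bleach-class proportions and
all dwell statistics untouched.

### Study-condition presets

Six presets (`scenario_presets()`) encode the experimental conditions of
the CXCR4/ACKR3 study this package models. State means are the reported
values (CXCR4: 0.85/0.59/0.19; ACKR3: 0.85/0.66/0.39/0.11, labeled R, R',
R*', R* from high to low FRET). Reported population data are deltas
(e.g. CXCL12 raises CXCR4 R* by 28 points and ACKR3 R*'+R* by 24 points);
absolute apo occupancies appear only in figures, so the presets fix
documented defaults — apo-CXCR4 at 0.75/0.20/0.05 (inactive-dominant) and
apo-ACKR3 at 0.25 each (the near-uniform landscape that distinguishes the
atypical receptor) — and apply the printed deltas on top.

Transition matrices are reversible nearest-neighbor (birth–death) chains
built by a Metropolis rule with neighbor proposal probability q = 0.03,
which (a) realizes the strictly sequential connectivity reported for both
receptors, (b) yields the required stationary occupancies exactly, and
(c) keeps every diagonal at or above 0.94 so dwells are seconds-scale
(median at least 1 s at 0.1 s frames). The initial state distribution is
the stationary distribution, so finite traces have unbiased occupancy.

## Trace processing

Recorded intensities are corrected as `donor' = donor - bg_D` and
`acceptor' = acceptor - bg_A - alpha * donor'`; no flooring is applied, so
the noise structure survives for the Gaussian emission model. Apparent
FRET is `E_app = I_A / (I_A + I_D)` per frame over the pre-bleach segment,
with frames below a 1e-9 denominator floor dropped and counted, and no
clamping to [0, 1]. Only apparent FRET is used throughout — no gamma or
quantum-yield calibration — matching standard practice when relative
state positions, not absolute distances, are the readout.

### Photobleach detection and screening

Published analyses screen traces manually for single bleach steps and
anti-correlated channels; `smfret` automates the screen with a
transparent, oracle-checkable detector:

* change points are localized by an exhaustive least-squares single-split
  scan (binary segmentation for multiple steps) and qualify as steps when
  the two-sample t statistic reaches 4;
* an acceptor down-step is a *bleach* candidate only if, up to the next
  change point, the acceptor sits near background, the donor carries
  essentially the whole photon budget, and the segment is quiet. These
  conditions separate bleaching from conformational transitions, which
  move the acceptor but conserve the summed intensity and retain the
  FRET jitter;
* a total-intensity down-step to near background is a *simultaneous*
  candidate; acceptor and total events within one frame merge.

A trace is accepted if it shows exactly one bleach event, its pre-bleach
channels have Pearson correlation at most -0.2, and at least 20 pre-bleach
frames remain. On the default presets the acceptance rate exceeds 0.95;
traces given two bleach events (acceptor loss followed by donor loss) are
always rejected.

## Global HMM, idealization, and state-count selection

All screened trajectories of a condition are fit *jointly* by one K-state
hidden Markov model with Gaussian emissions and a single shared variance:
one transition matrix, one set of means, one initial distribution, one
sigma. Baum–Welch accumulates sufficient statistics across molecules;
recursions are scaled per frame (underflow-free) and implemented in C++.
Convergence is declared at a relative log-likelihood change below 1e-6
(at most 1000 iterations); the shared variance is floored at 1e-6 FRET²
and flagged if the floor binds. States are relabeled in decreasing order
of mean after every fit, so state 1 is always the highest-FRET (inactive)
state. Viterbi decoding, with ties broken toward the lower state index,
produces the idealized path used for all downstream summaries.

Because EM only finds local optima, three deterministic starts are
evaluated and the best final log-likelihood wins: pooled quantiles
(levels `(k-0.5)/K`), the K tallest kernel-density modes, and K evenly
spaced points between the 2nd and 98th percentiles. The quantile start
alone can starve a sparsely populated state (a 5% active population
attracts no quantile), and the density start can miss a mode hidden in a
shoulder; the three together recover every preset reliably. Optional
seeded restarts are available via `hmm_config(n_restarts = )`.

The number of states is chosen per receptor across all its conditions.
For each candidate K (default 2–5) and condition, the pooled apparent-FRET
values are fit with a K-component Gaussian mixture (per-component
variances, initialized from the HMM solution) and its BIC
(`p ln n - 2 ln L`, with `p = 3K - 1` and n the pooled frame count,
ignoring temporal autocorrelation) is summed over conditions. Selection
then applies the same two criteria as the original analysis: the summed
BIC must be minimal *and* the fitted peak positions must be consistent
across conditions. Candidates whose cross-condition peak spread exceeds
0.05 FRET units are excluded before taking the BIC minimum (with a
flagged fallback to the raw minimum if none qualify), and ties go to the
smaller K. The consistency criterion matters in practice: a K one above
the truth can shave a few BIC points by splitting a mode, but the split
lands differently in every condition, betraying itself through peak
drift an order of magnitude above the genuine solution's.

## Landscape summaries

* **Populations** — fractional occupancy of each state over all Viterbi
  frames of a condition.
* **Composite histograms** — one Gaussian KDE (bandwidth 0.04, grid of
  512 points on [-0.2, 1.2], wide enough for unclamped values) per state
  over the frames assigned to it, scaled by occupancy so state curves sum
  pointwise to the overall envelope.
* **Transition density plots (TDPs)** — each consecutive label change
  contributes an event at (mean raw E_app of the preceding dwell, mean of
  the following dwell); events are smoothed with a 2-D Gaussian kernel
  (sigma 0.03) on a 128×128 grid and normalized to total probability 1.
  Using dwell-averaged raw FRET rather than fitted state means is what
  keeps distinct underlying levels distinguishable even if they share a
  model state — the property that lets a TDP discriminate a genuine
  on-pathway intermediate (sequential cross peaks) from a mixed-labeling
  artifact, where two label orientations produce four FRET levels but
  only two unordered cross-peak pairs (`mixed_labeling_events()` builds
  the analytic counterexample).
* **Dwell times** — completed dwells only (the first and last run of
  every trace are censored, standard practice since their true length is
  unknown); exponential rates as 1/mean.
* **Condition comparisons** — per-state population differences in
  percentage points (summing to zero), with optional grouped deltas such
  as R*' + R*.

## Numerical and design choices

* Frame indexing is 1-based in R; `bleach_frame` is the first post-bleach
  frame, and the usable segment is `1:(bleach_frame - 1)`. The on-disk
  exchange format (SMT-TSV) uses 0-based frame indices.
* Per-trace seeds derive from the master seed by a fixed integer hash, so
  any molecule can be regenerated in isolation and batches are
  reproducible bit for bit across platforms.
* Degenerate inputs: constant trajectories drive the shared variance to
  its floor and are flagged rather than erroring; empty states produce
  zero curves and empty dwell rows, flagged likewise.
* All serialized outputs (models, paths, selection, populations, TDP
  grids) embed a hash of the canonical run configuration plus the seed.

## Problem sizes and what the validation shows

The packaged validation works at the study's scale: 150 molecules × 300
frames per condition (tens of thousands of pooled frames), for which
state-count selection, state-mean recovery (±0.02), and sequential
connectivity are sharp. Population-shift recovery is a harder target: with
seconds-scale dwells a ~13 s pre-bleach trace contributes roughly one
effective occupancy sample, so the sampling SD of a recovered
population delta at 150 traces is ~3 percentage points. The reproduction
script therefore sizes the shift comparison at 1200 molecules per
condition, bringing the Monte Carlo standard error near 1 point; this is
a power choice, not a change to the generative conditions.

## Limitations

The screen's bleach/transition discrimination assumes corrected traces
(or small bleed-through) and a roughly constant total photon budget;
strongly varying excitation would need the thresholds in
`screen_config()` retuned. BIC with frame-level n overstates the
effective sample size of autocorrelated trajectories, which is why the
peak-consistency criterion shares the selection decision. Dwell-time
analysis stops at exponential fits; no rate-matrix inference or
semi-Markov modeling is attempted, and per-state emission variances are
deliberately out of scope.
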