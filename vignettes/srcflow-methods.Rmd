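---
title: "Measuring continuous visual evoked responses: methods and design notes"
author: "srcflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring continuous visual evoked responses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcflow)
```

# The problem

Conventional event-related potentials require discrete, repeatable stimulus
events. Naturalistic stimuli — a video game, a movie — offer no such events,
but they do offer a continuously varying feature such as the spatial-mean
optic-flow magnitude of the video. The strength of the visual evoked
response can then be measured as the *temporal correlation* between that
feature and the EEG, provided two mismatches are handled: the brain responds
with unknown, distributed latencies, and the response is spread over many
electrodes with unknown topography.

`srcflow` handles both with canonical correlation analysis (CCA). The
stimulus feature $s(t)$ is passed through a causal temporal filter,

$$u(t) = \sum_{\tau=0}^{L-1} h(\tau)\, s(t-\tau),$$

and the $D$-channel EEG $r_i(t)$ through a spatial filter,

$$v(t) = \sum_{i=1}^{D} w_i\, r_i(t),$$

with $(h, w)$ chosen to maximise the Pearson correlation $\rho_{uv}$. CCA
yields a sequence of such pairs $(h_j, w_j)$ with decreasing correlations
$\rho_1 \ge \rho_2 \ge \dots \ge \rho_K$, mutually uncorrelated component
time courses, and the summary measure

$$\mathrm{SRC} = \sum_{j=1}^{K} \rho_j,$$

the total stimulus–response correlation. The temporal filters $h_j(\tau)$
play the role of temporal response functions (the continuous-stimulus
analogue of an ERP time course), and each component's *forward model*
$a_j = C_{rr} w_j / (w_j^\top C_{rr} w_j)$ is its scalp expression — the
spatial response function.

# The analysis pipeline

The canonical settings, all exposed in `srcflow_config()`:

* analysis rate 30 Hz (the Nyquist rate afforded by a 60 Hz video);
* zero-phase high-pass at 1 Hz (4th-order Butterworth, forward–backward);
* robust PCA (principal component pursuit) with sparsity weight
  $\lambda = 0.5$ scaled by $1/\sqrt{\max(D,T)}$, keeping the low-rank part;
* four virtual ocular electrodes built from frontal channels (two lateral
  differences for horizontal eye movement, two superior sums for blinks),
  regressed out of every channel;
* iterative rejection: channels whose mean power exceeds the channel-power
  mean by 4 SD, and samples (plus immediate neighbours) whose absolute
  amplitude exceeds the channel's mean absolute amplitude by 4 SD, repeated
  for 3 iterations with statistics recomputed from surviving entries;
* temporal embedding with $L = 30$ causal lags (0–967 ms at 30 Hz);
* EEG-side regularisation by truncating the EEG covariance eigenspectrum to
  $K = 11$ dimensions (a variance-fraction alternative is available);
* alpha power as the temporal mean square of an 8–12 Hz zero-phase
  4th-order Butterworth band-pass, averaged over a subject's repeated
  trials;
* paired two-tailed Wilcoxon signed-rank tests for condition contrasts,
  one-tailed rank-sum tests for subgroup contrasts;
* subject-label-swap permutation tests (1000 permutations) with
  Benjamini–Hochberg FDR control at $q = 0.05$ across 96 electrodes or 30
  lags.

CCA bases are always fitted on data *pooled across conditions* (per
subject), and each condition is then projected through the common basis, so
that per-condition SRCs are comparable. The lag embedding restarts with
zero padding at every trial boundary; no lag row mixes samples from
different trials. Samples flagged invalid by the rejection stage are zeroed
and excluded from all covariance estimates by pairwise deletion.

# The synthetic-data generator

No public recordings accompany the analysis this package implements, so the
generator is a first-class module: every downstream stage is validated
against simulations with known ground truth.

A trial is built as

$$r(t) = g_c \sum_{j=1}^{K_0} a_j \,(h_j * s)(t) + \text{noise} +
  \text{alpha} + \text{artifacts} + \text{ocular},$$

where

* $s(t)$ is squared low-pass Gaussian noise (band-limited below 3 Hz by
  default): nonnegative, positively skewed, and slowly varying, like the
  optic flow of vehicle gameplay;
* $h_j$ are unit-norm smooth lag profiles; the defaults peak at lags 6 and
  12 (200 and 400 ms at 30 Hz), with later components biphasic;
* $a_j$ are smooth, linearly independent channel maps with decreasing
  norms (default $30/\sqrt{j}$ µV);
* $g_c$ is the condition gain (defaults: 1.25 for the engaged-play
  conditions, 1.0 for passive viewing);
* noise is AR(1)-coloured (coefficient 0.9, an approximately $1/f$
  spectrum) and spatially smoothed across the channel index (Gaussian
  kernel, $\sigma = 2$ channels), scaled to `noise_sd` µV per channel;
* alpha is a 10 Hz sinusoid with random phase per channel, added on a
  designated block of central channels with condition-dependent amplitude
  (defaults: 2 µV passive, 1 µV engaged — passive viewing shows *more*
  alpha, engaged conditions desynchronise it);
* artifacts are sparse single-sample spikes of 150–400 µV at a Poisson rate
  per minute;
* ocular activity comprises a vertical source (a train of 200 ms biphasic
  blinks plus weak slow drift) on the superior frontal channels and a
  horizontal gaze-drift source with antisymmetric weights on the lateral
  frontal channels. The split mirrors vertical/horizontal EOG derivations
  and makes the default virtual-electrode construction ocular-dominated,
  which is what gives ocular regression something meaningful to remove.

Cohorts share filter shapes across subjects; spatial maps receive
per-subject perturbations (relative SD 0.2, then renormalised), giving the
between-subject variability that group statistics need. Every generator is
bit-reproducible from its seed.

What the generator does **not** emulate: a real electrode montage and
volume-conduction geometry (channels live on an abstract index line), EEG
nonstationarity, stimulus-locked eye movements, movement/somatosensory
responses of active play, or the empirical spectrum of real optic flow.
Passing tests therefore demonstrate the correctness and calibration of the
*algorithms* under a plausible generative model — not fidelity to any
particular recording system.

# Numerical choices

**Stimulus-side conditioning.** A band-limited stimulus makes the lag
covariance $C_{ss}$ nearly singular: its trailing eigenvalues sit at the
low-pass filter's stopband floor (about $10^{-5}$ of the leading
eigenvalue for the default 3 Hz feature). Whitening with
$C_{ss}^{-1/2}$ would amplify sampling noise in those directions by
$1/\sqrt{\lambda}$ — several hundredfold — turning estimated temporal
filters into high-frequency noise while leaving the canonical correlations
essentially unchanged. `fit_cca()` therefore (a) truncates the stimulus
eigenspace at a relative tolerance of $10^{-5}$ (`stim_rank_tol`; a no-op
for broadband stimuli, which is why oracle-equivalence tests against
`stats::cancor` still agree to $10^{-15}$), and (b) offers an optional
ridge shrinkage of the stimulus whitening (`stim_shrinkage`, default 0 so
the solution is exact CCA). For filter-recovery work we use
`stim_shrinkage = 0.05` (of the mean eigenvalue); recovery quality is flat
across 0.05–0.2, so the value is not delicate.

**Identifiability at realistic SNR.** With a single planted component,
temporal filters are recovered at $|\mathrm{cor}| \ge 0.9$ even when
$\rho_1 \approx 0.3$ (six pooled 176 s trials). With three simultaneously
planted components at matched total SNR, the weakest component's
correlation sits near the sampling floor and neighbouring canonical pairs
with similar $\rho$ mix rotationally; the median per-component recovery
plateaus near 0.85 under the generator's coloured-noise model regardless of
regularisation. This is a property of the estimation problem, not a bug:
the acceptance suite documents both the single-component result and the
multi-component plateau.

**Robust PCA weights.** The solver is the inexact augmented-Lagrangian
principal component pursuit with effective weight
$\lambda/\sqrt{\max(D,T)}$. The classical choice $\lambda = 1$ carries the
exact-recovery guarantee and reproduces a planted rank-3 + 1 %-spikes
decomposition to $10^{-7}$ relative error; the pipeline default
$\lambda = 0.5$ is deliberately more aggressive (it shifts more energy into
the sparse term) and is kept because it is the canonical setting for this
analysis. Solver-exactness tests use $\lambda = 1$.

**When preprocessing helps.** Covariance-truncated CCA is intrinsically
robust to low-rank artifacts — a 700 µV blink occupies one of the 11
retained dimensions and leaves total SRC unchanged. Preprocessing earns its
keep when contamination is dense and spatially independent (heavy spike
regimes), where artifact energy displaces signal from the retained
subspace; the test suite demonstrates the benefit in that regime. Ocular
regression inevitably removes the small share of neural signal that lies in
the regressor span (about 2 % under the default generator).

**Permutation p-values and the BH floor.** Permutation p-values use the
$(1 + \#\{|null| \ge |obs|\})/(n_{perm}+1)$ convention, so
$p \ge 1/(n_{perm}+1)$. A consequence worth knowing: a *lone* discovery
among $m$ entries needs $p \le q/m$ under Benjamini–Hochberg, hence
$n_{perm} + 1 \ge m/q$ — at least 1920 permutations for 96 electrodes at
$q = 0.05$. With fewer permutations an isolated effect can never be
flagged, no matter how large. The default $n_{perm} = 1000$ is kept for
comparability, but localized single-electrode effects should be tested with
$n_{perm} \ge 2500$.

**Other conventions.** Component signs are fixed so each temporal filter's
largest-magnitude coefficient is positive. Rejected channels are dropped
(masked), not interpolated. The frame-to-frame difference feature is
rectified (absolute value) before spatial averaging, since a signed mean
cancels on pan-dominated content; a flag restores signed behaviour.
Zero-variance series fail loudly rather than silently z-scoring to zero.
The Horn–Schunck stencils are the classic 2×2×2 forward differences; they
carry a half-pixel directional offset, so flow estimates are
rotation-consistent to about 1–2 %, not machine precision. Exact Wilcoxon
p-values are computed by sign-pattern enumeration (as a polynomial
convolution over doubled mid-ranks, so ties are handled) for $n \le 25$.

# Statistical calibration and power, as tested

The test suite (see `tests/testthat/test-acceptance.R`) validates, among
others: agreement of canonical correlations with a brute-force generalized
eigenproblem oracle to $10^{-8}$ over 50 random instances; exact recovery
in the noiseless limit; Wilcoxon type-I error within [0.02, 0.09] at
$\alpha = 0.05$ over simulated null cohorts of 18 paired subjects; power
$\ge 0.8$ to detect a 1.25 response-gain ratio with paired Wilcoxon tests
over 50 simulated cohorts; FDR-flagged proportion $\le q$ under the global
null; and localisation of a planted central-channel alpha reduction in
$\ge 80\%$ of cohort replicates. To keep the default run fast the cohort
simulations use 48 channels and 60–120 s trials — dimensions at which the
per-subject effect size of the gain manipulation (about 1.4–2.5 SD of the
paired difference) is comfortably in the detectable range; the generator's
full-scale defaults (96 channels, 176 s) behave the same way and are used
in the slower recovery experiments.

# Known limitations

* Multi-component temporal-filter recovery at low SNR is limited by
  rotational mixing (above); interpret individual filter estimates from
  single sessions with care and prefer pooled or group-level fits.
* The masked (pairwise-deletion) covariance is not guaranteed positive
  semi-definite for heavily ragged masks; negative eigenvalues are clipped
  before whitening.
* The BrainVision reader covers multiplexed IEEE float-32 and int-16
  recordings — the common ActiChamp export — not the full format zoo, and
  EDF input is not implemented.
* The alpha analysis runs at the 30 Hz analysis rate (8–12 Hz sits below
  the 15 Hz Nyquist); running it on the raw acquisition rate before
  downsampling is possible by passing the raw recording directly to
  `alpha_power()`.
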