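---
title: "The Tsallis improved-permutation-entropy causality plane: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Tsallis improved-permutation-entropy causality plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipeplane)
```

## The model

A single-channel series $X = \{x_1,\dots,x_N\}$ is reduced to a
distribution over symbolic patterns and then summarized by a family of
entropy/complexity pairs indexed by the Tsallis parameter $q$.

**Symbolization.** The series is first mapped through the Gaussian CDF
of its own mean $\mu$ and population variance $\delta^2$,
$y_i = \Phi((x_i - \mu)/\delta)$, giving values strictly inside
$(0,1)$. Delay vectors
$Y_j = (y_j, y_{j+\tau}, \dots, y_{j+(m-1)\tau})$ are then quantized:
the first coordinate receives its bin index under a uniform
quantization of $[\min y, \max y]$ into $L$ bins of width
$\Delta = (\max y - \min y)/L$, and coordinate $k \ge 2$ receives
$S_{j,1} + \lfloor (Y_{j,k} - Y_{j,1})/\Delta \rfloor$. Unlike ordinal
(rank) patterns, these symbols keep the window's absolute level and
the amplitude gaps inside the window, and there is no tie-breaking
problem: equal values simply share a bin.

**q-statistics.** With pattern probabilities $P$ over $n = L^m$ states,
the Tsallis entropy is $S_q[P] = \sum_j P_j \ln_q(1/P_j)$ with
$\ln_q x = (x^{1-q}-1)/(1-q)$ and $\ln_1 x = \ln x$; normalized,
$H_q = S_q[P]/\ln_q n \in [0,1]$. The disequilibrium is a q-deformed
Jensen–Shannon divergence from the uniform distribution $U$,

$$D_q(P,U) = \tfrac12 K_q(P \,\|\, M) + \tfrac12 K_q(U \,\|\, M),
\qquad M = \tfrac{P+U}{2},
\qquad K_q(A \,\|\, B) = -\sum_{A_j > 0} A_j \ln_q\!\frac{B_j}{A_j},$$

normalized by its maximum $D_q^\* = D_q(\text{delta}, U)$ to give
$\Delta_q \in [0,1]$, and the statistical complexity is
$C_q = \Delta_q \cdot H_q$. $C_q$ vanishes at both extremes of order —
for the uniform distribution ($\Delta_q = 0$) and for a one-point
distribution ($H_q = 0$) — so it measures structure, not randomness.
Sweeping $q$ traces the curve $(H_q, C_q)$, the causality-plane
signature; small $q$ amplifies rare patterns, large $q$ the dominant
ones, so the curve probes the whole shape of $P$ rather than one
moment of it.

**Features and scales.** The grid $q$ at the minimum of $H_q$
($q_H^\*$) and at the maximum of $C_q$ ($q_C^\*$) are scalar features.
Coarse-graining (non-overlapping window means at scale $s$) followed by
the same analysis yields a multiscale feature vector.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| $m$ | 4 | embedding dimension; 3–7 is the informative range, 4 keeps $L^m$ small enough for short series |
| $\tau$ | 1 | time delay (samples); 1 is standard for densely sampled signals |
| $L$ | 4 | quantization levels; useful range 2–8, see below |
| q grid | 0 to 100 step 0.001 | closed at both ends; $q=0$ degenerates to $\ln_0 x = x - 1$, $q=1$ is the Shannon branch |
| scales | 1–20 | each scale must leave $\ge (m-1)\tau + 1$ coarse samples |

All quantities are dimensionless; the CDF normalization makes the
pipeline exactly invariant to positive affine rescaling of the input
(so units of the raw series never matter).

The choice $L = 4$ is the midrange of the useful 2–8 band and, in the
short white-noise benchmark below, the level whose ensemble statistics
sit closest to published reference behaviour. $L$ is exposed
everywhere and the acceptance suite sweeps the full 2–8 range.

## Numerical choices

- **Closed forms.** $S_q$ is evaluated as $(\sum_j P_j^q - 1)/(1-q)$
  and $K_q(A\|B)$ as $(1 - \sum_j A_j^q B_j^{1-q})/(1-q)$, algebraically
  identical to the defining sums; the brute-force sums serve as test
  oracles.
- **Stability.** Every power product is computed as a single
  $\exp(q \log A + (1-q)\log B)$; computing $B^{1-q}$ alone overflows
  for $q$ near 100. Quantities remain finite for $q \le 100$ and
  probabilities down to $10^{-6}$.
- **Grouping.** Identical pattern counts are grouped, and the
  $L^m - k$ unobserved states (which share one midpoint value
  $1/2n$) collapse into a single term, so a full 100001-point q sweep
  costs milliseconds even for $L = 8$.
- **$q = 1$.** Values of $q$ within $10^{-9}$ of 1 take the Shannon
  branch ($-\sum P \log P$, Kullback–Leibler forms), which is also the
  continuity limit of the deformed branch.
- **Ties and degeneracy.** Feature extraction breaks grid ties toward
  the smallest $q$; a curve constant in both coordinates is flagged
  `degenerate`. A constant input series is an error, not $H_q = 0$.
- **Clipping.** The difference symbols can fall outside $0\ldots L-1$
  (a large downward excursion from a low first bin); they are clipped
  back so the alphabet stays at exactly $L^m$ patterns — the only
  reading consistent with a fixed pattern count.
- **Bin range.** $\Delta$ uses the min/max of the whole normalized
  series (recomputed per coarse-graining scale), not per-window or the
  theoretical $(0,1)$; prototyping showed the empirical and theoretical
  ranges differ negligibly for $N \gtrsim 200$.

## Design choices that were genuinely open

- **The q-deformed divergence.** The printed source formula for
  $D_q$ is corrupted. We reconstructed it as the symmetrized
  q-Kullback form above, validated by requiring exact agreement with
  the classical Shannon JSD at $q = 1$; the deformation is isolated in
  one function (`q_jsd`) so an alternative kernel can be swapped. The
  Jensen-difference alternative $S_q(M) - \tfrac12 S_q(P) - \tfrac12
  S_q(U)$ was prototyped and rejected because it drives $C_q \to 0$ at
  large $q$, contradicting the known rising complexity tail of white
  noise.
- **The normalizer $D_q^\*$.** No closed form is stated in the
  literature for the deformed case; we evaluate the divergence at a
  one-point distribution, the known maximizer in the Shannon
  complexity-plane literature, and guard the choice with a
  numerical-maximization regression test (random and
  optimizer-refined distributions never exceed it).
- **$q_H^\*$ is the argmin of $H_q$.** The entropy argmax would sit at
  the grid boundary ($H_q \to 1$ as $q$ grows for any non-degenerate
  distribution) and carry no information.
- **Ensembles.** Multi-realization experiments average $H_q$/$C_q$
  pointwise over $q$ before feature extraction (`average_curves`);
  per-realization features remain available by mapping
  `extract_features` over the curve list. Both paths are exposed
  because published figures can be read either way.
- **Lorenz integration.** The classical fixed-step RK4 is implemented
  directly: a general-purpose ODE front end we tried first produced
  output deviating from the fixed-step scheme by far more than the
  $O(dt^4)$ truncation error, breaking the dt-halving convergence
  check. Initial state $(1,1,1)$, 5000-step burn-in, the $x$
  coordinate observed — all exposed as arguments.
- **Simulator conventions.** Pink noise is made by exact spectral
  shaping ($1/\sqrt f$ amplitude scaling, DC bin zeroed, standardized
  output) rather than octave-stacking approximations. AR burn-in is
  1000 samples from zero history; the innovation stream for order 0 is
  the white-noise generator itself. Noise injection scales the noise
  so the realized power ratio equals the requested SNR exactly.

## What the generators emulate — and what they do not

The simulators reproduce the canonical test battery: white and 1/f
noise (the two PSD archetypes), AR(1)–AR(8) with coefficients
$\alpha_i = 1/2^i$ (a ladder of increasing temporal correlation), and
the chaotic Lorenz attractor with additive Gaussian noise at controlled
SNR. Passing tests on these shows the statistic orders randomness and
structure correctly and is reproducible — it does **not** show
robustness to the nonstationarity, artifacts, missing beats, or
recording noise of real physiological data, which have no synthetic
counterpart here.

Two published qualitative claims did not survive reimplementation, and
the corresponding checks are left failing deliberately rather than
weakened. At $-10$ dB SNR the noise carries ten times the signal power
while the densely sampled ($dt = 0.001$) Lorenz signal moves only
$\sim\!10^{-2}$ of its range per step, so the sample-to-sample
amplitude differences the symbols encode are overwhelmingly noise: the
noisy curve is measurably indistinguishable from the white-noise curve
(ensemble $L_1$ distance $10^{-4}$) and not close to the clean curve
(distance $10^{-2}$). And at length 60 the white/pink ensemble-mean
$H_q$ curves separate by at most $\sim\!1.8$ pooled standard
deviations across $L = 2\ldots 8$, short of a strict 2-SD effect-size
bound (though overwhelming for a 20-vs-20 two-sample test).

## Problem sizes

The reference experiments run at desk scale by design: 20 realizations
of length 210 on the full 100001-point q grid for the white-noise
benchmark; $N = 10^4$, 20 seeds, single $q = 1.01$ for the AR ladder;
$N = 5\times 10^4$ with a 0.1-step grid for the Lorenz comparison;
$N = 60$ for the short-series separability check. The grouped sweep
makes the full grid cheap, so none of these choices trades fidelity
for speed.

```{r example}
x <- ar_process(2000, order = 4, seed = 1)
cv <- causality_curve(x, q = q_grid(0, 10, 0.01))
extract_features(cv)
```
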