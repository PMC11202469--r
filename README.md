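# tipeplane

Feature extraction for complex single-channel time series — heart-rate
(RR-interval) records, machine vibration, underwater acoustics, chaotic
signals — via a Tsallis-entropy complexity–entropy causality plane built
on an amplitude-aware ordinal symbolization.

## The method

Classical permutation entropy ranks the samples inside each embedded
window and discards their amplitudes, which blunts its ability to
separate signals and makes it fragile under noise. Here each window is
symbolized so that amplitude survives:

1. **Normalize**: map the series through the Gaussian CDF of its own
   mean μ and variance δ², `y_i = Φ((x_i − μ)/δ)`, so `y ∈ (0,1)` and
   the whole pipeline is invariant to positive affine rescaling.
2. **Embed**: form delay vectors `Y_j = (y_j, y_{j+τ}, …, y_{j+(m−1)τ})`.
3. **Symbolize**: quantize the first coordinate into one of `L` uniform
   bins over `[min y, max y]`; each later coordinate stores that bin
   plus `⌊(Y_{j,k} − Y_{j,1})/Δ⌋` (bin width `Δ`), clipped into
   `0…L−1`. Every pattern keeps the window's absolute level *and* its
   internal amplitude differences; the alphabet has `L^m` patterns.
4. **q-statistics**: from the pattern probabilities `P` compute, for
   each `q` on a grid, the normalized Tsallis entropy
   `H_q = S_q(P)/ln_q(L^m)` with `S_q = Σ_j P_j ln_q(1/P_j)`,
   `ln_q x = (x^{1−q} − 1)/(1 − q)`, and the statistical complexity
   `C_q = Δ_q · H_q`, where the disequilibrium
   `Δ_q = D_q(P,U)/D_q*` is a q-deformed Jensen–Shannon divergence from
   the uniform distribution `U`, normalized by its maximum (attained at
   a one-point distribution).
5. **Features**: the curve `(H_q, C_q)` traced over the q grid is the
   causality-plane signature; the grid locations of the entropy minimum
   (`q_H*`) and complexity maximum (`q_C*`) are scalar features.
   Coarse-graining (non-overlapping window means at scales `s = 1…20`)
   yields a multiscale feature vector of `(q_H*, q_C*)` pairs.

Defaults: `m = 4`, `τ = 1`, `L = 4`, q from 0 to 100 in steps of 0.001.

Seeded generators for white noise, 1/f (pink) noise, autoregressive
processes with the geometric coefficient scheme `α_i = 1/2^i`, and the
Lorenz system (fixed-step RK4, dt = 0.001) reproduce all simulation
experiments without external data.

## Worked example

Separate a strongly autocorrelated AR(4) process from white noise:

```r
library(tipeplane)

x <- ar_process(5000, order = 4, seed = 42)       # alpha = 1/2, 1/4, 1/8, 1/16
ms <- multiscale_features(x, m = 4, tau = 1, L = 4,
                          q = q_grid(0, 100, 0.01), scales = c(1, 2, 5))
ms$features
#>   scale q_H_star  H_min q_C_star  C_max degenerate
#> 1     1     0.27 0.4848     2.91 0.5781      FALSE
#> 2     2     0.14 0.4076     2.96 0.6228      FALSE
#> 3     5     0.00 0.4000     2.82 0.5664      FALSE

w <- white_noise(5000, seed = 42)
extract_features(causality_curve(w, q = q_grid(0, 100, 0.01)))
#>   scale q_H_star  H_min q_C_star  C_max degenerate
#> 1     1     0.56 0.9397     2.48 0.1078      FALSE
```

The AR(4) signal sits deep in the plane (entropy minimum ≈ 0.48,
complexity maximum ≈ 0.58 at scale 1): its samples are predictable but
structured. White noise hugs the low-complexity edge (`H_min ≈ 0.94`,
`C_max ≈ 0.11`): nearly maximal entropy, almost no structure. The
`(q_H*, q_C*)` columns across scales are the classifier-ready feature
vector.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/tipeplane.R simulate --kind ar --order 4 --n 5000 --seed 42 --out ar4.txt
Rscript inst/cli/tipeplane.R mscale --in ar4.txt --out ar4_plane --scales 1:5
```

which writes `ar4_plane.tsv` (columns `scale, q, Hq, Cq`) and
`ar4_plane.json` (per-scale features plus the echoed configuration).

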