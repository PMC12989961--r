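# gsvdnmf

Rank expansion for nonnegative matrix factorization (NMF) via the
generalized singular value decomposition (GSVD).

## The problem

NMF decomposes a nonnegative data matrix `X` (m × n) as `X ≈ W H` with
`W ≥ 0` (m × r, components as columns) and `H ≥ 0` (r × n, components as
rows), minimizing the squared Euclidean objective

    D(W, H; X) = ½ ‖X − W H‖²_F .

In source-separation practice — LC–MS ion-count unmixing, imaging,
audio spectrograms — the true number of sources is unknown. Running NMF
with too small a rank merges or drops sources, and the conventional
remedy, re-running NMF from scratch at a larger rank, discards all the
work already done and often lands in a worse local optimum.

This package augments an existing *under-complete* rank-`r0`
factorization `(W0, H0)` with `k` new components in a single, one-shot
linear-algebra step, then polishes by standard NMF. The key idea: the
truncated SVD `X ≈ U Σ Vᵀ` at rank `r0` is the *global* optimum of
unconstrained rank-`r0` approximation, so directions where the SVD and
the NMF disagree are exactly the directions the NMF is missing. Writing
`B = W0 H0`, those directions extremize the generalized Rayleigh
quotient `‖Σ ŷ‖² / ‖Uᵀ B V ŷ‖²`, which is solved to high accuracy by
the GSVD of the r0 × r0 pair

    Σ = M1 D1 Qᵀ ,   Uᵀ B V = M2 D2 Qᵀ .

The generalized singular values `λ_i = d1ᵢ²/d2ᵢ²` rank the candidate
directions `yᵢ = V (Qᵀ)⁻¹ zᵢ`: `λ` far above 1 (or infinite) flags
variance the NMF failed to capture. The top-`k` directions are made
nonnegative by sign-resolved truncation against the residual
`max(X − W0 H0, 0)`, new loading columns `S` and amplitude rescalers
`α ≥ 0` for the old components are fitted by a decoupled least-squares /
NNLS solve, each new rank-1 pair is truncated to its dominant
nonnegative section, and all `r0 + k` amplitudes `β ≥ 0` are rebalanced
by NNLS. The augmented factorization never fits worse than `(W0, H0)`,
strictly better whenever a residual remains, and costs about as much as
two or three HALS sweeps.

## What's in the package

- `gsvdNMF()` — the full pipeline: under-complete NMF → GSVD feature
  recovery → NMF refinement.
- `gsvdFeatureRecovery()` — the one-shot recovery step on an existing
  `(W0, H0)` (all intermediates returned: `Y`, `S`, `α`, `β`, spectrum).
- `incrementalExpand()` — grow the rank one component at a time.
- `benchmarkCompare()` — paired protocol: expansion vs. restarting NMF
  from a shared random initialization.
- `runHALS()`, `runMU()`, `nndsvdInit()` (plain/a/ar variants),
  per-component relative-change convergence, `relativeFittingError()`.
- `truncatedSVD()`, `gsvdPair()`, `nnlsGram()` — the numeric core.
- `makeSynthetic()` / `syntheticSpec()` — seeded generator of smooth
  nonnegative sources; `matchComponents()` — exact Hungarian matching
  of estimated to true components.
- `readMatrix()` / `writeMatrix()` (delimited, Matrix Market),
  factorization serialization, and a CLI (`inst/cli/gsvdnmf.R`) with
  `simulate`, `factorize`, `recover`, `run`, `expand`, `benchmark` and
  `replay` subcommands.

## Worked example

The package ships the 2 × 2 concept fixture: a data matrix together
with a deliberately imperfect rank-2 factorization.

```r
library(gsvdnmf)
fx <- fixture2x2()
relativeFittingError(fx$X, list(W = fx$W0, H = fx$H0))
#> [1] 14.43888
rec <- gsvdFeatureRecovery(fx$X, fx$W0, fx$H0, k = 1)
rec@lambda
#> [1] 2.7965420 0.2268592
relativeFittingError(fx$X, list(W = rec@Wg, H = rec@Hg))
#> [1] 1.560134e-29
```

The printed pair misfits `X` by 14.4 %. The generalized singular value
spectrum splits by an order of magnitude — the direction with
`λ ≈ 2.80` carries the variance the factorization is missing — and
adding that single flagged direction reproduces `X` to machine
precision.

On a realistic scale, a ten-source synthetic scene (200 × 300, Gaussian
bumps, 10 % noise):

```r
sc  <- makeSynthetic(syntheticSpec(seed = 1))
fit <- gsvdNMF(sc$X, r0 = 9, k = 1, engine = "hals", init = "nndsvd")
fit@metadata$finalError                      # rank-10 result via expansion
#> [1] 0.5596027
relativeFittingError(sc$X, runHALS(sc$X, nndsvdInit(sc$X, 10),
                                   convergenceControl()))
#> [1] 0.5693356
matchComponents(sc$Wtrue, basisMatrix(fit))$meanCorrelation
#> [1] 0.9523135
```

Expanding the rank-9 solution beats restarting HALS at rank 10 on this
draw and recovers the planted sources (mean matched Pearson
correlation 0.95; 0.96–0.98 averaged over draws, see the acceptance
script).

## Method details

See the methods vignette (`vignettes/gsvd-nmf-methods.Rmd`) for the
model, the decoupled solver, numerical conventions, the synthetic
generator's assumptions, and known limitations.
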