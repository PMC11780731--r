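---
title: "Walk relevances and interaction metrics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walk relevances and interaction metrics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walklrp)
```

This vignette is the package's own account of its science: the potential it
trains, the relevance propagation it runs, the metrics it computes, the
numerical conventions it fixes, and what the synthetic test systems can and
cannot tell you about real machine-learning force fields.

## The toy potential

The model is an invariant message-passing network of the
continuous-filter-convolution family. Atom `k` starts from an element
embedding of width `m`. At each of `T` layers, every neighbour `j` inside
the cutoff `c` sends a message: a filter MLP maps the Gaussian radial-basis
expansion of the distance `r_kj` to an `m`-vector that gates (elementwise)
a linear transform of `H_{t-1,j}`; messages are summed over neighbours and
combined with the atom's own state through a two-layer MLP. An atom-wise
readout MLP produces per-atom energies whose sum is the prediction. The
activation is the shifted softplus, smooth and zero at zero.

Assumptions and deliberate restrictions:

- **Distance-only featurization.** The network sees interatomic distances,
  never orientations, so predictions are exactly invariant under rigid
  motions and equivariant under atom permutation (both are tested).
- **Bias-free throughout.** Biases absorb relevance that no walk can carry;
  omitting them makes the conservation axiom exact in the zero-stabilizer
  limit. The cost — the network cannot represent a constant offset per
  atom — is immaterial for the synthetic targets used here.
- **Energy-only.** Explanations target the scalar prediction; forces are
  out of scope.

Tunable parameters, defaults, and why:

| parameter | default | units | rationale |
|---|---|---|---|
| depth `T` | 2 | layers | smallest depth with genuinely higher-order walks |
| cutoff `c` | 5 | Å | the range found adequate for molecular MLFFs |
| `n_rbf` | `round(4c)` | — | keeps basis spacing at 0.25 Å across model ladders |
| embedding `m` | 12 | neurons | fits 6-atom Morse clusters to a few % of label SD |
| learning rate | 0.01 | — | stable full-batch Adam on all test datasets |

The depth-ladder convention fixes `T * c` (e.g. 15 Å), so deeper models see
shorter edges but comparable total receptive fields; `n_rbf = round(4c)`
keeps the radial resolution constant along the ladder.

## Relevance propagation

Relevance starts at each atom's energy contribution (sum pooling is
trivially conservative) and is pushed down layer by layer. Every linear
step redistributes relevance proportionally to the contributions
`z = w * x`; elementwise nonlinearities pass relevance through unchanged;
the distance-dependent filter values are treated as constants (edge gates),
so relevance flows through atom features only — a walk is a sequence of
atoms, not of distances. At each layer the split over contributing atoms
(self state plus one gated message per neighbour) is kept unpooled, and the
chosen index is appended to the walk. Enumeration is exact and exponential
in `T`; a configurable cap (default 1e7 walks) aborts infeasible requests.
The polynomial-time reformulations of walk attribution are intentionally
out of scope: at the package's problem sizes exact masked propagation is
cheaper than their bookkeeping, and simpler to verify.

Numerical conventions:

- **Stabilizer.** The epsilon rule uses a sign-matched *relative*
  stabilizer: denominators become `d * (1 + eps)`. Epsilon is dimensionless
  and each division attenuates the redistributed relevance by exactly
  `1/(1+eps)`, so the conservation residual is about
  `(number of divisions) * eps` regardless of activation scale. An additive
  stabilizer `d + eps*sign(d)` makes the *relative* residual blow up
  whenever the per-atom energies nearly cancel in the total — a frequent
  situation in untrained networks — although both conventions are exact at
  `eps = 0`. Default `eps = 1e-6`; a gamma rule (positive-contribution
  boost) is available by configuration.
- **Exact zeros.** A denominator that is exactly zero cannot be
  stabilized multiplicatively; those relevance shares are dropped, counted,
  and surfaced through the map's `dropped` attribute.
- **Determinism.** Propagation contains no randomness; identical inputs
  give bitwise-identical maps.

Correctness is established two ways: conservation
(`sum_W R_W = y`, residual at machine precision for `eps = 0` and about
1e-5 at the default epsilon) and an independent algebraic oracle — on a
network with identity activations the prediction expands exactly into
per-walk weight products, which the engine must match to 1e-10.

## Metrics

- **Importance** normalizes absolute relevances per molecule. The
  absolute value is the only normalization that lands in `[0, 1]` for
  signed relevances; it also makes strengths comparable across conformers.
- **Extent** is the diameter of the minimum enclosing sphere of the
  visited atoms, computed by Welzl's algorithm with explicit circumsphere
  solves for 2–4 boundary points; degenerate boundaries (collinear
  triples, coplanar quadruples) fall back to sub-boundary spheres. A
  brute-force candidate-sphere oracle cross-checks it to 1e-9 Å in the
  tests.
- **Interaction range.** The threshold measure requires `p_min > 0`
  (at `p_min = 0` it would always return the geometric maximum, revealing
  nothing about the learned solution); default `p_min = 0.001`. The
  generalized expectation is evaluated in log space so large orders do not
  overflow; `a = 4` emphasizes the long tail while discarding negligible
  walks, `a -> infinity` recovers the maximum extent.
- **Interaction strength.** Exclusive mode compares visited-atom *sets* to
  `{i, j}`: walks may revisit either atom any number of times. Self
  strength (`i = j`), when requested, sums walks that visit only that
  atom — a documented extension, not part of the pair table by default.
- **Element-pair matrices** average `log10` strength (mean of logs, not
  log of means — the geometric picture matches the orders-of-magnitude
  reading of the many-bodyness measure); cells with no pairs are absent
  rather than zero-filled. The bonded/nonbonded split defaults to 1.6 Å.
- **Many-bodyness.** Percentiles use linear interpolation between order
  statistics (R type 7); the test targets are constructed so that any
  standard convention gives the same value. Bins default to 0.5 Å width
  with at least 20 pairs (dropped bins are reported); `gamma_bar` is the
  unweighted mean over retained bins — weighting by pair count would let
  the heavily populated bonded bins dominate a statistic that is about
  *equally distant* pairs. Zero strengths are excluded from log statistics
  and counted.
- **Decay fits** operate on per-bin medians (robust to the heavy tails of
  importance distributions); both candidate laws are fit to the same
  response `log(median)`, so their residual sums of squares are directly
  comparable and the preferred model is the smaller-residual one. Flat
  profiles set a degenerate flag instead of forcing a winner.

## Synthetic systems and what they show

The generator produces chains (fixed spacing, optional jitter), packed
random clusters (rejection sampling in a density-sized box), dimer scans,
and repeated-distance sets: clusters embedding one tagged same-element pair
at an exactly repeated separation. Labels come from a Morse pair potential
(`D = 5` kcal/mol, `r_e = 1.5` Å, `a = 1.5`/Å — covalent-bond-like scales)
plus an optional three-body term, `A sin^2(theta) exp(-(r1+r2)/rho)` summed
over triple vertices, chosen for its closed-form zero on collinear triples.
The tagged separations default to 2.2/3.2 Å, mid-bin for the 0.5 Å binning,
so floating-point rounding of a rotated exact distance can never straddle a
bin edge.

These systems give every metric a known answer: a strictly 2-body
potential yields identical strengths for equally distant same-element
pairs, hence exactly zero many-bodyness; adding the three-body term injects
neighborhood dependence whose magnitude grows with the amplitude (the
analytic strengths attribute each triple's absolute energy equally to its
three pairs); a trained cutoff-graph model must show exponentially decaying
strength with distance because walk counts decay exponentially.

What passing these tests does *not* show: behaviour on real chemistry.
The systems have no conformational ensembles, no electrostatics or
dispersion tails, no element diversity beyond a small palette, and energies
from closed-form potentials rather than electronic structure. Conclusions
about production MLFFs require applying the same metrics to those models;
the package's claim is that the metric implementations are correct, not
that the toy potential is chemistry.

## Problem sizes

The shipped tests and experiments use 5–10-atom systems, tens to a couple
hundred conformers, and a few hundred Adam epochs — sizes at which exact
walk enumeration, full-batch training and 1000-fold brute-force oracle
comparisons all complete in seconds, chosen so the entire evidence chain
stays cheap to re-run while still exercising every code path (deeper
models are covered by the depth ladder in `run_experiment()`).

## Known limitations

- Walk enumeration is exponential in depth; the engine is for small
  molecules and shallow models by design.
- Equivariant (vectorial-feature) architectures are not supported; the
  relevance rules here cover invariant scalar features only.
- The stability classifier consumes an energy series; it does not run
  molecular dynamics.
- Training is full-batch on CPU; it is a testbed, not a production
  trainer.
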