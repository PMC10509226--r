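---
title: "Cell-circuit methods: motif census and fibroblast-macrophage dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-circuit methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcircuit)
```

This vignette documents the science and the design choices behind
`cellcircuit`: the weighted motif census of cell–cell interaction networks,
the two-population growth circuit, the inference machinery, and the
synthetic-data generators that make everything testable without
measurements. It states no empirical result that the package's tests do not
themselves compute.

## 1. From an interaction matrix to a cell network

The input is a square cell-type × cell-type matrix of non-negative
interaction strengths (typically cumulative ligand–receptor scores from a
tool such as CellChat; that scoring is deliberately out of scope here). The
matrix is read as the adjacency matrix of a weighted directed graph: rows
send, columns receive, and the diagonal holds autocrine signaling, kept as
self-loop edges.

**Weak-edge pruning.** Interactions that *collectively* contribute at most
a fraction `weak_fraction` (default 0.10) of the total weight are excluded:
candidate edges sorted by ascending weight are removed greedily while the
cumulative removed weight stays within the budget. Ties are broken by
lexicographic (sender, receiver) order so the result is deterministic; the
choice only matters when equal-weight edges straddle the budget boundary.
Two consequences worth knowing: at `weak_fraction = 0` every positive cell
is an edge, and the retained weight is always at least
`(1 − weak_fraction)` of the total (both are tested properties).

**Hierarchy.** `node_strengths()` reports weighted out- and in-degrees
(self-loops count in both, since an autocrine interaction is both sent and
received) and flags the *root* — the node with the highest weighted
out-degree, ties again lexicographic. The layered visualization of such
hierarchies is presentation, not analysis, and is not reimplemented.

## 2. The weighted motif census

### Pattern classes

A *pattern* is an isomorphism class of small directed graphs that are
weakly connected through their inter-node edges. For two-cell circuits the
autocrine loops are biologically meaningful and distinguish classes: there
are exactly 7 connected two-node patterns with self-loops (single edge or
mutual edges, times the loop configurations). For three- and four-cell
circuits, classes are defined by the inter-node edge structure alone (13
connected triads, 199 connected four-node classes); the self-loop status of
matched nodes is observable per instance but does not split classes. This
split reading — loops classify at `k = 2`, not at `k ≥ 3` — is the only one
consistent with both printed counts (7 and 13) when top-scoring circuits
display autocrine loops.

Enumeration is exhaustive over all edge subsets with canonicalization by
minimum adjacency encoding over node permutations, and is verified in the
tests against an independent brute-force orbit counter.

### Matching, scoring, null model

Matching uses **induced** semantics: a set of k nodes is an instance of a
pattern exactly when its induced configuration equals the pattern. Induced
matching makes the 7 two-node classes a partition of all connected two-node
configurations, so every pair of interacting cell types belongs to exactly
one class. Each distinct node set counts once (automorphic remappings
deduplicated); because automorphism counts differ between classes, the raw
mapping count is also reported (`n_mappings = n_instances ×
n_automorphisms`) for comparison with tools that count mappings.

The per-instance statistic is the mean weight of the mapped edges; the
class score sums these means. Scores are compared against
degree-preserving randomized networks: repeated double-edge swaps
`(a→b, c→d) → (a→d, c→b)` with 10 swap attempts per edge per sample,
rejecting swaps that would duplicate an edge; self-loops may appear and
disappear, but every node's in- and out-degree is preserved exactly, and
the weight multiset is randomly permuted over the rewired edges. The
z-score `(S − mean₀)/sd₀` is one-sided: enrichment only, significant when
`z > 1.65` strictly (nominal 5%); depletion is not flagged. Degenerate
nulls (networks admitting no rewiring) give `z = 0` rather than an error.
On unstructured random networks the realized false-positive rate of this
procedure is close to the nominal 5% (a tested property), and a two-cell
mutual-plus-loops circuit planted at 10× weight enrichment is detected with
high power.

Swap count and convergence of the original rewiring routine are not
published; 10 × edge-count attempts is the package's choice, large enough
that successive samples decorrelate on networks of the sizes in play
(tens of edges).

## 3. The fibroblast–macrophage growth circuit

### Model

Each population `X ∈ {F, M}` changes by a balance of proliferation and
removal, `dX/dt = (p_X − r_X) X`. Growth-factor exchange is fast compared
with cell turnover, so the factor concentrations are collapsed at
quasi-steady state into effective autocrine/paracrine coefficients, and
proliferation saturates at a carrying capacity on the log scale:

$$\frac{dF}{dt} = F\left[(p_{FF} f(F) + p_{MF} f(M))\left(1 -
\frac{f(F)}{K_F}\right) - r_F\right],$$

and symmetrically for `M`, with `f(X) = log(X + 1)`. The log transform
expresses diminishing returns of large populations and behaves like a
saturating interaction without spending an extra halfway-point parameter
per term (a Michaelis–Menten variant would); the `+1` keeps zero counts
representable. Carrying capacities are therefore in log cell numbers.

The individual growth-factor rates (secretion, degradation, sensitivity)
exist only inside the composite `p` coefficients; they are not separately
identifiable from count data and have no representation in the package.

### Discrete day-3 → day-7 map

Approximating the logarithmic derivative over the experimental interval
`Δt` (4 days) gives the one-step map

$$\log(X_7+1) = \Delta t\left[(p_{XX} f(X_3) + p_{YX} f(Y_3))\left(1 -
\frac{f(X_3)}{K_X}\right) - r_X\right] + \log(X_3+1).$$

The package uses `log(X + 1)` *uniformly*, including in the trailing
terms, so that zero seedings are first-class data; inverted predictions
are clamped at zero counts. Relative to a formulation mixing `log X` and
`log(X+1)` this deviates by at most one count unit and removes the
singularity at empty wells. A map prediction that inverts below zero is
reported as zero — an absorbing state, matching the continuous model where
`X = 0` implies `dX/dt = 0`.

One visible consequence: starting from `X₃ = 0`, the map can predict a
positive `X₇` when the paracrine input exceeds removal. This reflects the
map acting on `f`-space rather than a claim about spontaneous generation,
and disappears in continuous mode.

### Numerics

Continuous trajectories use `deSolve::ode` (lsoda) at `rtol 1e-8`,
`atol 1e-10`, with the right-hand side clamped so non-negative states stay
non-negative and sub-`1e-6`-cell outputs snapped to zero. When lsoda cannot
hold `1e-10` near the absorbing zero state it falls back to `atol 1e-8`
and then to an explicit Runge–Kutta method; an integration that still
fails raises an error with the offending initial condition. Note one model
property: with a *negative* autocrine coefficient and a state beyond
capacity (`f > K`), the logistic factor flips sign and the model grows
without bound — that is a feature of the equations, not a solver defect.

### Collapse threshold

On the fibroblast axis the per-capita growth `p_FF f (1 − f/K_F) − r_F` is
a downward parabola in `f`, maximized at `f = K_F/2` with maximum
`p_FF K_F/4 − r_F`. The population therefore collapses from *every*
initial state exactly when `p_FF < 4 r_F / K_F`.
`autocrine_collapse_threshold()` returns the bound; the tests and the
acceptance script verify the constant 4 by independent numerical
maximization/root-finding and corroborate it dynamically at 0.99× and
1.01× the bound.

## 4. Phase portraits

Fixed points come from three sources: the origin (always); axis points as
closed-form roots of the on-axis quadratic; interior points by sign-change
scanning of both per-capita rates on an 80×80 grid in `f`-space followed by
Newton refinement with the analytic gradient, duplicates merged. The
search domain is `f ∈ [0, 1.5·max(K)]` per axis — beyond `f = K`
proliferation is non-positive, so no fixed points live far above capacity.
Every reported point satisfies a residual below `1e-9` counts/day (tested).

Stability uses the *analytic* Jacobian in count space. At an axis point the
Jacobian is triangular, so the within-axis and transverse eigenvalues are
its diagonal — exact even for the boundary case `r_M = 0`. Classification
(real-part tolerance `1e-8`):

* all eigenvalue real parts negative → **stable**, labeled by position:
  `OFF` (origin), `ON` (interior), `ON_OFF` (fibroblast axis), `OFF_ON`
  (macrophage axis);
* on an axis, attracting within the axis but neutral or repelling
  transverse → **`SEMI_STABLE`** (the operational meaning of a state that
  arrows approach along one axis and leave along the other);
* otherwise **`UNSTABLE`**.

Because a semi-stable fibroblast-only state is still scientifically an
"ON-OFF" state, every fixed-point row also carries a `position` field
(`off`/`on`/`on_off`/`off_on`) alongside `class`, so downstream code can
ask "is there an ON-OFF point?" independently of its stability.

Nullclines are zero-level contours of the per-capita rates
(`grDevices::contourLines`) plus the coordinate axes; their accuracy is the
grid's linear-interpolation error, which is why cross-checks use a
`1e-3` tolerance at default resolutions. The growth-rate heatmaps change
sign exactly on the nullclines, and basins of attraction are computed by
forward integration of a grid of seedings (default horizon 200 days),
labeling each cell by the attracting (stable or semi-stable) point nearest
in `f`-space to the trajectory endpoint, `UNKNOWN` if none is within 0.5
`f`-units.

## 5. Inference

Each population's equation has disjoint parameters and residuals, so the
two are fitted independently — the map's structure decouples them. The
objective is the summed squared residual of observed vs. predicted
`log(X₇+1)`, with the prediction floored at zero exactly as the map clamps
counts (so observed clamped zeros are consistent, not outliers). The
optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
`r ≥ 0`, `K ≥ 1e-3` and `p` unbounded — negative `p` reads as inhibition.
Because the optimizer is local, each equation starts from five
deterministic guesses (`p` pairs in {0, 0.5}² plus (0.25, 0.25);
`r = 0.1`; `K` = max observed `f` + 1) and keeps the best objective.

Datasets need at least 8 arrows, including 4 with each population seeded;
anything less is refused as underdetermined rather than silently fitted.

**Bootstrap.** Arrows are resampled with replacement (default 5000 draws),
each draw refitted starting from the point estimate (a local perturbation
of a converged optimum; the full multi-start is spent on the original
data). Summaries are the per-parameter median, interquartile range and
percentile 95% interval. Draws where the optimizer fails are excluded when
they are fewer than 1% of the total and an error otherwise — rare failures
must not silently bias summaries.

**Contrasts.** Draws of two conditions are paired by index; the two-sided
p-value of a parameter difference is twice the smaller tail fraction of
zero in the difference distribution, floored at `2/n_boot` (a resolution
limit, not a claim of exactness) and capped at 1.

**Fit quality.** Variance explained is `1 − SS_res/SS_tot` of the log
counts, per cell type (undefined — `NA` — when the outcomes are constant,
never 1). The direction error rate is the fraction of arrows whose
predicted log-change sign disagrees with the observed one; zero observed
change always counts as matched. Whether such quantities should be pooled
across cell types is a reporting choice; the package reports per-cell-type
R² and a pooled direction error.

## 6. Synthetic data: what it emulates, what it does not

`generate_arrows()` emulates the co-culture phase-portrait design: seeding
counts on a log-spaced grid (default 6 interior levels from 10 to 1e5
cells, echoing the 0–1e5 experimental seeding range) plus the two axes
(each population alone, including the empty well), day-7 counts from the
discrete map (or the ODE in continuous mode) times multiplicative
lognormal noise with mean 1 and CV `noise_cv`. Multiplicative noise is the
package's choice — cell-counting error scales with abundance — and the
default CV of 0.1 is a stand-in: the real measurement error magnitude is
not reported anywhere usable. Everything is deterministic given a seed.

What passing tests on these data show: the estimator recovers the
generating circuit exactly without noise, degrades gracefully with noise,
and its bootstrap intervals cover the truth at close to nominal rates
*when the model generating the data is the model being fitted* (or its
continuous counterpart, for the structure-level checks). What they cannot
show: robustness to real-world misspecification — settling transients
between day 0 and day 3 (day 3 is simply the initial condition, as in the
experimental design), density-dependent death, well-edge effects, or
counting bias at very low counts.

`generate_random_network()` provides Erdős–Rényi-style weighted digraphs
(independent edges at probability `p_edge`, self-loops included; lognormal
weights) with an optional planted two-cell circuit at a weight multiplier,
used to measure the census's false-positive rate and detection power.

### Preset regimes

The fitted parameter values behind the published portraits live in
supplementary material that is not reprinted here, so the presets are the
package's own, chosen once to satisfy the stated qualitative structure and
pinned:

| parameter | control | cancer_cm | meaning |
|---|---|---|---|
| `p_FF` | 0.6 | 0.6 | strong fibroblast autocrine loop (≫ 4·r_F/K_F) |
| `p_MF` | 0.05 | 0 | weak / absent macrophage→fibroblast feedback |
| `p_FM` | 0.3 | 0.1 | strong / reduced fibroblast support of macrophages |
| `p_MM` | 0.02 | 0.4 | very weak / raised macrophage self-sufficiency |
| `r_F` | 0.3 | 0.3 | fibroblast removal (per day) |
| `r_M` | 0.8 | 0 | macrophage removal; zero in cancer CM (enhanced survival) |
| `K_F` | 9 | 9 | fibroblast capacity (log-counts, ≈ 8100 cells) |
| `K_M` | 9 + ln 10 | 9 + ln 10 | ≈ 10-fold higher macrophage count capacity |

The control regime yields a stable OFF, a stable ON, an unstable seeding
threshold on the F-axis and a semi-stable ON-OFF state (fibroblasts alone
persist; macrophages invade when added — consistent with macrophages being
unable to grow alone in control medium, since
`p_MM · K_M/4 ≈ 0.06 ≪ r_M`). The cancer regime makes the origin
semi-stable (neutral along the macrophage axis) and adds a stable OFF-ON
state at `f_M = K_M`: macrophages no longer need fibroblasts. Removal
rates near 1/day for unsupported macrophages and ~0.3/day for fibroblasts
are in the range of in-vitro turnover for these cell types; they were set
from those considerations, not adjusted against test outcomes.

## 7. Problem sizes and reproducibility

The shipped test-suite and acceptance-script sizes are chosen to exercise
the statistics at meaningful scale while staying comfortably interactive:
null censuses use 150–500 rewired networks in tests (the API default is
10 000), bootstraps 50–1000 draws (default 5000), the coverage study 40
replicates at 500 draws, recovery studies 20 seeds, and basin grids 9–21
cells per axis. All stochastic steps take explicit seeds; pipeline JSON
reports embed their full resolved configuration, so any report is
reproducible from its own metadata.

## 8. Known limitations

* Two populations only; three-cell portraits and higher are out of scope.
* The census is weight-score based; an unweighted frequency census is not
  provided (`n_instances` is reported, but significance is always on the
  weighted score).
* `K` is unidentifiable when the corresponding `p` coefficients are ~0
  (it only appears multiplied by them); the bootstrap makes this visible
  as wide intervals rather than refusing to fit.
* The contrast p-value floor `2/n_boot` means very small p-values require
  proportionally many bootstrap draws.
* Basin labeling is by endpoint proximity at a finite horizon; extremely
  slow transients (eigenvalues near zero, as in the cancer regime's
  neutral direction) can label cells `UNKNOWN` at short horizons.
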