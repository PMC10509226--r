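# cellcircuit

Tools for dissecting cell–cell interaction circuits of the tumor
microenvironment (TME). The package addresses two connected questions that
arise when ligand–receptor scoring of single-cell data (e.g. CellChat
output) meets co-culture growth experiments:

1. **Which circuit patterns dominate the cell-interaction network?**
   Starting from a cell-type × cell-type interaction-strength matrix, the
   package builds a weighted directed network (self-loops = autocrine
   signaling), prunes weak interactions, enumerates all two-, three- and
   four-cell circuit patterns, and scores each pattern class against
   degree-preserving randomized networks.
2. **What growth circuit explains paired co-culture counts?** For the
   two-cell fibroblast–macrophage circuit, the package models, simulates,
   fits and compares a minimal population-dynamics model from day-3 → day-7
   cell counts ("arrows" in the phase plane).

It is aimed at systems-biology practitioners who have an interaction matrix
and/or paired count data and want motif statistics, inferred growth
circuits, phase portraits and condition contrasts in a few lines of
pipeable R.

## The models

**Motif census.** Edges sorted by ascending weight are removed while their
cumulative weight stays within 10% of the network total. For a pattern
class `P` with induced instances `I`, the class score is
`S(P) = Σ_I mean(w_e : e ∈ I)`. Significance is the one-sided z-score of
`S(P)` against its distribution over networks rewired by double-edge swaps
(in- and out-degrees preserved exactly, self-loops allowed, weights
permuted); classes with `z > 1.65` are reported as enriched.

**Growth circuit.** Fibroblast (F) and macrophage (M) counts follow

    dF/dt = F [ (p_FF f(F) + p_MF f(M)) (1 − f(F)/K_F) − r_F ]
    dM/dt = M [ (p_FM f(F) + p_MM f(M)) (1 − f(M)/K_M) − r_M ]

with `f(X) = log(X + 1)`. The `p` coefficients are effective autocrine and
paracrine proliferation rates (growth-factor exchange collapsed at
quasi-steady state), `r` are removal rates and `K` carrying capacities in
log-count units. Over an experimental interval `Δt` the model reduces to a
discrete map on the log scale,

    log(X₇+1) = Δt [ (p_XX f(X₃) + p_YX f(Y₃)) (1 − f(X₃)/K_X) − r_X ] + log(X₃+1),

which is fitted to arrow datasets by bounded nonlinear least squares
(`r ≥ 0`, `K > 0`, `p` free), with bootstrap uncertainty and
between-condition contrasts. The fibroblast-only circuit collapses from
every initial state exactly when `p_FF < 4 r_F / K_F`.

## Worked example

Motif census of a small synthetic TME interaction matrix (shipped with the
package; labeled synthetic — it is not a measured matrix):

```r
library(cellcircuit)

f <- system.file("extdata", "synthetic_tme_matrix.csv", package = "cellcircuit")
net <- read_interaction_matrix(f) |> build_cell_network(weak_fraction = 0.10)
node_strengths(net)
#> # A tibble: 6 × 4
#>   node   out_strength in_strength is_root
#> 1 CAF            30.5        18.8 TRUE
#> 2 Cancer         20.6        13.3 FALSE
#> 3 TAM            12.6        19.7 FALSE
#> 4 Tcell           2.4         7.3 FALSE
#> 5 EC              2.2         7.7 FALSE
#> 6 Bcell           1.1         2.6 FALSE
```

The cancer-associated fibroblast (CAF) is the root of the hierarchy — the
strongest sender — while the tumor-associated macrophage (TAM) is the main
receiver. Scoring all two- and three-cell patterns against 2000 rewired
networks:

```r
enr <- motif_significance(net, k = c(2, 3), n_random = 2000, seed = 42)
dplyr::filter(tidy(enr), significant)
#>       k pattern_id n_instances score     z
#> 1     3 k3_13                2  9.03  1.78
```

Here the fully reciprocal three-cell circuit (pattern `k3_13`; its two
instances in this matrix are CAF–TAM–Cancer and CAF–TAM–EC) is the only
class scoring above the rewired null.

Inferring a circuit from synthetic day-3 → day-7 arrows generated by the
documented `control` regime (noise CV 0.1) and bootstrapping:

```r
arrows <- generate_arrows(preset_params("control"), noise_cv = 0.1, seed = 7)
fit <- bootstrap_fit(arrows, n_boot = 1000, seed = 7)
tidy(fit)
#>   parameter estimate  median conf_low conf_high
#> 1 p_FF        0.603   0.603    0.595     0.610
#> 2 p_MF        0.0500  0.0500   0.0451    0.0537
#> 3 p_FM        0.301   0.301    0.300     0.303
#> 4 p_MM        0.0176  0.0174   0.0119    0.0230
#> 5 r_F         0.310   0.311    0.269     0.344
#> 6 r_M         0.797   0.797    0.782     0.809
#> 7 K_F         9.03    9.03     8.96      9.09
#> 8 K_M        11.3    11.3     11.2      11.4
glance(fit)
#>    r2_F  r2_M direction_error_rate n_arrows delta_t n_boot
#> 1 0.999 0.999                    0       49       4   1000
```

All eight generating parameters are recovered inside their 95% intervals,
with > 99% of the variance in the log counts explained. The phase portrait
of the point estimate shows the bistable structure of the control circuit:

```r
phase_portrait(fit$params, basins = FALSE)$fixed_points
#>            F        M position   stability       class
#> 1       0.00    0.000      off      stable         OFF
#> 2       0.73    0.000   on_off    unstable    UNSTABLE
#> 3    4816.35    0.000   on_off semi_stable SEMI_STABLE
#> 4    5022.63 2864.116       on      stable          ON
```

A stable OFF state, a stable ON state where both populations coexist, an
unstable seeding threshold on the fibroblast axis, and a semi-stable
fibroblast-only (ON-OFF) state that attracts along the axis but is invaded
by macrophages. `autoplot()` methods draw the census, the portrait (with
basins) and the bootstrap forest plot; `run_motif_pipeline()` /
`run_circuit_pipeline()` chain the steps and write JSON/CSV reports.

## Package layout

- `R/interaction-network.R` — matrix I/O, weak-edge pruning, node strengths
- `R/motif-patterns.R`, `R/motif-analysis.R` — pattern enumeration,
  induced-subgraph census, rewiring null, z-scores
- `R/circuit-model.R`, `R/phase-portrait.R` — ODE/discrete dynamics, fixed
  points, nullclines, basins, collapse threshold
- `R/inference.R` — bounded least-squares fitting, bootstrap, contrasts
- `R/synthetic-data.R` — arrow and random-network generators, presets
- `R/pipeline.R`, `R/plots.R` — orchestration and ggplot2 output
- `vignettes/cell-circuits.Rmd` — methods and design notes
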