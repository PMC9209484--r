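# fvscreen

Feedback vertex set control screening on signed biological networks.

## The problem

Reprogramming a cell fate — turning a therapy-resistant tumour cell
sensitive, or a primed stem cell naive — requires knowing *which* genes to
override and *in which direction*, given only a static signed regulatory
network and expression snapshots of the source ("undesired") and target
("desired") phenotypes. Feedback vertex set (FVS) control theory says
*where* to intervene: a set of nodes whose removal leaves the directed
graph acyclic is, for a broad class of nonlinear dynamics with only
positive self-regulation and first-argument decay, a set of determining
nodes — permanently overriding their states steers the whole system into
any of its natural attractors. It does not say *how* to set them. This
package closes that gap in silico: it estimates the network's attractor
landscape, screens every override combination on the FVS control nodes,
and filters the outcomes down to the combinations that move the system
into the desired phenotype's basin.

`fvscreen` is aimed at systems biologists with a curated signed network
(activation/inhibition edge lists), normalized expression for two or more
phenotypes, and a handful of literature-backed marker genes.

## The method

**Attractors by signal flow analysis (SFA).** Node activities (log scale)
are propagated synchronously,

```
x_i(t+1) = α Σ_j W_ij x_j(t) + (1 − α) b_i ,   W_ij = sign(ij) / √(D_out(j) · D_in(i))
```

where `b_i` is the node's initial activity, `sign(ij)` is ±1 for
activation/inhibition, and `α = 0.9` weighs network topology against the
initial state. Iteration stops when `max_i |x_i(t+1) − x_i(t)| < 10⁻⁶`,
giving one fixed-point attractor per initial state. Overridden nodes are
pinned at a fixed value `p_i` throughout (they still feed their value to
their targets).

**Landscape and phenotypes.** One attractor per experimental sample plus
100,000 (by default) attractors from random initial states drawn uniformly
within each node's observed expression range. The attractors are
partitioned by k-means; `k` is chosen by the elbow (maximum curvature of
the within-cluster sum of squares) and mean-silhouette optima, falling
back to the smallest candidate that puts the undesired- and desired-sample
attractors in disjoint clusters. Internal-marker nodes are checked for the
expected desired-vs-undesired direction and for replicate-range overlap.

**Control nodes and the screen.** Minimal FVSes are found by an SA-FVSP
simulated-annealing local search (exact enumeration doubles as the oracle
on small networks); nodes already fixed by mutations (gain/loss of
function) are excluded. All `3^n` schemes over the `n` control nodes —
each node overexpressed (`p = 3.5·max(normexp)`), knocked out
(`p = −1.5·min(normexp)`), or left unchanged — are simulated from each
undesired replicate's expression profile.

**Two filters.** Criterion 1: Naive Bayes, a linear SVM, and a Random
Forest are trained on the clustered landscape; a scheme passes when at
least 2 of 3 classifiers assign its attractor to the desired cluster, on
every replicate (top-10% feature importances are reported per
classifier). Criterion 2: at least 90% of the marker nodes must move past
the desired phenotype's attractor-value boundary in the expected direction
(strict mode) or past the undesired value (relaxed mode), per marker group
independently. Survivors are ranked smallest-intervention-first.

## Worked example

The built-in 12-node fixture plants a 3-cycle `A → B → C → A` whose node
`A` activates three marker genes; the desired phenotype has `A` and the
markers high.

```r
library(fvscreen)
fx <- standard_fixture(seed = 1)
fx$g
#> signed_digraph: 12 nodes, 12 edges ( 11 activating / 1 inhibiting )

enumerate_fvs(fx$g)$fvs
#> three singleton FVSes: {A}, {B}, {C}

res <- screen_and_filter(fx$g, fx$expr, fx$markers, control = "A",
                         n_random = 1000, seed = 1)
res$model
#> cluster_model: k = 2 ( elbow 4 , silhouette 2 )
#>    metrics disagree (elbow k=4, silhouette k=2); smallest candidate
#>    separating the phenotypes
res$clfs
#> attractor_classifiers on 12 features, 2 clusters; training accuracy:
#> naive_bayes=0.934, svm=0.986, random_forest=1.000
res$report
#> filter_report: 3 schemes -> 1 passed criterion 1 -> 1 passed both
#>   best (fewest perturbations): A:up
```

The screen tries the three schemes on `A` (unchanged / up / down) from
each of the three undesired replicates. Only overexpressing `A`
(`A:up`, pinned at `3.5 × max(undesired A) ≈ 1.86`) survives both
filters: its attractor raises every marker to ≈ 0.88, past the desired
attractors' marker values (≈ 0.42), while the unchanged scheme stays at
the undesired attractor (markers ≈ 0.11) and is rejected by the
classifier vote.

The same stages run file-to-file with checkpoints via `run_pipeline()`
(see `?run_config`), or from a shell through the thin front end
`inst/cli/fvscreen.R`.

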