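---
title: "Methods: attractor estimation, FVS control screening, and filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attractor estimation, FVS control screening, and filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvscreen)
```

This vignette documents the model behind `fvscreen`, its assumptions, the
tunable parameters and their defaults, the numerical decisions made where
the design was open, and the limits of what the synthetic fixtures can
demonstrate.

## The model

### Signal flow analysis

The package treats a signed directed network as a linear signal-routing
substrate. For node $i$ with incoming edges from nodes $j$, the (log-scale)
activity is iterated synchronously:

$$x_i(t+1) = \alpha \sum_j W_{ij}\, x_j(t) + (1-\alpha)\, b_i,
\qquad
W_{ij} = \frac{\mathrm{sign}(ij)}{\sqrt{D_{\mathrm{out}}(j)\, D_{\mathrm{in}}(i)}}$$

with $b_i$ the node's initial activity and $\mathrm{sign}(ij) = \pm 1$ for
activation/inhibition. The degree normalization damps hubs on both ends of
an edge; self-loops count in both degrees of the looping node. Because the
update is affine, a converged state is (up to the stopping tolerance) the
solution of $(I - \alpha W)x = (1-\alpha) b$ — the test suite exploits this
as an independent oracle, comparing the iterated fixed point against the
direct linear solve on random networks, both free-running and with pinned
rows.

**Assumptions.** Inputs are taken to be already normalized, log-scale
values and are never re-logged (the in-silico 0/1 initial states used for
networks without expression data enter the same way). The dynamics are a
linear surrogate of the true regulatory kinetics: differences between two
attractors are read like a log fold-change — the *sign* is meaningful, the
magnitude is not quantitative.

**Overrides.** A permanently perturbed node is pinned at a fixed value
$p_i$ at every iteration; it ignores incoming flow but still feeds $p_i$
to its targets. Overexpression and knockout values come from the node's
expression across the undesired-phenotype samples,
$p^{\mathrm{up}} = 3.5 \cdot \max(\mathit{normexp})$ and
$p^{\mathrm{down}} = -1.5 \cdot \min(\mathit{normexp})$, or $\pm 2.5$ when
no expression data exist. Note the knockout formula yields a value *above*
the observed minimum whenever $\min(\mathit{normexp}) < 0$, which can
happen on log-scale data; the formula is applied verbatim and a warning is
emitted rather than silently substituting something else.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.9 | — | weight of network vs initial state; 0.9 favours topology |
| `tolerance` | 1e-6 | log-activity | max-norm stopping threshold |
| `max_iterations` | 1000 | iterations | hard cap; non-convergence is flagged, never silent |
| `n_random` | 100000 | states | random landscape initial states |
| `k_range` | 2–10 | clusters | candidate k for k-means |
| `threshold` | 0.9 | fraction | criterion-2 passing-marker fraction |
| comparison guard | 1e-9 | log-activity | \|difference\| below this is "unchanged" |

The convergence criterion uses the max (infinity) norm — the strictest
elementwise choice and the natural reading of a fixed-point stopping rule.
The initial iterate is $b$ with overrides applied. The $10^{-9}$ equality
guard exists because any nonzero signed difference is otherwise called
up/down, which would amplify float noise into spurious calls.

### Landscape estimation and clustering

One attractor is computed per experimental sample, plus `n_random`
attractors from initial states drawn *uniformly* within each node's
observed `[min, max]` expression range. The sampling distribution within
the range is a package decision (recorded in the k-selection report);
pooling the ranges across all supplied phenotypes is the default, with a
stratified per-phenotype mode behind a flag. Non-converged states are
excluded from clustering, with a warning and an exact count, so attractor
bookkeeping always balances.

k-means runs with 10 seeded random starts per candidate $k$. Two optima
are computed: the elbow of the WCSS curve, estimated as the maximum
discrete curvature (second difference — the elbow method itself names no
estimator), and the maximum mean silhouette width. Mean silhouette needs
pairwise distances, which are quadratic in landscape size, so it is
evaluated on a seeded subsample capped at 5,000 attractors (experimental
attractors always included). When the metrics agree and that $k$ separates
the undesired- and desired-sample attractors into disjoint clusters it is
chosen; otherwise the smallest candidate that separates them is taken, and
if none does the run stops with an error advising revision of the network,
markers, or settings — a $k$ that co-clusters the two phenotypes is never
returned.

### FVS search

Minimal feedback vertex sets are found with an SA-FVSP simulated-annealing
local search: the state is the complement — an acyclic induced subgraph
held in topological order — and a move inserts an outside node immediately
after its last in-neighbour or before its first out-neighbour, evicting
order-violating neighbours, with Metropolis acceptance. Defaults: initial
temperature 0.6, geometric cooling ×0.99, $50\,|V|$ moves per level, stop
after 50 stagnant levels; all seeded. The inner loop is compiled (Rcpp)
and uses R's RNG, so runs are reproducible under `set.seed()`.

Decisions worth recording:

* **Self-loops are cycles of length 1** and force their node into every
  FVS; such nodes are flagged in the result (`self_loop_members`). The FVS
  control guarantee assumes self-regulation is positive; the package does
  not verify the sign, it reports the membership.
* **"Minimal" means inclusion-minimal** after a deterministic greedy
  pruning pass in node order; minimum *size* is certified only against the
  brute-force oracle (exact subset enumeration, guarded at ≤ 20 nodes).
* **Enumeration** of distinct minimal FVSes is exact for small graphs
  (≤ 12 nodes by default) and otherwise collects distinct minimum-size
  results over randomized SA restarts until 25 consecutive restarts add
  nothing new. Saturation is a stopping heuristic, not a completeness
  certificate, and is documented as such in the output (`method` field).

### The screen and the filters

Schemes are ternary assignments over the control nodes, generated as a
deterministic ternary counter in node order (all-unchanged first), `3^n`
in total, with a refusal cap at 16 control nodes (≈ 43M schemes) unless
explicitly overridden. Override values are computed once from the pooled
undesired-phenotype extrema and shared across replicates; mutation
(gain/loss of function) and treatment overrides are applied to every
scheme, and mutation-fixed nodes are removed from the control set before
scheme generation, mirroring how an already-knocked-out gene cannot be
independently perturbed.

Criterion 1 trains Naive Bayes, a linear-kernel SVM, and a Random Forest
(500 trees) on the full attractor vectors with their cluster labels —
library defaults otherwise, fixed seeds, full-fit with training accuracy
reported (no held-out split: the filter is a lookup against the landscape
partition, not a generalization claim). A scheme passes when ≥ 2 of 3
classifiers put its attractor in a desired cluster, on every replicate.
Feature importance uses each model's native notion where one exists
(Gini decrease for the forest, aggregate |w| of the primal weights for the
linear SVM — the linear kernel is chosen precisely so this is well
defined) and seeded permutation importance (10 repeats) for Naive Bayes,
which has no native ranking; the top ⌈10%⌉ per classifier is reported with
an overlap summary.

Criterion 2 checks each marker's attractor value against phenotype
ranges. With replicates, the desired range is `[min, max]` over the
desired-sample attractor values; **strict** mode requires the value beyond
the desired-range boundary facing the undesired side (above `min(desired)`
for up-markers, below `max(desired)` for down-markers), generalizing the
single-value rule "must exceed the desired value"; **relaxed** mode only
requires moving past the undesired values. A scheme passes a replicate
when the passing fraction is ≥ `threshold` within every marker group
independently; the overall verdict requires all replicates, and
per-replicate lists are also emitted. Markers whose direction cannot be
resolved (desired = undesired, no literature direction) are excluded from
the denominator with a warning — keeping them would silently deflate every
scheme's fraction. Markers that are also control nodes are evaluated at
their override value and flagged. The criteria are deterministic filters,
not hypothesis tests, so no multiple-testing control applies.

## Synthetic fixtures

`make_network()` plants vertex-disjoint directed cycles (the only cycles,
by construction: scaffold edges run strictly forward in the node order and
never enter a cycle block), so the minimum FVS size equals the number of
planted cycles — certified against the brute-force oracle at build time
for ≤ 15 nodes. `make_expression()` separates designated markers between
phenotypes by an effect size of 2 log units with replicate jitter of 0.05
log units (small against the effect so marker checks are unambiguous);
baselines are uniform in [0.5, 1.5], a realistic span for normalized
log-scale expression. `standard_fixture()` is the hand-built 12-node
end-to-end case: a 3-cycle whose member `A` activates three markers, with
both `A` and the markers high in the desired phenotype — so `A:up` is a
provably recoverable reprogramming scheme and the all-unchanged scheme a
guaranteed negative control. `inject_noise()` reproduces the robustness
protocol of adding Gaussian noise with an *absolute* standard deviation of
0.01–0.50 to every nonzero initial value (the levels are stated against
unit-scale concentrations, so the SD is treated as absolute, not
relative).

**What passing fixtures does and does not show.** The fixtures have
linear-friendly dynamics, well-separated phenotypes, and markers directly
downstream of the control node; real networks have unknown kinetics,
overlapping expression ranges, and markers many hops from any FVS node.
Green fixtures demonstrate that the machinery — propagation, search,
screening, filtering, checkpointing — is correct and reproducible, not
that SFA's linear surrogate is faithful to any particular biological
system. The published full-scale case studies are encoded as gated
external validations (`external_validations()`) and run only when their
externally distributed inputs are supplied.

## Problem sizes used by the tests and the acceptance script

Property tests run at the sizes where their oracles are exact: random
graphs of ≤ 30 nodes for the SFA/linear-solve equivalence (100 seeded
graphs), ≤ 12 nodes for SA-vs-brute-force FVS agreement (200 seeded
graphs), and the 12-node standard fixture (with 400–1,000 random landscape
states and 150–200 forest trees) for end-to-end recovery across 20 seeds —
sizes at which the full pipeline is exercised thousands of times while the
suite stays fast. The landscape-size check runs at full scale (100,006
attractors on a 36-node fixture), where batched propagation takes a few
seconds. The noise-robustness harness re-runs the entire pipeline per
trial (landscape, clustering, classifiers, screen, filters) at 300 random
states per trial.

## Known limitations

* Only fixed-point attractors: a limit cycle would simply fail the
  tolerance and be flagged non-converged.
* Synchronous, deterministic updates; no asynchronous or stochastic
  schemes, and no transient (initial-state-only) perturbations — the FVS
  control guarantee is for permanent overrides.
* Landscape basins are degenerate (one attractor per initial state), so
  phenotype association leans entirely on clustering.
* Edge-deletion perturbations are out of scope by design: node-state
  overrides preserve the network's FVS, edge edits do not.
* `enumerate_fvs()` on large graphs is complete only up to the saturation
  heuristic.
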