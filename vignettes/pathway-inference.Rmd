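---
title: "Inferring and ranking gene regulatory pathways as a shortest-path problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and ranking gene regulatory pathways as a shortest-path problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmi)
```

## The problem

Whole-network inference from expression data produces "hairballs" that are
hard to act on. A more interpretable unit is a *linear pathway*: the chain of
direct regulatory interactions connecting two genes of interest. `pathmi`
infers such pathways directly, rather than extracting them from an inferred
network, and attaches to each pathway a probability that can be used to
prioritise interactions for laboratory validation.

## The model

Dependence between expression profiles is measured by mutual information
(MI), which captures nonlinear relationships and makes no distributional
assumptions. MI alone cannot separate direct regulation from co-expression;
that separation comes from the **data processing inequality (DPI)**: if gene
A influences gene C only through gene B, then

$$I(A;C) \le \min\{I(A;B),\, I(B;C)\}.$$

In a biological context the inequality can be taken to be strict, and with
exact MI values DPI pruning recovers an acyclic dependency graph perfectly
(the package verifies this on a Gaussian tree model with closed-form MI,
where the correlation of a pair is the product of edge correlations along
the tree path and $I = -\tfrac12\log(1-\rho^2)$).

An edge $(A,B)$ is called **direct** when it is not the strictly least edge
in any triplet comparison with a third gene $C$. Because estimated MI is
noisy, directness is treated probabilistically:

1. Draw $B$ bootstrap resamples of the samples (columns), jointly across
   genes.
2. On each resample, estimate the full MI matrix and classify every edge by
   the DPI.
3. The **probability of directness** of an edge is the proportion of rounds
   in which it is direct, Laplace-smoothed to $(c+1)/(B+2)$.

A path is correct when *all* of its edges are direct. Assuming edges are
independent, the probability of a path $p$ with edge set $e_p$ is
$\prod_{AB \in e_p} P(\mathrm{direct}(AB))$, and

$$\arg\max_p \prod_{AB \in e_p} P(\mathrm{direct}(AB))
  \;=\; \arg\min_p \sum_{AB \in e_p} -\log P(\mathrm{direct}(AB)),$$

so the most probable all-direct path is the shortest path under
negative-log-probability weights — nonnegative, hence searchable with
Dijkstra's algorithm. The test suite verifies this order equivalence against
exhaustive path enumeration on random complete graphs.

The ranking across gene pairs simply sorts each pair's best path by its
joint probability (`rank_paths()`).

## Tunable parameters

* **MI estimator** (`mi_config()`): plug-in estimate on binned data.
  Equal-frequency (quantile) binning by default — invariant to monotone
  transforms of the expression scale — with `floor(sqrt(n))` bins clamped to
  `[2, n]`; equal-width binning is available. Natural log (nats); only the
  MI ordering matters for the DPI, but the base must be fixed. No bias
  correction is applied: the DPI compares three estimates that share the
  estimator, so a common bias largely cancels, and the uncorrected plug-in
  keeps the closed-form test oracles exact. Ties at quantile boundaries are
  broken by stable sample-index order, making every estimate deterministic.
* **Bootstrap rounds** (`n_boot`, default 100): the resolution of the
  probability estimates is $1/B$; 100 rounds resolve differences of one
  percentage point at modest cost.
* **Smoothing and floor**: Laplace smoothing keeps probabilities strictly
  inside $(0,1)$; a raw 0 would map to an infinite weight and silently
  delete the edge. The search graph stays *complete* — improbable edges get
  large finite weights (hard pruning is the comparison methods' job) — and a
  probability floor of $1/(10B)$ caps the dynamic range of the weights.
* **Tie rules**: DPI pruning requires strict inequality (an edge tied with
  the triplet minimum survives); Dijkstra and Prim break ties towards the
  lexicographically smallest label so all outputs are reproducible.
* **Hop cap** (`max_edges`, off by default): a biological-plausibility limit
  on path length. Dijkstra does not respect a hop cap natively, so when set
  the search switches to a layered bounded relaxation.
* **ARACNe comparator** (`aracne_config()`): significance threshold from a
  permutation null (each profile of a random gene pair permuted
  independently), default `alpha = 0.30` (permissive), and a *relative* DPI
  tolerance margin (prune when $I(A,B) < (1-\tau)\min(\cdot)$), default
  $\tau = 0$ (stringent) — the tuning that favours path extraction. The
  relative form is scale-free in the MI units.
* **MST comparator** (`mst_network()`): Prim's algorithm on MI scaled by the
  dataset maximum and subtracted from one, or on $-\log(I/I_{max})$. Both
  transforms are strictly decreasing in MI, so they yield the same tree
  whenever all MI values are positive — a property the suite checks on random
  matrices. Both comparators optionally run on the mean (or median) of
  bootstrap MI estimates for robustness.

## The synthetic benchmark

`sim_config()` / `generate_network()` / `simulate_expression()` generate
ground-truth networks (chains, random trees, trees plus cycle-closing back
edges at a controllable rate) and expression data from them. Per sample,
source genes are standard normal and each regulated gene responds to the
mean of its parents through a bounded sigmoid with additive Gaussian noise:

$$x_g = \tanh\!\big(k \cdot \overline{x}_{\mathrm{pa}(g)}\big) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2).$$

Defaults are $k = 1.5$ and $\sigma = 0.5$. The gain keeps standard-normal
parent levels inside the sigmoid's active range: a much larger gain
saturates the response, expression becomes quasi-binary, and almost no
information is lost per regulatory step — an unrealistic regime in which the
DPI triplet ordering degenerates. The noise, at half the source-profile
scale, makes each step lose information, which is what the DPI exploits.
Cyclic networks are resolved by synchronous iteration (10 rounds) from
random initial states with per-gene measurement noise drawn once; acyclic
networks are evaluated exactly in topological order. All randomness flows
from one seed through named streams (topology, initial states, noise).

The simulator emulates the *dependence structure* the method needs —
nonlinear propagation, per-step information loss, multi-channel cycles — and
deliberately not transcription/translation kinetics, ODE steady states,
time-series designs, or measurement models of any particular platform.
Passing tests therefore show that the method recovers pathways when its
assumptions hold in data of realistic size and noise; they do not certify
performance on any particular microarray or RNA-seq dataset.

A four-node scenario with two parallel channels $A \to B \to D$ and
$A \to C \to D$ reproduces the method's documented failure mode
(**skipping**): the DPI assumes a single influence channel, so when two
strong channels combine, the shortcut edge A–D tends to look direct while
true edges are pruned. The scenario uses gain 3 — the saturating,
near-lossless regime — because skipping is by nature a strong-channel
phenomenon; the test documents the limitation rather than celebrating a
success.

## Evaluation conventions

Inferred paths are scored against the *most direct* true path (fewest hops
in the undirected ground truth; MI symmetry makes direction unrecoverable).
Precision is $tp/(tp+fp)$ and recall $tp/(tp+fn)$, each 0 when its
denominator is 0. Edge-wise scores compare unordered edge sets; node-wise
scores compare interior nodes only — root and target are inputs to the
query, and counting them would inflate node-wise precision. Only pairs whose
true path has at least two edges contribute, since node-wise measures are
meaningless for single-edge paths. Network cyclicity is the fraction of back
edges met in a deterministic depth-first search of the directed truth. The
random-path baseline draws, per connected ordered pair, one uniformly random
simple path no longer than the longest true path. The association between
path probability and performance is summarised by the Pearson correlation
with the average of precision and recall (a linear relation being the
simplest candidate); it is reported as undefined when either vector is
constant.

## Numerical and design choices

* Probability/weight duality is maintained exactly: a returned path's
  `total_weight` is the sum of its edge weights and its `probability` is
  `exp(-total_weight)`, so $|w + \log p| < 10^{-9}$ always holds.
* Constant expression profiles have zero marginal entropy; their MI is 0 by
  definition rather than an error, and missing values are rejected rather
  than imputed (imputation would silently change MI estimates).
* Edge probabilities are treated as independent when multiplied along a
  path. Adjacent edges share triplet comparisons, so this is an
  approximation — the package implements the independence-based product, not
  a joint model.
* Problem sizes in the test suite (networks of 3–21 genes, 100–2000 samples,
  up to 100 bootstrap rounds, exhaustive oracles up to 8 nodes) were chosen
  so exhaustive enumeration stays tractable as an oracle while remaining in
  the regime the method targets (tens of genes of interest, hundreds of
  samples).

## Known limitations

* Direction of regulation is not inferred; everything downstream of MI is
  undirected.
* Skipping in cycles, as above, is inherent to DPI-based directness.
* Scoring against the most direct true path gives no credit to valid but
  less direct paths; all-or-nothing path metrics favour methods that
  optimise whole paths over methods (like MSTs) that excel at partial
  credit.
* The ARACNe comparator is an independent implementation for contrast
  experiments — plug-in binned MI, not the kernel estimator of the official
  implementation.
* MI estimation quality limits everything downstream at small sample sizes;
  the bootstrap only propagates that uncertainty, it does not remove it.
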