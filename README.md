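# pathmi

Probabilistic inference and ranking of linear gene-regulatory pathways from
expression data, as a shortest-path problem.

## The problem

Expression profiling (microarrays, RNA-seq) measures thousands of genes at
once, and the dependence between genes' profiles carries information about
regulation. Whole-network inference turns that information into a "hairball"
that is hard to act on. A more useful unit for an experimentalist is a
**linear pathway**: the most likely chain of *direct* regulatory
interactions connecting two genes of interest, together with a probability
that can prioritise interactions for laboratory validation.

## The method

Dependence is measured by mutual information (MI), which captures nonlinear
relationships. Directness is decided by the **data processing inequality
(DPI)**: if A influences C only through B, then

    I(A;C) ≤ min{ I(A;B), I(B;C) }

so an edge that is the strictly least of some triplet is indirect. Because
MI must be estimated, directness is made probabilistic by bootstrapping: the
sample columns are resampled B times, each round's MI matrix is classified
by the DPI, and each edge's **probability of directness** P(direct(AB)) is
the (Laplace-smoothed) proportion of rounds in which it is direct. Under
edge independence, the probability that a path p is entirely direct is the
product of its edge probabilities, and

    argmax_p  ∏ P(direct(AB))  =  argmin_p  ∑ −log P(direct(AB))
              AB∈e_p                        AB∈e_p

so the most probable pathway is the shortest path under nonnegative
negative-log weights — found with Dijkstra's algorithm, and ranked across
gene pairs by the joint probability.

The package also provides the two standard comparison methods (an
ARACNe-style permutation-threshold + DPI-tolerance pruner, and a minimum
spanning tree on transformed MI, both with unit-weight path extraction),
path-level precision/recall evaluation against a ground-truth network, a
random-path baseline, network cyclicity, and a simulator generating networks
of controllable topology and cyclicity with nonlinear, noisy expression
data.

## Worked example

Simulate an 8-gene regulatory chain (400 samples, sigmoidal regulation,
additive noise), fit edge-directness probabilities with 100 bootstrap
rounds, and query the most probable pathway from G1 to G8:

```r
library(pathmi)

cfg  <- sim_config(n_genes = 8, n_samples = 400, seed = 5)
net  <- generate_network(cfg)                # ground truth: G1 -> ... -> G8
expr <- simulate_expression(net, cfg)

fit <- path_directness(expr, n_boot = 100, seed = 5)
fit
#> Edge-directness model
#>   call: path_directness(x = expr, n_boot = 100, seed = 5)
#>   8 genes, 100 bootstrap rounds, eqfreq binning
#>   P(direct): min 0.020, median 0.064, max 0.971

predict(fit, "G1", "G8")
#> G1 -> G2 -> G3 -> G4 -> G5 -> G6 -> G7 -> G8  [p = 0.5179]
```

The fitted object holds one probability of directness per gene pair
(`coef(fit)`); `summary(fit)` ranks the edges:

```r
summary(fit)
#> Edge-directness model: 28 edges, 100 bootstrap rounds (laplace)
#> Top edges by probability of directness:
#>   gene_a gene_b probability   mi weight
#> 1     G1     G2       0.971 1.09 0.0299
#> 2     G6     G7       0.971 1.11 0.0299
#> 3     G7     G8       0.951 1.08 0.0503
#> 4     G4     G5       0.922 1.10 0.0817
#> 5     G5     G6       0.882 1.08 0.1252
```

All seven true chain edges head the ranking, and the predicted G1→G8
pathway is the exact chain with joint probability 0.52 — the product of its
seven edge probabilities. Scoring against the ground truth:

```r
evaluate_paths(list(predict(fit, "G1", "G8")), net)
#> Path evaluation: 1 contributing pairs
#>   edge-wise mean precision 1.000, mean recall 1.000
#>   truth cyclicity 0.000; probability/performance correlation undefined
```

A thin command-line front-end over the same functions is installed at
`system.file("cli", "pathmi.R", package = "pathmi")` with subcommands
`simulate`, `mi`, `directness`, `infer-paths`, `infer-network`, `evaluate`.

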