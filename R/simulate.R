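#' Simulation configuration
#'
#' Study conditions for the synthetic ground-truth networks and expression
#' data used to exercise the inference methods. Defaults describe a strongly
#' regulated, noisy system: bounded (sigmoidal) regulatory response — the
#' nonlinear dependence that motivates mutual information over correlation —
#' with gain 1.5, which keeps standard-normal parent levels inside the
#' sigmoid's active range rather than saturating it, and additive noise of
#' sd 0.5, half the source-profile scale, so each regulatory step loses a
#' realistic amount of information.
#'
#' @param n_genes number of genes.
#' @param topology `"chain"` (path G1 -> G2 -> ... -> Gn), `"tree"` (random
#'   directed tree), or `"cycles"` (random tree plus cycle-closing edges).
#' @param cycle_fraction target fraction of extra cycle-closing edges,
#'   relative to the `n_genes - 1` tree edges; only meaningful (and only
#'   allowed) with `topology = "cycles"`.
#' @param n_samples number of samples (columns), >= 4.
#' @param regulation_strength positive gain applied to the mean parent
#'   expression inside the response function.
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise on every regulated gene.
#' @param nonlinearity `"sigmoid"` (tanh response) or `"linear"`.
#' @param seed master seed; all randomness (topology, initial states, noise)
#'   flows from it through named streams, so the same configuration is
#'   bit-reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10L,
                       topology = c("chain", "tree", "cycles"),
                       cycle_fraction = 0,
                       n_samples = 400L,
                       regulation_strength = 1.5,
                       noise_sd = 0.5,
                       nonlinearity = c("sigmoid", "linear"),
                       seed = 1L) {
  topology <- match.arg(topology)
  nonlinearity <- match.arg(nonlinearity)
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  stopifnot(n_genes >= 2L, n_samples >= 4L,
            cycle_fraction >= 0, cycle_fraction <= 1,
            regulation_strength > 0, noise_sd > 0)
  if (cycle_fraction > 0 && topology != "cycles") {
    stop("cycle_fraction > 0 requires topology = \"cycles\"")
  }
  structure(list(n_genes = n_genes, topology = topology,
                 cycle_fraction = cycle_fraction, n_samples = n_samples,
                 regulation_strength = regulation_strength,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a ground-truth regulatory network
#'
#' Chain topologies are the deterministic path G1 -> ... -> Gn. Trees attach
#' each gene to a uniformly chosen earlier gene. The `"cycles"` topology
#' starts from such a tree and adds `round(cycle_fraction * (n - 1))` extra
#' edges, each pointing from a node back to one of its ancestors so that
#' every added edge closes a directed cycle.
#'
#' @param config a [sim_config()].
#' @return a directed [regulatory_network()] with genes `G1 ... Gn`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  genes <- paste0("G", seq_len(n))
  seeds <- stream_seeds(config$seed, c("network", "init", "noise"))
  if (config$topology == "chain") {
    edges <- cbind(genes[-n], genes[-1L])
    return(regulatory_network(edges, genes = genes, directed = TRUE))
  }
  with_seed(seeds[["network"]], {
    parent <- c(NA_integer_,
                vapply(seq.int(2L, n), function(i) {
                  if (i == 2L) 1L else sample.int(i - 1L, 1L)
                }, integer(1L)))
    edges <- cbind(genes[parent[-1L]], genes[-1L])
    if (config$topology == "cycles") {
      n_extra <- round(config$cycle_fraction * (n - 1L))
      have <- paste(edges[, 1L], edges[, 2L])
      added <- 0L
      attempts <- 0L
      while (added < n_extra && attempts < 100L * n_extra) {
        attempts <- attempts + 1L
        v <- sample.int(n - 1L, 1L) + 1L      # any non-root node
        anc <- integer()
        a <- parent[v]
        while (!is.na(a)) {
          anc <- c(anc, a)
          a <- parent[a]
        }
        a <- if (length(anc) == 1L) anc else sample(anc, 1L)
        key <- paste(genes[v], genes[a])
        if (!key %in% have) {
          edges <- rbind(edges, c(genes[v], genes[a]))
          have <- c(have, key)
          added <- added + 1L
        }
      }
    }
    regulatory_network(edges, genes = genes, directed = TRUE)
  })
}

topological_order <- function(genes, parents) {
  indeg <- vapply(genes, function(g) length(parents[[g]]), integer(1L))
  children <- lapply(genes, function(g) {
    genes[vapply(genes, function(h) g %in% parents[[h]], logical(1L))]
  })
  names(children) <- genes
  queue <- genes[indeg == 0L]
  out <- character()
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, u)
    for (v in children[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  if (length(out) == length(genes)) out else NULL  # NULL when cyclic
}

#' Simulate expression data from a regulatory network
#'
#' Per sample, source genes (no regulators) are drawn from a standard normal;
#' every regulated gene responds to the mean of its parents through the
#' configured response function plus independent Gaussian noise:
#' `x_g = f(strength * mean(parents)) + e`, `f = tanh` (sigmoid) or identity.
#' Acyclic networks are evaluated exactly in topological order; networks with
#' cycles are resolved by synchronous iteration (10 rounds) from random
#' initial states, with each gene's measurement noise drawn once and applied
#' at every round.
#'
#' @param network a directed [regulatory_network()] (typically from
#'   [generate_network()], but any network over labelled genes works).
#' @param config a [sim_config()]; `n_samples`, `regulation_strength`,
#'   `noise_sd`, `nonlinearity` and `seed` are used.
#' @return an expression matrix (genes x samples), gene order as in
#'   `network$genes`, samples labelled `S1 ... Sn`.
#' @export
simulate_expression <- function(network, config) {
  stopifnot(inherits(network, "regulatory_network"),
            inherits(config, "sim_config"))
  genes <- network$genes
  ns <- config$n_samples
  parents <- lapply(genes, function(g) network$edges[network$edges[, 2L] == g, 1L])
  names(parents) <- genes
  f <- if (config$nonlinearity == "sigmoid") tanh else identity
  k <- config$regulation_strength
  seeds <- stream_seeds(config$seed, c("network", "init", "noise"))
  is_source <- vapply(genes, function(g) length(parents[[g]]) == 0L, logical(1L))
  x <- matrix(0, nrow = length(genes), ncol = ns,
              dimnames = list(genes, paste0("S", seq_len(ns))))
  x[] <- with_seed(seeds[["init"]], {
    init <- matrix(stats::rnorm(length(genes) * ns), nrow = length(genes))
    init
  })
  noise <- with_seed(seeds[["noise"]], {
    matrix(stats::rnorm(length(genes) * ns, sd = config$noise_sd),
           nrow = length(genes), dimnames = dimnames(x))
  })
  update_gene <- function(g, state) {
    pa <- parents[[g]]
    m <- if (length(pa) == 1L) state[pa, ] else colMeans(state[pa, , drop = FALSE])
    f(k * m) + noise[g, ]
  }
  topo <- topological_order(genes, parents)
  if (!is.null(topo)) {
    for (g in topo) {
      if (!is_source[g]) x[g, ] <- update_gene(g, x)
    }
  } else {
    for (round in seq_len(10L)) {
      new_x <- x
      for (g in genes) {
        if (!is_source[g]) new_x[g, ] <- update_gene(g, x)
      }
      x <- new_x
    }
  }
  as_expression_matrix(x)
}
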