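#' ARACNe configuration
#'
#' Defaults encode the tuning that favours path extraction: a stringent
#' (zero) DPI tolerance margin and a permissive significance threshold
#' (`alpha = 0.30`).
#'
#' @param n_permutations permutation rounds for the null MI distribution,
#'   >= 10.
#' @param significance_alpha significance level in (0, 1]; the MI threshold
#'   is the `1 - alpha` quantile of the null distribution.
#' @param dpi_tolerance relative tolerance margin in `[0, 1)` for DPI
#'   pruning.
#' @param seed integer seed for the permutation test.
#' @return an object of class `aracne_config`.
#' @export
aracne_config <- function(n_permutations = 100L, significance_alpha = 0.30,
                          dpi_tolerance = 0, seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 10L,
            significance_alpha > 0, significance_alpha <= 1,
            dpi_tolerance >= 0, dpi_tolerance < 1)
  structure(list(n_permutations = n_permutations,
                 significance_alpha = significance_alpha,
                 dpi_tolerance = dpi_tolerance,
                 seed = as.integer(seed)),
            class = "aracne_config")
}

#' MI significance threshold by permutation test
#'
#' Builds a null distribution of MI values between independently permuted
#' gene profiles (which destroys any dependence while preserving the
#' marginals) and returns its `1 - alpha` quantile. Each permutation round
#' permutes the two profiles of a randomly chosen gene pair independently;
#' several pairs are drawn per round.
#'
#' @param expr expression matrix.
#' @param config an [aracne_config()].
#' @param mi_conf an [mi_config()].
#' @param pairs_per_round gene pairs sampled per permutation round.
#' @return nonnegative MI threshold, reproducible given `config$seed`.
#' @export
permutation_threshold <- function(expr, config = aracne_config(),
                                  mi_conf = mi_config(),
                                  pairs_per_round = 5L) {
  expr <- as_expression_matrix(expr)
  g <- nrow(expr)
  n <- ncol(expr)
  if (g < 2L) stop("need at least 2 genes")
  with_seed(config$seed, {
    null_mi <- replicate(config$n_permutations, {
      vapply(seq_len(pairs_per_round), function(k) {
        ij <- sample.int(g, 2L)
        mi_pair(expr[ij[1L], sample.int(n)],
                expr[ij[2L], sample.int(n)], mi_conf)
      }, numeric(1L))
    })
    unname(stats::quantile(null_mi, 1 - config$significance_alpha))
  })
}

#' ARACNe-style network inference
#'
#' Keeps an edge (A,B) when its MI clears the significance threshold and it
#' is not pruned by the data processing inequality with a relative tolerance
#' margin: pruned iff some third gene C has
#' \eqn{I(A,B) < (1 - \tau)\,\min(I(A,C), I(B,C))}. With `tolerance = 0` this
#' reduces to [dpi_classify()] intersected with the threshold filter.
#'
#' @param mi symmetric MI matrix.
#' @param threshold minimum MI to keep an edge, e.g. from
#'   [permutation_threshold()].
#' @param tolerance relative tolerance margin in `[0, 1)`.
#' @return an undirected [regulatory_network()] over the genes of `mi`.
#' @export
aracne_network <- function(mi, threshold = 0, tolerance = 0) {
  mi <- symmetric_gene_matrix(mi, check = "none")
  stopifnot(tolerance >= 0, tolerance < 1)
  genes <- rownames(mi)
  n <- length(genes)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (is.na(mi[i, j]) || mi[i, j] < threshold) next
      others <- seq_len(n)[-c(i, j)]
      ok <- if (length(others)) {
        mi[i, j] >= (1 - tolerance) * max(pmin(mi[i, others], mi[j, others]))
      } else {
        TRUE
      }
      keep[i, j] <- ok
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  regulatory_network(cbind(genes[idx[, 1L]], genes[idx[, 2L]]),
                     genes = genes, directed = FALSE)
}

#' Minimum spanning tree network from MI
#'
#' Prim's algorithm on transformed MI values. MI measures edge strength, so
#' it is turned into a cost to minimise: either scaled by the dataset maximum
#' and subtracted from one (`"sub1"`, weight `1 - I/I_max`), or negative-log
#' transformed (`"neglog"`, weight `-log(I/I_max)`, zero-MI edges excluded).
#' Both transforms are strictly decreasing in MI, so whenever all MI values
#' are positive they produce the same tree. Prim is seeded at the
#' lexicographically smallest gene of each component; frontier ties are
#' broken by label for determinism.
#'
#' @param mi symmetric MI matrix with at least one positive value.
#' @param transform `"sub1"` or `"neglog"`.
#' @return an undirected [regulatory_network()] spanning every connected
#'   component (`n - 1` edges when connected).
#' @export
mst_network <- function(mi, transform = c("sub1", "neglog")) {
  transform <- match.arg(transform)
  mi <- symmetric_gene_matrix(mi, check = "mi")
  genes <- rownames(mi)
  n <- length(genes)
  if (n < 2L) stop("need at least 2 genes")
  off <- mi[row(mi) != col(mi)]
  imax <- max(off, na.rm = TRUE)
  if (!is.finite(imax) || imax <= 0) {
    stop("all-zero MI matrix: no spanning criterion")
  }
  w <- if (transform == "sub1") 1 - mi / imax else -log(mi / imax)
  w[mi == 0 & transform == "neglog"] <- Inf
  diag(w) <- NA_real_
  ord <- order(genes)
  in_tree <- rep(FALSE, n)
  edges <- matrix(character(), ncol = 2L)
  for (s in ord) {
    if (in_tree[s]) next
    in_tree[s] <- TRUE                    # new component root
    repeat {
      best <- NULL
      for (u in which(in_tree)) {
        for (v in which(!in_tree)) {
          wuv <- w[u, v]
          if (!is.finite(wuv)) next
          if (is.null(best) || wuv < best$w ||
              (wuv == best$w && (genes[v] < genes[best$v] ||
                (genes[v] == genes[best$v] && genes[u] < genes[best$u])))) {
            best <- list(u = u, v = v, w = wuv)
          }
        }
      }
      if (is.null(best)) break
      in_tree[best$v] <- TRUE
      edges <- rbind(edges, c(genes[best$u], genes[best$v]))
    }
  }
  regulatory_network(edges, genes = genes, directed = FALSE)
}

# Unit-weight adjacency of a network's undirected view, for hop searches.
unit_weight_graph <- function(network) {
  net <- undirected_view(network)
  n <- length(net$genes)
  w <- matrix(NA_real_, n, n, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges)) {
    w[net$edges] <- 1
    w[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  w
}

#' Fewest-hop path through an inferred network
#'
#' Shortest path between two genes in a network whose edges all carry unit
#' weight: the path-extraction step applied to networks inferred by the
#' comparison methods. Tie-breaking is deterministic as in [dijkstra()].
#'
#' @param network a [regulatory_network()] (used via its undirected view).
#' @param root,target gene labels.
#' @return a [gene_path()] (no probability annotation), or `NULL` when the
#'   target is unreachable.
#' @export
extract_path <- function(network, root, target) {
  w <- unit_weight_graph(network)
  if (!root %in% rownames(w)) stop("unknown root node '", root, "'")
  if (!target %in% rownames(w)) stop("unknown target node '", target, "'")
  if (root == target) stop("root and target must differ")
  nodes <- trace_path(dijkstra(w, root), target)
  if (is.null(nodes)) return(NULL)
  gene_path(nodes)
}
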