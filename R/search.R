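#' Single-source shortest paths (Dijkstra)
#'
#' Dijkstra's algorithm over a nonnegatively weighted undirected graph.
#' Ties — both in the choice of the next node to settle and between
#' equal-weight paths — are broken towards the lexicographically smallest
#' label, so results are fully deterministic. Because all weights are
#' nonnegative, shortest paths are automatically simple.
#'
#' @param graph a [weighted_graph()] or a symmetric weight matrix (`NA` or
#'   `Inf` off-diagonal entries mean "no edge").
#' @param root label of the source node.
#' @return an object of class `shortest_paths`: list with `root`,
#'   `distance` (named numeric; `Inf` = unreachable) and `predecessor`
#'   (named character; `NA` for the root and unreachable nodes).
#' @export
dijkstra <- function(graph, root) {
  w <- if (inherits(graph, "weighted_graph")) graph$weights else {
    weighted_graph(graph)$weights
  }
  genes <- rownames(w)
  n <- length(genes)
  if (!root %in% genes) stop("unknown root node '", root, "'")
  dist <- rep(Inf, n)
  names(dist) <- genes
  pred <- rep(NA_character_, n)
  names(pred) <- genes
  visited <- rep(FALSE, n)
  dist[root] <- 0
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    dmin <- min(dist[cand])
    u <- cand[dist[cand] == dmin]
    if (length(u) > 1L) u <- u[order(genes[u])][1L]
    visited[u] <- TRUE
    wu <- w[u, ]
    for (v in which(!visited & is.finite(wu))) {
      nd <- dist[u] + wu[v]
      if (nd < dist[v] ||
          (nd == dist[v] && !is.na(pred[v]) && genes[u] < pred[v])) {
        dist[v] <- nd
        pred[v] <- genes[u]
      }
    }
  }
  structure(list(root = root, distance = dist, predecessor = pred),
            class = "shortest_paths")
}

#' @export
print.shortest_paths <- function(x, ...) {
  cat(sprintf("Shortest paths from '%s': %d of %d nodes reachable\n",
              x$root, sum(is.finite(x$distance)), length(x$distance)))
  invisible(x)
}

# Walk predecessors back from target to root; NULL when unreachable.
trace_path <- function(sp, target) {
  if (!target %in% names(sp$distance)) {
    stop("unknown target node '", target, "'")
  }
  if (!is.finite(sp$distance[[target]])) return(NULL)
  nodes <- target
  while (nodes[1L] != sp$root) {
    nodes <- c(sp$predecessor[[nodes[1L]]], nodes)
  }
  nodes
}

# Minimum-weight walk from root using at most max_edges edges
# (Bellman-Ford-style layered relaxation). With strictly positive weights the
# optimum is a simple path; any zero-weight cycle produced by ties is
# collapsed on reconstruction.
bounded_shortest_path <- function(w, root, target, max_edges) {
  genes <- rownames(w)
  n <- length(genes)
  r <- match(root, genes)
  t <- match(target, genes)
  dist <- matrix(Inf, nrow = max_edges + 1L, ncol = n)
  pred <- matrix(NA_integer_, nrow = max_edges + 1L, ncol = n)
  dist[1L, r] <- 0
  for (h in seq_len(max_edges)) {
    dist[h + 1L, ] <- dist[h, ]
    pred[h + 1L, ] <- pred[h, ]
    for (u in which(is.finite(dist[h, ]))) {
      for (v in which(is.finite(w[u, ]))) {
        nd <- dist[h, u] + w[u, v]
        if (nd < dist[h + 1L, v] ||
            (nd == dist[h + 1L, v] && !is.na(pred[h + 1L, v]) &&
             genes[u] < genes[pred[h + 1L, v]])) {
          dist[h + 1L, v] <- nd
          pred[h + 1L, v] <- u
        }
      }
    }
  }
  if (!is.finite(dist[max_edges + 1L, t])) return(NULL)
  h <- which(dist[, t] == dist[max_edges + 1L, t])[1L]
  nodes <- t
  while (nodes[1L] != r) {
    h <- h - 1L
    nodes <- c(pred[h + 1L, nodes[1L]], nodes)
  }
  nodes <- genes[nodes]
  while (anyDuplicated(nodes)) {
    d <- which(duplicated(nodes))[1L]
    f <- which(nodes == nodes[d])[1L]
    nodes <- nodes[-seq.int(f, d - 1L)]
  }
  nodes
}

as_search_graph <- function(result, probability_floor = NULL) {
  if (inherits(result, "weighted_graph")) result
  else if (inherits(result, "path_directness")) result$graph
  else to_weighted_graph(result, probability_floor)
}

#' Most probable all-direct path between two genes
#'
#' Finds the path from `root` to `target` that maximises the product of its
#' edges' probabilities of directness, assuming independence of edges. The
#' search runs Dijkstra's algorithm on the negative-log-probability weights,
#' for which the minimum-weight path is exactly the maximum-product path.
#'
#' @param result a `directness_result` from [edge_probabilities()] (or an
#'   already-built [weighted_graph()]).
#' @param root,target distinct gene labels.
#' @param probability_floor passed to [to_weighted_graph()].
#' @param max_edges optional cap on the number of edges (a limit of
#'   biological plausibility). When set, a layered bounded search replaces
#'   plain Dijkstra. `NULL` (default) means no cap.
#' @return a [gene_path()] with `probability` and `total_weight`, or `NULL`
#'   if target is unreachable within the cap.
#' @export
most_probable_path <- function(result, root, target,
                               probability_floor = NULL, max_edges = NULL) {
  g <- as_search_graph(result, probability_floor)
  if (!root %in% g$genes) stop("unknown root node '", root, "'")
  if (!target %in% g$genes) stop("unknown target node '", target, "'")
  if (root == target) stop("root and target must differ")
  nodes <- if (is.null(max_edges)) {
    trace_path(dijkstra(g, root), target)
  } else {
    bounded_shortest_path(g$weights, root, target, as.integer(max_edges))
  }
  if (is.null(nodes)) return(NULL)
  tw <- sum(g$weights[cbind(nodes[-length(nodes)], nodes[-1L])])
  gene_path(nodes, probability = exp(-tw), total_weight = tw)
}

#' Rank most-probable paths across gene pairs
#'
#' Computes the most probable path for every requested (root, target) pair
#' and returns the paths sorted by descending joint probability of
#' directness; ties are broken by (root, target) label order. The ranking is
#' invariant to the order of the input pairs.
#'
#' @param result as in [most_probable_path()].
#' @param pairs two-column matrix or data frame of (root, target) labels, or
#'   a list of length-2 character vectors.
#' @param ... passed to [most_probable_path()].
#' @return list of [gene_path()] objects, unreachable pairs dropped.
#' @export
rank_paths <- function(result, pairs, ...) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  g <- as_search_graph(result)
  paths <- lapply(seq_len(nrow(pairs)), function(i) {
    most_probable_path(g, pairs[i, 1L], pairs[i, 2L], ...)
  })
  keep <- !vapply(paths, is.null, logical(1L))
  paths <- paths[keep]
  pairs <- pairs[keep, , drop = FALSE]
  probs <- vapply(paths, `[[`, numeric(1L), "probability")
  paths[order(-probs, pairs[, 1L], pairs[, 2L])]
}
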