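# Independent oracles and fixture builders, deliberately brute-force and
# separate from the implementation paths they check.

# Random symmetric matrix with off-diagonal entries in (lo, hi), NA diagonal.
rand_sym_matrix <- function(n, lo = 0, hi = 1, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("N%02d", seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  ut <- upper.tri(m)
  m[ut] <- stats::runif(sum(ut), lo, hi)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Exhaustive simple-path enumeration: minimum total weight from root to every
# node. NA/Inf entries of w mean "no edge".
enum_min_dists <- function(w, root) {
  genes <- rownames(w)
  n <- length(genes)
  best <- rep(Inf, n)
  names(best) <- genes
  r <- match(root, genes)
  best[r] <- 0
  used <- rep(FALSE, n)
  used[r] <- TRUE
  visit <- function(u, d) {
    for (v in seq_len(n)) {
      wuv <- w[u, v]
      if (used[v] || is.na(wuv) || !is.finite(wuv)) next
      nd <- d + wuv
      if (nd < best[v]) best[v] <<- nd
      used[v] <<- TRUE
      visit(v, nd)
      used[v] <<- FALSE
    }
  }
  visit(r, 0)
  best
}

# Exhaustive maximum-product simple path between two nodes on a probability
# matrix (NA diagonal). Returns list(nodes, prob).
enum_max_product <- function(p, root, target, max_edges = Inf) {
  genes <- rownames(p)
  n <- length(genes)
  r <- match(root, genes)
  t <- match(target, genes)
  best <- list(nodes = NULL, prob = -Inf)
  used <- rep(FALSE, n)
  used[r] <- TRUE
  visit <- function(u, nodes, prob) {
    if (u == t) {
      if (prob > best$prob) best <<- list(nodes = genes[nodes], prob = prob)
      return()
    }
    if (length(nodes) - 1L >= max_edges) return()
    for (v in seq_len(n)) {
      pv <- p[u, v]
      if (used[v] || is.na(pv) || pv <= 0) next
      used[v] <<- TRUE
      visit(v, c(nodes, v), prob * pv)
      used[v] <<- FALSE
    }
  }
  visit(r, r, 1)
  best
}

# Brute-force DPI classification by explicit triple loop.
brute_dpi <- function(mi) {
  n <- nrow(mi)
  direct <- matrix(NA, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (mi[i, j] < min(mi[i, k], mi[j, k])) d <- FALSE
      }
      direct[i, j] <- d
    }
  }
  direct
}

# Breadth-first-search hop counts over an undirected edge list.
bfs_hops <- function(network, root) {
  net <- undirected_view(network)
  genes <- net$genes
  adj <- lapply(genes, function(g) {
    e <- net$edges
    sort(unique(c(e[e[, 1L] == g, 2L], e[e[, 2L] == g, 1L])))
  })
  names(adj) <- genes
  dist <- stats::setNames(rep(Inf, length(genes)), genes)
  dist[root] <- 0
  queue <- root
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# Closed-form MI matrix of a Gaussian tree model: a random tree over n nodes
# with edge correlations drawn in (0.4, 0.8); the correlation of any pair is
# the product of edge correlations along their tree path, and
# I = -log(1 - rho^2) / 2.
gaussian_tree_mi <- function(n = 10, seed = 1) {
  set.seed(seed)
  genes <- sprintf("N%02d", seq_len(n))
  parent <- c(NA_integer_, vapply(seq.int(2L, n), function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1L)))
  rho_edge <- c(NA_real_, stats::runif(n - 1L, 0.4, 0.8))
  depth <- function(i) {
    d <- 0L
    while (!is.na(parent[i])) {
      i <- parent[i]
      d <- d + 1L
    }
    d
  }
  pair_rho <- function(i, j) {
    # climb to the common ancestor, multiplying edge correlations
    rho <- 1
    di <- depth(i)
    dj <- depth(j)
    while (di > dj) {
      rho <- rho * rho_edge[i]
      i <- parent[i]
      di <- di - 1L
    }
    while (dj > di) {
      rho <- rho * rho_edge[j]
      j <- parent[j]
      dj <- dj - 1L
    }
    while (i != j) {
      rho <- rho * rho_edge[i] * rho_edge[j]
      i <- parent[i]
      j <- parent[j]
    }
    rho
  }
  mi <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      rho <- pair_rho(i, j)
      mi[i, j] <- mi[j, i] <- -0.5 * log(1 - rho^2)
    }
  }
  edges <- cbind(genes[parent[-1L]], genes[-1L])
  list(mi = mi, edges = edges, genes = genes)
}

# Canonical unordered edge keys of an edge matrix / network.
edge_keys <- function(x) {
  e <- if (inherits(x, "regulatory_network")) x$edges else x
  if (!nrow(e)) return(character())
  sort(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "|"))
}

# Random undirected weight matrix with some edges absent.
rand_weight_graph <- function(n, p_edge = 0.7, wmax = 3) {
  genes <- sprintf("N%02d", seq_len(n))
  w <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (stats::runif(1) < p_edge) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0, wmax)
      }
    }
  }
  w
}

# Upper-triangle TRUE entries of a logical symmetric matrix, as an edge matrix.
which_edges <- function(flags) {
  f <- flags
  f[is.na(f)] <- FALSE
  idx <- which(f & upper.tri(f), arr.ind = TRUE)
  cbind(rownames(flags)[idx[, 1L]], colnames(flags)[idx[, 2L]])
}
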