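#' Reference path through the ground-truth network
#'
#' The fewest-hop (most direct) path between two genes in the true network's
#' undirected view, against which inferred paths are scored. Undirected,
#' because MI-based inference cannot recover edge direction.
#'
#' @param truth a [regulatory_network()].
#' @param root,target gene labels.
#' @return a [gene_path()], or `NULL` when the pair is not connected.
#' @export
true_path <- function(truth, root, target) {
  extract_path(truth, root, target)
}

#' Score an inferred path against the true path
#'
#' Edge-wise scoring compares the two paths' edge sets (as unordered pairs;
#' inference is undirected). Node-wise scoring compares interior nodes only:
#' the root and target are inputs to the query, not inferences, so counting
#' them would inflate the node-wise metrics. Precision is `tp / (tp + fp)`
#' and recall `tp / (tp + fn)`, each defined as 0 when its denominator is 0.
#'
#' @param inferred,truth_path [gene_path()] objects sharing root and target.
#' @param level `"edge"` or `"node"`.
#' @return an object of class `path_score`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `level`.
#' @export
score_path <- function(inferred, truth_path, level = c("edge", "node")) {
  level <- match.arg(level)
  items <- function(p, lev) {
    nodes <- if (inherits(p, "gene_path")) p$nodes else as.character(p)
    if (lev == "edge") path_edges(nodes)
    else if (length(nodes) > 2L) nodes[-c(1L, length(nodes))]
    else character()
  }
  inf <- items(inferred, level)
  tru <- items(truth_path, level)
  tp <- length(intersect(inf, tru))
  fp <- length(setdiff(inf, tru))
  fn <- length(setdiff(tru, inf))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    level = level
  ), class = "path_score")
}

#' @export
print.path_score <- function(x, ...) {
  cat(sprintf("%s-wise score: tp=%d fp=%d fn=%d precision=%.3f recall=%.3f\n",
              x$level, x$tp, x$fp, x$fn, x$precision, x$recall))
  invisible(x)
}

#' Cyclicity of a directed network
#'
#' The fraction of edges classified as back edges during a depth-first
#' search of the directed graph: an edge pointing to a node currently on the
#' DFS stack closes a directed cycle. DFS roots are taken in label order, as
#' are neighbours, so the value is deterministic. A DAG has cyclicity 0; a
#' single directed n-cycle has cyclicity 1/n.
#'
#' @param truth a directed [regulatory_network()].
#' @return back-edge fraction in `[0, 1]`; 0 for an empty edge set.
#' @export
cyclicity <- function(truth) {
  stopifnot(inherits(truth, "regulatory_network"))
  m <- nrow(truth$edges)
  if (m == 0L) return(0)
  genes <- sort(truth$genes)
  adj <- split(truth$edges[, 2L], factor(truth$edges[, 1L], levels = genes))
  adj <- lapply(adj, sort)
  state <- stats::setNames(rep(0L, length(genes)), genes)  # 0 white 1 gray 2 black
  back <- 0L
  visit <- function(u) {
    state[u] <<- 1L
    for (v in adj[[u]]) {
      if (state[v] == 1L) back <<- back + 1L
      else if (state[v] == 0L) visit(v)
    }
    state[u] <<- 2L
  }
  for (u in genes) if (state[u] == 0L) visit(u)
  back / m
}

#' Random path baseline
#'
#' For every ordered (root, target) pair connected in the true network, draws
#' one random simple path: a length (edge count) uniform on `[1, L_max]`,
#' where `L_max` is the longest true-path edge count over all pairs, followed
#' by uniformly sampled distinct intermediate nodes. The sampler ignores the
#' graph entirely — it is the chance-performance reference for the inference
#' methods.
#'
#' @param truth a [regulatory_network()].
#' @param gene_ids node pool to draw intermediates from; defaults to the
#'   network's genes.
#' @param seed integer seed.
#' @return named list of [gene_path()] objects (names `"root->target"`).
#' @export
random_baseline <- function(truth, gene_ids = NULL, seed = 1L) {
  stopifnot(inherits(truth, "regulatory_network"))
  if (is.null(gene_ids)) gene_ids <- truth$genes
  if (length(gene_ids) < 3L) stop("need at least 3 genes")
  pairs <- expand.grid(root = truth$genes, target = truth$genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$root != pairs$target, ]
  tp_len <- mapply(function(r, t) {
    p <- true_path(truth, r, t)
    if (is.null(p)) NA_integer_ else length(p$nodes) - 1L
  }, pairs$root, pairs$target)
  pairs <- pairs[!is.na(tp_len), ]
  if (!nrow(pairs)) return(list())
  l_max <- max(tp_len, na.rm = TRUE)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(pairs)), function(i) {
      r <- pairs$root[i]
      t <- pairs$target[i]
      len <- if (l_max == 1L) 1L else sample.int(l_max, 1L)
      pool <- setdiff(gene_ids, c(r, t))
      len <- min(len, length(pool) + 1L)
      mid <- if (len > 1L) sample(pool, len - 1L) else character()
      gene_path(c(r, mid, t))
    })
    names(out) <- paste0(pairs$root, "->", pairs$target)
    out
  })
}

#' Evaluate inferred paths against a ground-truth network
#'
#' Scores each inferred path against the most direct true path between its
#' endpoints, at both the edge and the interior-node level. Only pairs whose
#' true path is longer than a single edge contribute: single-edge paths make
#' the node-wise measures meaningless.
#'
#' @param paths list of [gene_path()] objects (probability annotations, when
#'   present, are carried into the report).
#' @param truth a [regulatory_network()].
#' @return an object of class `path_evaluation`: list with `table` (one row
#'   per contributing (root, target, level)), `cyclicity` of the truth
#'   network, and `correlation` between path probability and mean
#'   performance (`NA` when undefined).
#' @export
evaluate_paths <- function(paths, truth) {
  rows <- list()
  for (p in paths) {
    r <- p$nodes[1L]
    t <- p$nodes[length(p$nodes)]
    tp_path <- true_path(truth, r, t)
    if (is.null(tp_path)) next
    true_len <- length(tp_path$nodes) - 1L
    if (true_len < 2L) next
    for (level in c("edge", "node")) {
      s <- score_path(p, tp_path, level)
      rows[[length(rows) + 1L]] <- data.frame(
        root = r, target = t, true_length = true_len,
        probability = if (is.null(p$probability)) NA_real_ else p$probability,
        level = level, tp = s$tp, fp = s$fp, fn = s$fn,
        precision = s$precision, recall = s$recall,
        stringsAsFactors = FALSE
      )
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(root = character(), target = character(),
               true_length = integer(), probability = numeric(),
               level = character(), tp = integer(), fp = integer(),
               fn = integer(), precision = numeric(), recall = numeric())
  }
  corr <- tryCatch(
    probability_performance_correlation(table),
    error = function(e) NA_real_
  )
  structure(list(table = table, cyclicity = cyclicity(truth),
                 correlation = corr),
            class = "path_evaluation")
}

#' @export
print.path_evaluation <- function(x, ...) {
  e <- x$table[x$table$level == "edge", ]
  cat(sprintf("Path evaluation: %d contributing pairs\n", nrow(e)))
  if (nrow(e)) {
    cat(sprintf("  edge-wise mean precision %.3f, mean recall %.3f\n",
                mean(e$precision), mean(e$recall)))
  }
  cat(sprintf("  truth cyclicity %.3f; probability/performance correlation %s\n",
              x$cyclicity,
              if (is.na(x$correlation)) "undefined" else
                sprintf("%.3f", x$correlation)))
  invisible(x)
}

#' Correlation between path probability and path performance
#'
#' Pearson correlation between each path's joint probability of directness
#' and the average of its precision and recall, across (root, target) pairs.
#' A linear relation is the simplest one that could link the two; rank
#' measures would hide its sign and scale.
#'
#' @param report a `path_evaluation` object or its `table` data frame.
#' @param level which scoring level to correlate against, `"edge"` or
#'   `"node"`.
#' @return Pearson correlation in `[-1, 1]`; `NaN` with attribute
#'   `defined = FALSE` when either vector is constant.
#' @export
probability_performance_correlation <- function(report, level = "edge") {
  tab <- if (inherits(report, "path_evaluation")) report$table else report
  tab <- tab[tab$level == level & !is.na(tab$probability), ]
  if (nrow(tab) < 3L) stop("need at least 3 contributing pairs")
  perf <- (tab$precision + tab$recall) / 2
  if (stats::sd(tab$probability) == 0 || stats::sd(perf) == 0) {
    return(structure(NaN, defined = FALSE))
  }
  structure(stats::cor(tab$probability, perf), defined = TRUE)
}
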