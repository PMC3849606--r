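#' Classify edges as direct or indirect by the data processing inequality
#'
#' The data processing inequality (DPI) states that if gene A influences gene
#' C only through gene B, then \eqn{I(A;C) \le \min(I(A;B), I(B;C))}. An edge
#' (A,B) is therefore classified as *indirect* when some third gene C makes
#' it the strictly least edge of the triplet, i.e. when
#' \eqn{I(A,B) < \min(I(A,C), I(B,C))}, and *direct* otherwise. Ties leave
#' the edge direct: in biological systems the inequality can be taken to be
#' strict, so equality on estimates favours retention.
#'
#' @param mi symmetric MI matrix (diagonal ignored). With only 2 genes the
#'   single edge is trivially direct.
#' @return symmetric logical matrix; `TRUE` = direct, diagonal `NA`.
#' @export
dpi_classify <- function(mi) {
  mi <- symmetric_gene_matrix(mi, check = "none")
  n <- nrow(mi)
  if (n < 2L) stop("need at least 2 genes")
  direct <- matrix(NA, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      others <- seq_len(n)[-c(i, j)]
      d <- if (length(others)) {
        mi[i, j] >= max(pmin(mi[i, others], mi[j, others]))
      } else {
        TRUE
      }
      direct[i, j] <- d
      direct[j, i] <- d
    }
  }
  direct
}

#' Per-edge probability of directness from bootstrap MI matrices
#'
#' For each bootstrap round the full MI matrix is classified with
#' [dpi_classify()]; an edge's probability of directness is the proportion of
#' rounds in which it is direct. With Laplace smoothing (the default) the
#' proportion is `(count + 1) / (n_boot + 2)`, which keeps every probability
#' strictly inside (0, 1): a raw probability of 0 would map to an infinite
#' negative-log weight and silently delete the edge from the search graph.
#'
#' @param boot_mi nonempty list of MI matrices, e.g. from [bootstrap_mi()].
#' @param smoothing `"laplace"` or `"none"`.
#' @return an object of class `directness_result`: list with elements
#'   `probability` (symmetric matrix, diagonal `NA`), `n_boot`, `smoothing`.
#' @export
edge_probabilities <- function(boot_mi, smoothing = c("laplace", "none")) {
  smoothing <- match.arg(smoothing)
  if (!length(boot_mi)) stop("empty list of bootstrap MI matrices")
  n_boot <- length(boot_mi)
  counts <- Reduce(`+`, lapply(boot_mi, function(m) {
    d <- dpi_classify(m)
    d[is.na(d)] <- 0
    d + 0
  }))
  prob <- if (smoothing == "laplace") {
    (counts + 1) / (n_boot + 2)
  } else {
    counts / n_boot
  }
  diag(prob) <- NA_real_
  structure(
    list(probability = symmetric_gene_matrix(prob, check = "probability"),
         n_boot = n_boot, smoothing = smoothing),
    class = "directness_result"
  )
}

#' @export
print.directness_result <- function(x, ...) {
  p <- x$probability[upper.tri(x$probability)]
  cat(sprintf(
    "Edge directness probabilities: %d genes, %d bootstrap rounds (%s smoothing)\n",
    nrow(x$probability), x$n_boot, x$smoothing))
  cat(sprintf("  P(direct): min %.3f, median %.3f, max %.3f\n",
              min(p), stats::median(p), max(p)))
  invisible(x)
}

#' Negative-log-probability weighted graph
#'
#' Transforms edge probabilities of directness into shortest-path weights
#' `w = -log(max(p, probability_floor))`. Minimising the sum of these weights
#' over a path is equivalent to maximising the product of its edge
#' probabilities, so Dijkstra's algorithm on this graph finds the most
#' probable all-direct path. The graph stays complete: improbable edges get
#' large finite weights rather than being pruned (hard pruning is the
#' comparison methods' job), and the floor bounds the dynamic range of the
#' weights.
#'
#' @param result a `directness_result` from [edge_probabilities()], or a
#'   symmetric probability matrix.
#' @param probability_floor clamp applied after smoothing; defaults to
#'   `1 / (10 * n_boot)` when `result` carries `n_boot`, else 0 (no floor).
#' @return an object of class `weighted_graph`: list with `genes` and the
#'   symmetric nonnegative `weights` matrix (diagonal `NA`).
#' @export
to_weighted_graph <- function(result, probability_floor = NULL) {
  if (inherits(result, "directness_result")) {
    p <- result$probability
    if (is.null(probability_floor)) {
      probability_floor <- 1 / (10 * result$n_boot)
    }
  } else {
    p <- symmetric_gene_matrix(result, check = "probability")
    if (is.null(probability_floor)) probability_floor <- 0
  }
  off <- p[row(p) != col(p)]
  if (any(off <= 0 & probability_floor <= 0)) {
    stop("zero edge probability: enable smoothing or set probability_floor")
  }
  w <- -log(pmax(p, probability_floor))
  diag(w) <- NA_real_
  weighted_graph(w)
}

#' Construct a weighted graph from a symmetric weight matrix
#'
#' @param weights symmetric numeric matrix of nonnegative edge weights with
#'   gene labels; `NA`/`Inf` off-diagonal entries mean "no edge".
#' @return an object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights) {
  weights <- symmetric_gene_matrix(weights, check = "none")
  off <- weights[row(weights) != col(weights)]
  if (any(off < 0, na.rm = TRUE)) stop("edge weights must be nonnegative")
  structure(list(genes = rownames(weights), weights = weights),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("Weighted gene graph: %d nodes, %d finite edges\n",
              length(x$genes),
              sum(is.finite(x$weights[upper.tri(x$weights)]))))
  invisible(x)
}
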