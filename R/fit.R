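#' Fit edge-directness probabilities to an expression matrix
#'
#' The top-level fitting function. Pairwise mutual information is estimated
#' on `n_boot` bootstrap resamples of the samples; in each round every edge
#' is classified direct or indirect by the data processing inequality; the
#' per-edge proportions of direct rounds (Laplace-smoothed) are the fitted
#' probabilities of directness; and their negative logs form the weighted
#' search graph. The returned object supports `print`, `summary`, `coef`
#' (the probability matrix), `plot`, and `predict` (the most probable path
#' between a root and a target).
#'
#' @param x expression matrix (genes x samples) or a path readable by
#'   [read_expression()].
#' @param n_boot bootstrap rounds, >= 1; 100 is a practical default.
#' @param config an [mi_config()].
#' @param smoothing passed to [edge_probabilities()].
#' @param probability_floor passed to [to_weighted_graph()].
#' @param seed integer seed for the bootstrap.
#' @return an object of class `path_directness` with elements `directness`
#'   (see [edge_probabilities()]), `graph` (the [weighted_graph()]), `mi`
#'   (bootstrap-mean MI matrix), `config`, `n_boot`, `seed` and `call`.
#' @examples
#' cfg <- sim_config(n_genes = 5, n_samples = 120, seed = 3)
#' net <- generate_network(cfg)
#' fit <- path_directness(simulate_expression(net, cfg), n_boot = 20, seed = 3)
#' fit
#' predict(fit, root = "G1", target = "G5")
#' @export
path_directness <- function(x, n_boot = 100L, config = mi_config(),
                            smoothing = c("laplace", "none"),
                            probability_floor = NULL, seed = 1L) {
  smoothing <- match.arg(smoothing)
  if (is.character(x) && length(x) == 1L) x <- read_expression(x)
  x <- as_expression_matrix(x)
  boots <- bootstrap_mi(x, config, n_boot = n_boot, seed = seed)
  directness <- edge_probabilities(boots, smoothing = smoothing)
  structure(list(
    directness = directness,
    graph = to_weighted_graph(directness, probability_floor),
    mi = aggregate_mi(boots, "mean"),
    config = config,
    n_boot = length(boots),
    seed = as.integer(seed),
    call = match.call()
  ), class = "path_directness")
}

#' @export
print.path_directness <- function(x, ...) {
  cat("Edge-directness model\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d genes, %d bootstrap rounds, %s binning\n",
              length(x$graph$genes), x$n_boot, x$config$estimator))
  p <- x$directness$probability
  p <- p[upper.tri(p)]
  cat(sprintf("  P(direct): min %.3f, median %.3f, max %.3f\n",
              min(p), stats::median(p), max(p)))
  invisible(x)
}

#' @export
summary.path_directness <- function(object, n_top = 10L, ...) {
  p <- object$directness$probability
  ut <- which(upper.tri(p), arr.ind = TRUE)
  tab <- data.frame(
    gene_a = rownames(p)[ut[, 1L]],
    gene_b = colnames(p)[ut[, 2L]],
    probability = p[ut],
    mi = object$mi[ut],
    weight = object$graph$weights[ut],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$probability, tab$gene_a, tab$gene_b), ]
  rownames(tab) <- NULL
  structure(list(edges = tab, n_boot = object$n_boot,
                 smoothing = object$directness$smoothing,
                 n_top = min(n_top, nrow(tab))),
            class = "summary.path_directness")
}

#' @export
print.summary.path_directness <- function(x, ...) {
  cat(sprintf("Edge-directness model: %d edges, %d bootstrap rounds (%s)\n",
              nrow(x$edges), x$n_boot, x$smoothing))
  cat("Top edges by probability of directness:\n")
  print(utils::head(x$edges, x$n_top), digits = 3)
  invisible(x)
}

#' @export
coef.path_directness <- function(object, ...) {
  object$directness$probability
}

#' Most probable path from a fitted model
#'
#' @param object a `path_directness` fit.
#' @param root,target gene labels.
#' @param ... passed to [most_probable_path()] (e.g. `max_edges`).
#' @return a [gene_path()].
#' @export
predict.path_directness <- function(object, root, target, ...) {
  most_probable_path(object, root, target, ...)
}

#' @export
plot.path_directness <- function(x, ...) {
  p <- x$directness$probability
  diag(p) <- 1
  n <- nrow(p)
  graphics::image(seq_len(n), seq_len(n), t(p[n:1, ]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "P(edge is direct)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(p), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(p)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
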