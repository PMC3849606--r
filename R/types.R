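#' Validate and construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, carrying unique gene labels as rownames and unique
#' sample labels as colnames. All values must be finite; missing values are
#' rejected rather than imputed, since silent imputation would change the
#' mutual-information estimates downstream.
#'
#' @param values numeric matrix (genes x samples), or an object coercible to
#'   one that already carries dimnames.
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return a numeric matrix with validated dimnames.
#' @examples
#' x <- as_expression_matrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(c("G1", "G2", "G3"), paste0("S", 1:4))))
#' @export
as_expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene (row) and sample (column) labels")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene label(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample label(s): ", paste(dup_s, collapse = ", "))
  }
  if (ncol(values) == 0L) stop("no samples")
  if (nrow(values) == 0L) stop("no genes")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-finite value at gene '%s', sample '%s'",
      rownames(values)[bad[1L]], colnames(values)[bad[2L]]
    ))
  }
  values
}

#' Construct a symmetric gene-by-gene matrix
#'
#' Shared container for pairwise mutual-information matrices and edge
#' probability-of-directness matrices: square, symmetric, labelled by gene on
#' both margins. The diagonal carries no information for either use (an edge
#' from a gene to itself is never compared) and may be `NA`.
#'
#' @param values square numeric matrix.
#' @param gene_ids optional labels overriding dimnames.
#' @param check one of `"none"`, `"mi"` (off-diagonals must be >= 0) or
#'   `"probability"` (off-diagonals must lie in `[0, 1]`).
#' @return the validated matrix.
#' @export
symmetric_gene_matrix <- function(values, gene_ids = NULL,
                                  check = c("none", "mi", "probability")) {
  check <- match.arg(check)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (!is.null(gene_ids)) dimnames(values) <- list(gene_ids, gene_ids)
  if (is.null(rownames(values))) stop("gene labels required")
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels must agree")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene labels")
  off <- values[row(values) != col(values)]
  if (!isTRUE(all.equal(values[row(values) != col(values)],
                        t(values)[row(values) != col(values)],
                        tolerance = 1e-12, check.attributes = FALSE))) {
    stop("matrix is not symmetric")
  }
  if (check == "mi" && any(off < 0, na.rm = TRUE)) {
    stop("mutual information values must be nonnegative")
  }
  if (check == "probability" && any(off < 0 | off > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  values
}

#' Ground-truth regulatory network
#'
#' A set of regulatory edges over labelled genes. Networks are stored as read
#' (directed by default); [undirected_view()] collapses reciprocal edges.
#' Self-loops are rejected and duplicate edges are collapsed.
#'
#' @param edges two-column character matrix or data frame of
#'   (source, target) pairs; may have zero rows.
#' @param genes optional character vector of node labels; defaults to the
#'   labels appearing in `edges`. Every edge endpoint must be listed.
#' @param directed logical; whether edge orientation is meaningful.
#' @return an object of class `regulatory_network` with elements `genes`
#'   (character), `edges` (2-column character matrix) and `directed`.
#' @export
regulatory_network <- function(edges, genes = NULL, directed = TRUE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("source", "target")))
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    stop("self-loop on node '", edges[which(loops)[1L], 1L], "'")
  }
  edges <- unique(edges)
  if (is.null(genes)) genes <- sort(unique(as.vector(edges)))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene labels")
  missing <- setdiff(as.vector(edges), genes)
  if (length(missing)) {
    stop("edge endpoint(s) not in gene set: ", paste(missing, collapse = ", "))
  }
  structure(
    list(genes = genes, edges = edges, directed = isTRUE(directed)),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "%s regulatory network: %d genes, %d edges\n",
    if (x$directed) "Directed" else "Undirected",
    length(x$genes), nrow(x$edges)
  ))
  invisible(x)
}

#' Undirected view of a network
#'
#' Collapses edges `(a, b)` and `(b, a)` into a single undirected edge,
#' stored with its endpoints in sorted order. Mutual information is symmetric
#' so inference is undirected; the directed representation is retained only
#' where direction matters (e.g. cyclicity).
#'
#' @param network a [regulatory_network()].
#' @return a `regulatory_network` with `directed = FALSE` and canonically
#'   ordered endpoints.
#' @export
undirected_view <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    colnames(e) <- c("source", "target")
    e <- unique(e)
  }
  regulatory_network(e, genes = network$genes, directed = FALSE)
}

#' Construct a gene path
#'
#' An ordered, simple (no repeated node) sequence of genes, optionally
#' annotated with the joint probability that all of its edges are direct and
#' the corresponding total negative-log weight. When both annotations are
#' present they must satisfy `total_weight == -log(probability)` to within
#' 1e-9.
#'
#' @param nodes character vector of gene labels, length >= 1.
#' @param probability joint probability of directness in `[0, 1]`, or `NULL`.
#' @param total_weight nonnegative total path weight, or `NULL`.
#' @return an object of class `gene_path`.
#' @export
gene_path <- function(nodes, probability = NULL, total_weight = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a path needs at least one node")
  if (anyDuplicated(nodes)) stop("path is not simple: repeated node")
  if (!is.null(probability)) {
    stopifnot(length(probability) == 1L, probability >= 0, probability <= 1)
  }
  if (!is.null(total_weight)) {
    stopifnot(length(total_weight) == 1L, total_weight >= 0)
  }
  if (!is.null(probability) && !is.null(total_weight)) {
    if (abs(total_weight + log(probability)) > 1e-9) {
      stop("total_weight and -log(probability) disagree")
    }
  }
  structure(
    list(nodes = nodes, probability = probability,
         total_weight = total_weight),
    class = "gene_path"
  )
}

#' @export
print.gene_path <- function(x, ...) {
  cat(paste(x$nodes, collapse = " -> "))
  if (!is.null(x$probability)) {
    cat(sprintf("  [p = %.4g]", x$probability))
  }
  cat("\n")
  invisible(x)
}

#' Edges of a path as unordered pairs
#'
#' @param path a [gene_path()] or character vector of nodes.
#' @return character vector of canonical `"a|b"` edge keys (sorted
#'   endpoints); empty for single-node paths.
#' @export
path_edges <- function(path) {
  nodes <- if (inherits(path, "gene_path")) path$nodes else as.character(path)
  if (length(nodes) < 2L) return(character())
  a <- nodes[-length(nodes)]
  b <- nodes[-1L]
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
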