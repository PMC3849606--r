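#' Read an expression matrix from a TSV file
#'
#' The file format is tab-separated text with one header row of sample labels
#' and one leading column of gene labels (the first header cell is ignored),
#' the common microarray export shape. The transpose is accepted via
#' `orientation = "genes_in_columns"`.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @return a validated expression matrix (genes x samples).
#' @seealso [write_expression()], [as_expression_matrix()]
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows",
                                            "genes_in_columns")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(lines) < 2L) stop("no samples")
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncols <- length(header)
  labels <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncols - 1L)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncols) {
      stop(sprintf("row %d has %d fields, expected %d", i + 1L,
                   length(row), ncols))
    }
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row label '%s', column '%s'",
                   row[j + 1L], labels[i], header[j + 1L]))
    }
    vals[i, ] <- v
  }
  if (ncol(vals) == 0L) stop("no samples")
  rownames(vals) <- labels
  colnames(vals) <- header[-1L]
  if (orientation == "genes_in_columns") vals <- t(vals)
  as_expression_matrix(vals)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()] with genes in rows; round-trips labels and
#' values (to double-precision formatting).
#'
#' @param expr expression matrix with dimnames.
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  header <- paste(c("gene", colnames(expr)), collapse = "\t")
  rows <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i],
            formatC(expr[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a regulatory network from an edge-list file
#'
#' Accepts whitespace- or tab-delimited edge lists of two or three columns
#' (source, target, optional relation/weight column, ignored; this makes SIF
#' files with one target per row readable). Duplicate edges are collapsed;
#' self-loops are an error.
#'
#' @param path file path.
#' @param directed logical, stored on the returned network.
#' @return a [regulatory_network()].
#' @export
read_network <- function(path, directed = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(regulatory_network(matrix(character(), ncol = 2L),
                              directed = directed))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- vapply(fields, length, integer(1L))
  if (any(n < 2L)) {
    stop(sprintf("line %d: fewer than two fields", which(n < 2L)[1L]))
  }
  src <- vapply(fields, `[[`, character(1L), 1L)
  # three-column files put the target last (SIF convention); two-column files
  # put it second
  tgt <- mapply(function(f) if (length(f) >= 3L) f[[3L]] else f[[2L]],
                fields)
  loops <- src == tgt
  if (any(loops)) {
    stop(sprintf("line %d: self-loop on '%s'", which(loops)[1L],
                 src[which(loops)[1L]]))
  }
  regulatory_network(cbind(src, tgt), directed = directed)
}

#' Write a network as an edge list
#'
#' @param network a [regulatory_network()].
#' @param path output file path.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  writeLines(apply(network$edges, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Write ranked paths to TSV
#'
#' One row per path: root, target, the arrow-joined node sequence, the joint
#' probability of directness, and the total negative-log weight. Rows are
#' sorted by descending probability.
#'
#' @param paths list of [gene_path()] objects, each with a defined
#'   probability.
#' @param path output file path.
#' @export
write_paths <- function(paths, path) {
  header <- "root\ttarget\tpath\tprobability\ttotal_weight"
  if (!length(paths)) {
    writeLines(header, path)
    return(invisible(path))
  }
  probs <- vapply(paths, function(p) {
    if (is.null(p$probability)) stop("path without a probability")
    p$probability
  }, numeric(1L))
  paths <- paths[order(-probs)]
  rows <- vapply(paths, function(p) {
    w <- if (is.null(p$total_weight)) -log(p$probability) else p$total_weight
    paste(p$nodes[1L], p$nodes[length(p$nodes)],
          paste(p$nodes, collapse = "->"),
          formatC(p$probability, format = "g", digits = 12),
          formatC(w, format = "g", digits = 12),
          sep = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a labelled symmetric gene matrix (MI or probabilities) to TSV
#'
#' @param mat symmetric gene matrix.
#' @param path output file path.
#' @export
write_gene_matrix <- function(mat, path) {
  mat <- symmetric_gene_matrix(mat)
  header <- paste(c("gene", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 12)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a labelled symmetric gene matrix from TSV
#'
#' @param path file path.
#' @param check passed to [symmetric_gene_matrix()].
#' @return the matrix.
#' @export
read_gene_matrix <- function(path, check = "none") {
  x <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  symmetric_gene_matrix(as.matrix(x), check = check)
}
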