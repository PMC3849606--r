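make_expr <- function(values, genes = NULL) {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  as_expression_matrix(values, gene_ids = genes,
                       sample_ids = paste0("S", seq_len(ncol(values))))
}

test_that("permutation threshold is deterministic and a degenerate quantile", {
  set.seed(3)
  expr <- make_expr(matrix(rnorm(4 * 60), 4, 60))
  cfg <- aracne_config(n_permutations = 20, significance_alpha = 0.3,
                       seed = 11)
  t1 <- permutation_threshold(expr, cfg)
  t2 <- permutation_threshold(expr, cfg)
  expect_identical(t1, t2)
  expect_gte(t1, 0)

  cfg_min <- aracne_config(n_permutations = 20, significance_alpha = 1,
                           seed = 11)
  tmin <- permutation_threshold(expr, cfg_min)
  expect_lte(tmin, t1)
})

test_that("null threshold sits below the MI of a perfectly dependent pair", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  expr <- make_expr(rbind(x, rnorm(n), rnorm(n)))
  thr <- permutation_threshold(expr, aracne_config(n_permutations = 30,
                                                   significance_alpha = 0.3,
                                                   seed = 7))
  expect_gt(mi_pair(x, x), thr)
})

test_that("zero tolerance reduces ARACNe to DPI flags plus the threshold", {
  set.seed(19)
  for (i in 1:20) {
    mi <- rand_sym_matrix(6, lo = 0.01, hi = 1)
    net <- aracne_network(mi, threshold = 0, tolerance = 0)
    expect_identical(edge_keys(net), edge_keys(which_edges(dpi_classify(mi))))
  }
})

test_that("the tolerance margin spares near-minimal edges", {
  tri <- symmetric_gene_matrix(
    matrix(c(NA, 0.8, 0.59,
             0.8, NA, 0.6,
             0.59, 0.6, NA), 3, 3, byrow = TRUE),
    gene_ids = c("A", "B", "C"))
  # 0.59 >= 0.95 * min(0.8, 0.6) = 0.57, so the A-C edge survives
  expect_length(edge_keys(aracne_network(tri, 0, tolerance = 0.05)), 3L)
  expect_identical(edge_keys(aracne_network(tri, 0, tolerance = 0)),
                   c("A|B", "B|C"))

  strict <- symmetric_gene_matrix(
    matrix(c(NA, 0.8, 0.3,
             0.8, NA, 0.6,
             0.3, 0.6, NA), 3, 3, byrow = TRUE),
    gene_ids = c("A", "B", "C"))
  expect_identical(edge_keys(aracne_network(strict, 0, 0)), c("A|B", "B|C"))
})

test_that("threshold filter removes weak edges regardless of DPI", {
  tri <- symmetric_gene_matrix(
    matrix(c(NA, 0.8, 0.3,
             0.8, NA, 0.6,
             0.3, 0.6, NA), 3, 3, byrow = TRUE),
    gene_ids = c("A", "B", "C"))
  expect_identical(edge_keys(aracne_network(tri, threshold = 0.7)), "A|B")
})

test_that("MST picks the strongest spanning edges", {
  tri <- symmetric_gene_matrix(
    matrix(c(NA, 0.9, 0.1,
             0.9, NA, 0.8,
             0.1, 0.8, NA), 3, 3, byrow = TRUE),
    gene_ids = c("A", "B", "C"))
  expect_identical(edge_keys(mst_network(tri, "sub1")), c("A|B", "B|C"))
  expect_identical(edge_keys(mst_network(tri, "neglog")), c("A|B", "B|C"))
})

test_that("both MST transforms give the same tree on all-positive MI", {
  set.seed(31)
  for (i in 1:20) {
    mi <- rand_sym_matrix(7, lo = 0.01, hi = 2)
    expect_identical(edge_keys(mst_network(mi, "sub1")),
                     edge_keys(mst_network(mi, "neglog")))
  }
})

test_that("MST spans with n-1 edges and minimal total weight", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:10) {
    n <- 8
    mi <- rand_sym_matrix(n, lo = 0.01, hi = 1)
    tree <- mst_network(mi, "sub1")
    expect_equal(nrow(tree$edges), n - 1L)
    w <- 1 - mi / max(mi, na.rm = TRUE)
    got <- sum(w[tree$edges])
    adj <- w
    adj[is.na(adj)] <- 0
    g <- igraph::graph_from_adjacency_matrix(adj + 1, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ref <- sum(igraph::E(igraph::mst(g))$weight) - (n - 1)
    expect_equal(got, ref, tolerance = 1e-9)
  }
  expect_error(mst_network(matrix(c(NA, 0, 0, NA), 2, 2,
                                  dimnames = list(c("A", "B"), c("A", "B")))),
               "all-zero")
})

test_that("unit-weight extraction equals BFS hop counts", {
  chain <- regulatory_network(rbind(c("A", "B"), c("B", "C")))
  expect_identical(extract_path(chain, "A", "C")$nodes, c("A", "B", "C"))

  disc <- regulatory_network(rbind(c("A", "B"), c("C", "D")))
  expect_null(extract_path(disc, "A", "D"))
  expect_error(extract_path(chain, "A", "Z"), "unknown")

  set.seed(39)
  for (i in 1:20) {
    n <- 8
    genes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    if (!any(keep)) next
    net <- regulatory_network(pairs[keep, , drop = FALSE], genes = genes,
                              directed = FALSE)
    hops <- bfs_hops(net, "N01")
    for (t in setdiff(genes, "N01")) {
      p <- extract_path(net, "N01", t)
      if (is.null(p)) {
        expect_false(is.finite(hops[[t]]))
      } else {
        expect_equal(length(p$nodes) - 1, hops[[t]])
      }
    }
  }
})

test_that("comparators accept bootstrap-aggregated MI", {
  set.seed(15)
  cfg <- sim_config(n_genes = 5, n_samples = 100, seed = 15)
  expr <- simulate_expression(generate_network(cfg), cfg)
  agg <- aggregate_mi(bootstrap_mi(expr, n_boot = 20, seed = 2), "mean")
  expect_s3_class(aracne_network(agg, threshold = 0.05), "regulatory_network")
  tree <- mst_network(agg, "sub1")
  expect_equal(nrow(tree$edges), 4L)
})
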