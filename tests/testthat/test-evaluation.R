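test_that("true path is the fewest-hop route through the undirected truth", {
  chain <- regulatory_network(rbind(c("A", "B"), c("B", "C")))
  expect_identical(true_path(chain, "A", "C")$nodes, c("A", "B", "C"))
  # direction is ignored
  expect_identical(true_path(chain, "C", "A")$nodes, c("C", "B", "A"))
  disc <- regulatory_network(rbind(c("A", "B"), c("C", "D")))
  expect_null(true_path(disc, "A", "C"))

  set.seed(47)
  for (i in 1:10) {
    genes <- sprintf("N%02d", 1:7)
    pairs <- t(combn(genes, 2))
    net <- regulatory_network(pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE],
                              genes = genes)
    hops <- bfs_hops(net, "N01")
    for (t in setdiff(genes, "N01")) {
      p <- true_path(net, "N01", t)
      if (is.null(p)) expect_false(is.finite(hops[[t]]))
      else expect_equal(length(p$nodes) - 1, hops[[t]])
    }
  }
})

test_that("path scores follow the stated edge and node conventions", {
  s <- score_path(gene_path(c("A", "B", "C")), gene_path(c("A", "B", "D")),
                  "edge")
  expect_equal(c(s$tp, s$fp, s$fn), c(1, 1, 1))
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.5)

  same <- gene_path(c("A", "B", "C"))
  for (level in c("edge", "node")) {
    s <- score_path(same, same, level)
    expect_equal(s$precision, 1)
    expect_equal(s$recall, 1)
  }

  # endpoints excluded node-wise; levels diverge by design
  s_node <- score_path(gene_path(c("A", "X", "D")),
                       gene_path(c("A", "B", "C", "D")), "node")
  expect_equal(c(s_node$tp, s_node$fp, s_node$fn), c(0, 1, 2))
  expect_equal(s_node$precision, 0)
  expect_equal(s_node$recall, 0)
  s_edge <- score_path(gene_path(c("A", "X", "D")),
                       gene_path(c("A", "B", "C", "D")), "edge")
  expect_equal(s_edge$fp, 2)

  # tp + fn equals the number of true items at the chosen level
  set.seed(51)
  genes <- letters[1:8]
  for (i in 1:10) {
    inf <- gene_path(sample(genes, sample(2:6, 1)))
    tru <- gene_path(sample(genes, sample(2:6, 1)))
    for (level in c("edge", "node")) {
      s <- score_path(inf, tru, level)
      n_true <- if (level == "edge") length(tru$nodes) - 1 else
        max(0, length(tru$nodes) - 2)
      expect_equal(s$tp + s$fn, n_true)
      expect_gte(s$precision, 0)
      expect_lte(s$precision, 1)
      expect_gte(s$recall, 0)
      expect_lte(s$recall, 1)
    }
  }
})

test_that("cyclicity is the back-edge fraction of a directed DFS", {
  dag <- regulatory_network(rbind(c("A", "B"), c("A", "C"), c("B", "D"),
                                  c("C", "D")))
  expect_equal(cyclicity(dag), 0)

  for (n in 3:8) {
    genes <- paste0("V", seq_len(n))
    cyc <- regulatory_network(cbind(genes, genes[c(2:n, 1)]))
    expect_equal(cyclicity(cyc), 1 / n)
  }

  empty <- regulatory_network(matrix(character(), ncol = 2),
                              genes = c("A", "B"))
  expect_equal(cyclicity(empty), 0)

  set.seed(53)
  cfg <- sim_config(n_genes = 12, topology = "tree", seed = 9)
  expect_equal(cyclicity(generate_network(cfg)), 0)
})

test_that("random baseline respects the longest-true-path cap and the seed", {
  chain <- regulatory_network(rbind(c("A", "B")), genes = c("A", "B", "C"))
  base <- random_baseline(chain, seed = 4)
  # L_max = 1: every baseline path is the direct root-target edge
  expect_true(all(vapply(base, function(p) length(p$nodes) == 2, logical(1))))
  expect_identical(random_baseline(chain, seed = 4), base)

  # intermediates are drawn from the supplied pool, never the endpoints
  chain3 <- regulatory_network(rbind(c("A", "B"), c("B", "C")))
  pool <- c("A", "B", "C", "X", "Y")
  for (s in 1:5) {
    b <- random_baseline(chain3, gene_ids = pool, seed = s)
    for (p in b) {
      mids <- p$nodes[-c(1, length(p$nodes))]
      expect_true(all(mids %in% pool))
      expect_false(p$nodes[1] %in% mids || p$nodes[length(p$nodes)] %in% mids)
    }
  }
})

test_that("baseline path lengths are uniform on 1..L_max", {
  chain4 <- regulatory_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  lens <- integer()
  for (s in 1:850) {
    b <- random_baseline(chain4, seed = s)
    lens <- c(lens, vapply(b, function(p) length(p$nodes) - 1L, integer(1)))
  }
  expect_gte(length(lens), 10000)
  tab <- table(factor(lens, levels = 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("probability/performance correlation handles the stated edge cases", {
  mk_tab <- function(prob, perf) {
    data.frame(root = "A", target = "B", true_length = 2, probability = prob,
               level = "edge", tp = 1, fp = 0, fn = 0,
               precision = perf, recall = perf)
  }
  tab <- mk_tab(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(as.numeric(probability_performance_correlation(tab)), 1.0)

  anti <- mk_tab(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1))
  expect_equal(as.numeric(probability_performance_correlation(anti)), -1.0)

  const <- mk_tab(c(0.1, 0.5, 0.9), c(0.4, 0.4, 0.4))
  r <- probability_performance_correlation(const)
  expect_true(is.nan(r))
  expect_false(attr(r, "defined"))

  expect_error(probability_performance_correlation(mk_tab(0.5, 0.5)),
               "at least 3")
})

test_that("evaluation reports only pairs with true paths of 2+ edges", {
  truth <- regulatory_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  paths <- list(
    gene_path(c("A", "B"), probability = 0.9, total_weight = -log(0.9)),
    gene_path(c("A", "C"), probability = 0.5, total_weight = -log(0.5)),
    gene_path(c("A", "B", "C", "D"), probability = 0.4,
              total_weight = -log(0.4))
  )
  ev <- evaluate_paths(paths, truth)
  # A->B has a single-edge true path and is excluded
  expect_setequal(unique(ev$table$target), c("C", "D"))
  expect_equal(ev$cyclicity, 0)
  e <- ev$table[ev$table$level == "edge" & ev$table$target == "D", ]
  expect_equal(e$precision, 1)
  expect_equal(e$recall, 1)
})
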