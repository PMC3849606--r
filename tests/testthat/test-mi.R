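# Direct plug-in evaluation of MI from a joint count table, used as the
# independent oracle for the binned estimator.
plugin_mi <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

test_that("independent samples give MI near zero", {
  set.seed(101)
  x <- runif(10000)
  y <- runif(10000)
  expect_lte(mi_pair(x, y, mi_config("eqfreq", n_bins = 10)), 0.02)
})

test_that("identical vectors give MI equal to the binned marginal entropy", {
  set.seed(7)
  x <- rnorm(100)  # 100 divisible by 10 bins
  expect_equal(mi_pair(x, x, mi_config("eqfreq", n_bins = 10)), log(10),
               tolerance = 1e-9)
})

test_that("estimator reproduces the hand plug-in sum on a 2x2 count table", {
  # joint counts [5,5; 0,10], n = 20, realised with equal-width 2-bin cuts
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 5), rep(1, 5), rep(1, 10))
  got <- mi_pair(x, y, mi_config("eqwidth", n_bins = 2))
  expect_equal(got, plugin_mi(matrix(c(5, 0, 5, 10), 2, 2)), tolerance = 1e-12)
})

test_that("plug-in estimate matches closed-form MI on exact empirical tables", {
  # dependent 2x2 table [15,5; 5,15]
  x <- rep(c(0, 0, 1, 1), times = c(15, 5, 5, 15))
  y <- rep(c(0, 1, 0, 1), times = c(15, 5, 5, 15))
  closed <- plugin_mi(matrix(c(15, 5, 5, 15), 2, 2))
  expect_equal(mi_pair(x, y, mi_config("eqwidth", n_bins = 2)), closed,
               tolerance = 1e-9)
  # exactly independent table -> MI exactly 0
  x <- rep(c(0, 0, 1, 1), times = 10)
  y <- rep(c(0, 1, 0, 1), times = 10)
  expect_equal(mi_pair(x, y, mi_config("eqwidth", n_bins = 2)), 0)
})

test_that("MI is symmetric, nonnegative, and zero for constant vectors", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(50)
    y <- if (i %% 2) rnorm(50) else x + rnorm(50, sd = 0.3)
    expect_identical(mi_pair(x, y), mi_pair(y, x))
    expect_gte(mi_pair(x, y), 0)
  }
  expect_identical(mi_pair(rep(1, 50), rnorm(50)), 0)
  expect_error(mi_pair(rnorm(10), rnorm(11)), "equal length")
})

test_that("duplicating every sample leaves equal-width estimates unchanged", {
  set.seed(3)
  x <- rnorm(60)
  y <- x + rnorm(60, sd = 0.5)
  cfg <- mi_config("eqwidth", n_bins = 6)
  expect_equal(mi_pair(rep(x, 2), rep(y, 2), cfg), mi_pair(x, y, cfg),
               tolerance = 1e-12)
})

test_that("MI matrix is symmetric and invariant to joint sample permutation", {
  set.seed(21)
  expr <- as_expression_matrix(matrix(rnorm(3 * 40), 3, 40,
    dimnames = list(paste0("G", 1:3), paste0("S", 1:40))))
  m <- mi_matrix(expr)
  expect_true(all(is.na(diag(m))))
  expect_identical(m, t(m))
  perm <- sample(40)
  expect_equal(mi_matrix(expr[, perm]), m, tolerance = 1e-12)
})

test_that("bootstrap MI is reproducible and degenerates sensibly", {
  set.seed(5)
  expr <- as_expression_matrix(matrix(rnorm(3 * 30), 3, 30,
    dimnames = list(paste0("G", 1:3), paste0("S", 1:30))))
  b1 <- bootstrap_mi(expr, n_boot = 5, seed = 99)
  b2 <- bootstrap_mi(expr, n_boot = 5, seed = 99)
  expect_identical(b1, b2)
  expect_length(b1, 5L)
  # aggregation with one matrix reproduces it exactly
  expect_identical(aggregate_mi(b1[1], "mean"), b1[[1]])
  expect_identical(aggregate_mi(b1[1], "median"), b1[[1]])
})

test_that("bootstrap mean MI separates dependent from independent pairs", {
  set.seed(31)
  n <- 200
  a <- rnorm(n)
  expr <- as_expression_matrix(
    rbind(A = a, B = tanh(1.5 * a) + rnorm(n, sd = 0.5), C = rnorm(n)),
    sample_ids = paste0("S", seq_len(n)))
  m <- aggregate_mi(bootstrap_mi(expr, n_boot = 50, seed = 1), "mean")
  expect_gt(m["A", "B"], m["A", "C"])
})

test_that("aggregation arithmetic is element-wise mean/median", {
  mk <- function(v) symmetric_gene_matrix(
    matrix(c(NA, v, v, NA), 2, 2), gene_ids = c("A", "B"))
  mats <- lapply(c(0.1, 0.3, 0.8), mk)
  expect_equal(aggregate_mi(mats, "mean")["A", "B"], 0.4)
  expect_equal(aggregate_mi(mats, "median")["A", "B"], 0.3)
  expect_error(aggregate_mi(list(), "mean"), "empty")
  agg <- aggregate_mi(mats, "mean")
  expect_identical(agg, t(agg))
})

test_that("auto bin count is floor(sqrt(n)) clamped to [2, n]", {
  set.seed(13)
  x <- rnorm(100)
  expect_identical(mi_pair(x, x, mi_config("eqfreq", "auto")),
                   mi_pair(x, x, mi_config("eqfreq", n_bins = 10)))
  expect_error(mi_config(n_bins = 1), "n_bins")
})
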