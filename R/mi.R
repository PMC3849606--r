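#' Mutual information estimator configuration
#'
#' Controls the plug-in (binned) mutual information estimator. The default is
#' equal-frequency (quantile) binning with `floor(sqrt(n))` bins, which is
#' robust to monotone transforms of the expression scale and standard in
#' MI-based network inference. Ties at quantile boundaries are broken by the
#' stable rank order of the sample index, so estimates are deterministic.
#' Values are reported in nats (natural log) by default; only the relative
#' ordering of MI values matters for the data processing inequality, but the
#' base must be fixed.
#'
#' @param estimator `"eqfreq"` (equal-frequency/quantile binning) or
#'   `"eqwidth"` (equal-width binning).
#' @param n_bins positive integer >= 2, or `"auto"` for
#'   `floor(sqrt(n_samples))` clamped to `[2, n_samples]`.
#' @param base logarithm base; `exp(1)` for nats.
#' @return an object of class `mi_config`.
#' @export
mi_config <- function(estimator = c("eqfreq", "eqwidth"),
                      n_bins = "auto", base = exp(1)) {
  estimator <- match.arg(estimator)
  if (!identical(n_bins, "auto")) {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2 or \"auto\"")
  }
  stopifnot(is.numeric(base), base > 1)
  structure(list(estimator = estimator, n_bins = n_bins, base = base),
            class = "mi_config")
}

resolve_bins <- function(config, n) {
  if (identical(config$n_bins, "auto")) {
    max(2L, min(as.integer(floor(sqrt(n))), n))
  } else {
    config$n_bins
  }
}

# Assign each value to a bin index in 1..nb. Equal-frequency binning sorts
# with ties broken by sample index and fills bins to equal depth; equal-width
# binning cuts the observed range into nb equal intervals.
bin_vector <- function(x, nb, estimator) {
  n <- length(x)
  if (estimator == "eqfreq") {
    ord <- order(x, seq_len(n))
    b <- integer(n)
    b[ord] <- as.integer(floor((seq_len(n) - 1L) * nb / n)) + 1L
    b
  } else {
    r <- range(x)
    w <- (r[2L] - r[1L]) / nb
    pmin.int(as.integer(floor((x - r[1L]) / w)) + 1L, nb)
  }
}

# Plug-in MI (in units of log base `base`) from two bin-index vectors.
mi_from_bins <- function(bx, by, nbx, nby, base) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * nby + by, nbins = nbx * nby) / n
  px <- tabulate(bx, nbins = nbx) / n
  py <- tabulate(by, nbins = nby) / n
  jm <- matrix(joint, nrow = nbx, ncol = nby, byrow = TRUE)
  nz <- jm > 0
  denom <- outer(px, py)
  val <- sum(jm[nz] * (log(jm[nz]) - log(denom[nz]))) / log(base)
  max(val, 0)
}

#' Estimate mutual information between two sample vectors
#'
#' Discrete plug-in estimate of \eqn{I(X;Y) = \sum p(x,y)
#' \log[p(x,y)/(p(x)p(y))]} on binned data. The estimate is symmetric in its
#' arguments and clamped at zero against negative rounding. A constant vector
#' has zero marginal entropy, so the MI is 0 (not an error).
#'
#' @param x,y numeric vectors of equal length `n >= 4` with finite values.
#' @param config an [mi_config()].
#' @return nonnegative MI estimate.
#' @examples
#' set.seed(1)
#' mi_pair(rnorm(100), rnorm(100))          # near 0
#' x <- rnorm(100); mi_pair(x, x)           # near log(10)
#' @export
mi_pair <- function(x, y, config = mi_config()) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  }
  n <- length(x)
  if (n < 4L) stop("need at least 4 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (min(x) == max(x) || min(y) == max(y)) return(0)
  nb <- resolve_bins(config, n)
  mi_from_bins(bin_vector(x, nb, config$estimator),
               bin_vector(y, nb, config$estimator),
               nb, nb, config$base)
}

# Bin every gene once, then compute all pairwise MIs from the bin indices.
mi_matrix_from_values <- function(values, config) {
  g <- nrow(values)
  n <- ncol(values)
  nb <- resolve_bins(config, n)
  bins <- matrix(0L, nrow = g, ncol = n)
  const <- logical(g)
  for (i in seq_len(g)) {
    xi <- values[i, ]
    if (min(xi) == max(xi)) {
      const[i] <- TRUE
    } else {
      bins[i, ] <- bin_vector(xi, nb, config$estimator)
    }
  }
  out <- matrix(NA_real_, g, g, dimnames = list(rownames(values),
                                                rownames(values)))
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      v <- if (const[i] || const[j]) 0 else {
        mi_from_bins(bins[i, ], bins[j, ], nb, nb, config$base)
      }
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Pairwise mutual information matrix
#'
#' Estimates MI for every gene pair of an expression matrix. The diagonal is
#' left `NA`: self-information is never used in triplet comparisons.
#'
#' @param expr expression matrix (genes x samples) with >= 2 genes.
#' @param config an [mi_config()].
#' @return symmetric gene matrix of MI estimates with `NA` diagonal.
#' @export
mi_matrix <- function(expr, config = mi_config()) {
  expr <- as_expression_matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  mi_matrix_from_values(expr, config)
}

#' Bootstrap replicate MI matrices
#'
#' Draws `n_boot` resamples of the samples (columns) with replacement —
#' jointly across genes, since a sample is the exchangeable unit — and
#' computes the full MI matrix on each resample. The list of matrices
#' approximates the sampling distribution of the pairwise MI estimates.
#'
#' @param expr expression matrix.
#' @param config an [mi_config()].
#' @param n_boot number of bootstrap rounds, >= 1.
#' @param seed integer seed; the same seed reproduces the same list.
#' @return list of `n_boot` symmetric MI matrices.
#' @export
bootstrap_mi <- function(expr, config = mi_config(), n_boot = 100L,
                         seed = 1L) {
  expr <- as_expression_matrix(expr)
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  n <- ncol(expr)
  with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      mi_matrix_from_values(expr[, idx, drop = FALSE], config)
    })
  })
}

#' Aggregate bootstrap MI matrices
#'
#' Element-wise mean or median across bootstrap rounds. The aggregate is a
#' robustified MI estimate that the comparison methods (ARACNe, MST) can use
#' in place of the single full-data estimate, trading some sensitivity for
#' resistance to outlying resamples.
#'
#' @param matrices nonempty list of MI matrices over the same genes.
#' @param method `"mean"` or `"median"`.
#' @return one symmetric MI matrix.
#' @export
aggregate_mi <- function(matrices, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!length(matrices)) stop("empty list of matrices")
  ref <- dimnames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(dimnames(m), ref)) stop("gene sets differ across matrices")
  }
  arr <- array(unlist(matrices, use.names = FALSE),
               dim = c(dim(matrices[[1L]]), length(matrices)))
  f <- if (method == "mean") function(v) mean(v) else function(v) stats::median(v)
  out <- apply(arr, c(1L, 2L), f)
  dimnames(out) <- ref
  out
}
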