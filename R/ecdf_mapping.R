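#' Empirical CDF of a sample
#'
#' Standard right-continuous step eCDF. A constant vector is rejected
#' because a zero range leaves the smoothing bandwidth undefined downstream.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with sorted `support`, cumulative `prob`, `n`, and the step
#'   function `fun` (from [stats::ecdf()]).
#' @export
build_ecdf <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) {
    stop("need at least 2 distinct finite values (constant vector has zero range)")
  }
  f <- stats::ecdf(values)
  support <- sort(unique(values))
  list(support = support, prob = f(support), n = length(values), fun = f)
}

#' Gaussian-kernel smoothed CDF
#'
#' The step eCDF is smoothed by Nadaraya-Watson kernel regression of the
#' mid-rank cumulative probabilities on a regular grid, with a Gaussian
#' kernel whose bandwidth is a fixed fraction (default 1%) of the sample
#' range, then isotonized (running maximum) so the result is a proper
#' monotone CDF that can be inverted one-to-one.
#'
#' @param values Numeric sample (>= 2 distinct values).
#' @param bandwidth_frac Bandwidth as a fraction of the range (default 0.01).
#' @param grid_n Grid size (default 512).
#' @return List with `grid`, `cdf` (values in \[0,1\], strictly increasing up
#'   to numerical ties broken by a negligible ramp), `bandwidth`, `n`.
#' @export
smooth_cdf <- function(values, bandwidth_frac = 0.01, grid_n = 512) {
  values <- sort(values[is.finite(values)])
  n <- length(values)
  if (length(unique(values)) < 2) stop("constant vector: zero range")
  rng <- range(values)
  bw <- bandwidth_frac * diff(rng)
  # mid-rank probabilities avoid pinning the extremes to exactly 0/1
  p <- (seq_len(n) - 0.5) / n
  grid <- seq(rng[1] - 3 * bw, rng[2] + 3 * bw, length.out = grid_n)
  sm <- vapply(grid, function(g) {
    lw <- -0.5 * ((g - values) / bw)^2   # Gaussian kernel, log scale
    w <- exp(lw - max(lw))               # safe at very small bandwidths
    sum(w * p) / sum(w)
  }, numeric(1))
  sm <- pmin(pmax(cummax(sm), 0), 1)
  # strictly increasing for invertibility (negligible ramp)
  sm <- sm + seq(0, 1e-9, length.out = grid_n)
  list(grid = grid, cdf = sm, bandwidth = bw, n = n)
}

#' Consensus protein CDF pooled across cohorts
#'
#' Percentage-extent values from several cohorts are pooled into one sample
#' and smoothed at a bandwidth of `bandwidth_frac` of the pooled range,
#' giving the benchmark distribution that mRNA percentiles are inverted
#' through.
#'
#' @param cohorts List of numeric vectors (per-cohort extents, %), or a
#'   single numeric vector.
#' @param bandwidth_frac Bandwidth fraction (default 0.01).
#' @return A smoothed CDF as returned by [smooth_cdf()], with `n` the pooled
#'   sample size.
#' @export
consensus_protein_cdf <- function(cohorts, bandwidth_frac = 0.01) {
  pooled <- if (is.list(cohorts)) unlist(cohorts, use.names = FALSE) else cohorts
  smooth_cdf(pooled, bandwidth_frac = bandwidth_frac)
}

# Evaluate a smoothed CDF at x (linear interpolation, clamped to [0,1]).
eval_scdf <- function(scdf, x) {
  stats::approx(scdf$grid, scdf$cdf, xout = x, rule = 2)$y
}

# Invert a smoothed CDF at probability p (lowest matching grid point on
# exact ties, via linear interpolation on the strictly monotone grid).
invert_scdf <- function(scdf, p) {
  stats::approx(scdf$cdf, scdf$grid, xout = pmin(pmax(p, min(scdf$cdf)),
                                                 max(scdf$cdf)))$y
}

#' Map mRNA values onto protein percentage extents by percentile matching
#'
#' Each sample's mRNA value is converted to a percentile under the smoothed
#' eCDF of its own dataset, and that percentile is inverted through the
#' smoothed consensus protein CDF, yielding an inferred percentage extent.
#' The mapping is monotone and is performed independently per mRNA dataset
#' to mitigate batch effects.
#'
#' @param mrna Numeric vector of expression values for one marker in one
#'   dataset (non-constant).
#' @param protein_cdf Smoothed consensus protein CDF ([consensus_protein_cdf()]).
#' @param bandwidth_frac Bandwidth fraction for the mRNA eCDF smoothing.
#' @return Numeric vector of inferred extents, clamped to \[0, 100\].
#' @export
map_mrna_to_extent <- function(mrna, protein_cdf, bandwidth_frac = 0.01) {
  if (length(unique(mrna[is.finite(mrna)])) < 2) {
    stop("mRNA vector is constant; percentile mapping is undefined")
  }
  mrna_cdf <- smooth_cdf(mrna, bandwidth_frac = bandwidth_frac)
  p <- eval_scdf(mrna_cdf, mrna)
  pmin(pmax(invert_scdf(protein_cdf, p), 0), 100)
}

#' Inferred subpopulation metrics from marker mRNA
#'
#' Maps MYC, BCL2 and BCL6 mRNA vectors onto inferred percentage extents via
#' their consensus protein CDFs, then composes the probabilistic
#' independence prediction ([predict_profile()]) per sample — yielding e.g.
#' the M+2+6- metric.
#'
#' @param expr Genes x samples numeric matrix containing the marker rows.
#' @param protein_cdfs Named list `MYC`/`BCL2`/`BCL6` of smoothed consensus
#'   protein CDFs.
#' @param marker_rows Named character vector mapping markers to row names of
#'   `expr` (default identity: `c(MYC = "MYC", ...)`).
#' @param bandwidth_frac Bandwidth fraction for mRNA smoothing.
#' @return Data frame: `sample_id`, inferred marginals `pM`, `p2`, `p6` (%),
#'   and the eight predicted pattern extents. Samples with a missing value
#'   in any marker are excluded with a warning.
#' @export
inferred_metric <- function(expr, protein_cdfs,
                            marker_rows = c(MYC = "MYC", BCL2 = "BCL2", BCL6 = "BCL6"),
                            bandwidth_frac = 0.01) {
  stopifnot(all(c("MYC", "BCL2", "BCL6") %in% names(protein_cdfs)))
  missing_rows <- setdiff(unname(marker_rows), rownames(expr))
  if (length(missing_rows)) {
    stop("marker row(s) absent from expression matrix: ",
         paste(missing_rows, collapse = ", "))
  }
  samples <- colnames(expr)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(expr)))
  complete <- stats::complete.cases(t(expr[marker_rows, , drop = FALSE]))
  if (!all(complete)) {
    warning(sum(!complete), " sample(s) missing a marker value excluded")
  }
  sub <- expr[, complete, drop = FALSE]
  mapped <- vapply(c("MYC", "BCL2", "BCL6"), function(m) {
    map_mrna_to_extent(sub[marker_rows[[m]], ], protein_cdfs[[m]],
                       bandwidth_frac = bandwidth_frac)
  }, numeric(ncol(sub)))
  mapped <- matrix(mapped, ncol = 3,
                   dimnames = list(NULL, c("MYC", "BCL2", "BCL6")))
  out <- data.frame(sample_id = samples[complete],
                    pM = mapped[, "MYC"], p2 = mapped[, "BCL2"],
                    p6 = mapped[, "BCL6"],
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, predict_profile(out$pM, out$p2, out$p6))
}

#' Read a genes x samples expression matrix from TSV
#' @param path TSV path (first column = gene IDs).
#' @return Numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
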