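#' Gene-wise Spearman correlation with the M+2+6- metric
#'
#' Per-gene Spearman rho between (standardized) expression and a per-sample
#' metric, with Fisher-z 95% confidence intervals and z-based p values.
#' Genes with constant expression are reported with `NA` (undefined) and are
#' excluded from pooling downstream.
#'
#' @param expr Genes x samples numeric matrix (>= 10 samples).
#' @param metric Numeric metric per sample, aligned with `expr` columns.
#' @return Data frame: `gene_id`, `rho`, `ci95_lo`, `ci95_hi`, `p`, `n`.
#' @export
gene_metric_correlation <- function(expr, metric) {
  if (ncol(expr) != length(metric)) {
    stop("metric is not aligned with the expression matrix columns")
  }
  n <- length(metric)
  if (n < 10) stop("at least 10 samples are required")
  rk_metric <- rank(metric)
  rk <- t(apply(expr, 1, rank))
  rho <- as.numeric(suppressWarnings(stats::cor(t(rk), rk_metric)))
  rho[apply(expr, 1, stats::sd) == 0 | stats::sd(metric) == 0] <- NA_real_
  z <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
  se_z <- 1 / sqrt(n - 3)
  data.frame(gene_id = rownames(expr),
             rho = rho,
             ci95_lo = tanh(z - 1.96 * se_z),
             ci95_hi = tanh(z + 1.96 * se_z),
             p = 2 * stats::pnorm(-abs(z / se_z)),
             n = n, stringsAsFactors = FALSE)
}

#' Pool per-cohort gene correlations and call hits
#'
#' Per-cohort Spearman correlations are pooled per gene on the Fisher-z
#' scale with the Paule-Mandel random-effects model (reusing
#' [pool_random_effects()]), p values are adjusted by Benjamini-Hochberg
#' across genes, and hits are genes with |pooled rho| >= `rho_min` and
#' FDR <= `fdr_max`.
#'
#' @param tables List of [gene_metric_correlation()] outputs (one per cohort).
#' @param min_cohorts Minimum cohorts a gene must appear in (default 2).
#' @param rho_min,fdr_max Hit thresholds (defaults 0.2 and 0.001).
#' @return Data frame: `gene_id`, `pooled_rho`, `pooled_p`, `fdr`, `is_hit`,
#'   `k` (cohorts pooled).
#' @export
pool_gene_correlations <- function(tables, min_cohorts = 2,
                                   rho_min = 0.2, fdr_max = 0.001) {
  long <- do.call(rbind, lapply(tables, function(t) t[!is.na(t$rho), ]))
  rows <- lapply(split(long, long$gene_id), function(g) {
    if (nrow(g) < min_cohorts) return(NULL)
    z <- atanh(pmin(pmax(g$rho, -1 + 1e-12), 1 - 1e-12))
    fits <- data.frame(log_hr = z, se = 1 / sqrt(g$n - 3))
    pooled <- pool_random_effects(fits, n_hypotheses = 1)
    data.frame(gene_id = g$gene_id[1],
               pooled_rho = tanh(pooled$pooled_log_hr),
               pooled_p = pooled$pooled_p, k = nrow(g),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene present in enough cohorts")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$pooled_p, method = "BH")
  out$is_hit <- abs(out$pooled_rho) >= rho_min & out$fdr <= fdr_max
  out
}

#' Assign an expression status to single cells from counts
#'
#' Each cell is called positive for a marker when its count exceeds the
#' marker's threshold (default 0, i.e. any detected count), labeled with
#' the corresponding MYC/BCL2/BCL6 pattern, and contrasted as M+2+6- versus
#' all others.
#'
#' @param counts Genes x cells matrix (dense or `Matrix` sparse) with marker
#'   rows present.
#' @param marker_rows Named character vector mapping `MYC`/`BCL2`/`BCL6` to
#'   row names.
#' @param thresholds Named numeric vector of count thresholds per marker
#'   (default 0 for each; positivity is count > threshold).
#' @return Data frame: `cell_id`, the three positivity flags, `pattern`,
#'   `group` (`"M+2+6-"` or `"other"`).
#' @export
sc_assign_status <- function(counts,
                             marker_rows = c(MYC = "MYC", BCL2 = "BCL2", BCL6 = "BCL6"),
                             thresholds = c(MYC = 0, BCL2 = 0, BCL6 = 0)) {
  missing_rows <- setdiff(unname(marker_rows), rownames(counts))
  if (length(missing_rows)) {
    stop("marker row(s) absent from count matrix: ",
         paste(missing_rows, collapse = ", "))
  }
  get_row <- function(m) as.numeric(counts[marker_rows[[m]], ])
  myc <- get_row("MYC") > thresholds[["MYC"]]
  bcl2 <- get_row("BCL2") > thresholds[["BCL2"]]
  bcl6 <- get_row("BCL6") > thresholds[["BCL6"]]
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("cell", seq_along(myc))
  pattern <- label_subpopulation(myc, bcl2, bcl6)
  data.frame(cell_id = ids, myc_pos = myc, bcl2_pos = bcl2, bcl6_pos = bcl6,
             pattern = pattern,
             group = ifelse(pattern == "M+2+6-", "M+2+6-", "other"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Wilcoxon marker test between M+2+6- cells and all others
#'
#' Counts are normalized to counts-per-10k and log2(x+1)-transformed, then
#' each gene is compared between the two groups with a two-sided Wilcoxon
#' rank-sum test; `avg_log2FC` is the difference of group means on the log2
#' scale, and genes are flagged upregulated when `avg_log2FC > 0` and
#' `p < 0.05`.
#'
#' @param counts Genes x cells count matrix.
#' @param status [sc_assign_status()] output aligned with the columns.
#' @param normalize Set `FALSE` if `counts` is already log-normalized.
#' @return Data frame: `gene_id`, `avg_log2FC`, `p`, `upregulated`.
#' @export
sc_marker_test <- function(counts, status, normalize = TRUE) {
  stopifnot(ncol(counts) == nrow(status))
  in_group <- status$group == "M+2+6-"
  if (sum(in_group) < 3 || sum(!in_group) < 3) {
    stop("both groups need at least 3 cells")
  }
  m <- as.matrix(counts)
  if (normalize) {
    depth <- colSums(m)
    depth[depth == 0] <- 1
    m <- log2(sweep(m, 2, depth, "/") * 1e4 + 1)
  }
  p <- apply(m, 1, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::wilcox.test(g[in_group], g[!in_group], exact = FALSE)$p.value
  })
  fc <- rowMeans(m[, in_group, drop = FALSE]) -
    rowMeans(m[, !in_group, drop = FALSE])
  data.frame(gene_id = rownames(m), avg_log2FC = fc, p = p,
             upregulated = !is.na(p) & fc > 0 & p < 0.05,
             stringsAsFactors = FALSE)
}

#' Differential-expression hit criterion (pluggable)
#'
#' Default rule: FDR <= `fdr_sig`, optionally also requiring a minimum
#' absolute log2 fold change. A custom predicate `function(fdr, abs_log2fc)`
#' can be supplied and is applied verbatim, accommodating dynamic
#' significance curves in the FDR-fold-change plane.
#'
#' @param fdr_gene Per-gene FDR values in \[0, 1\].
#' @param abs_log2fc Per-gene absolute log2 fold changes (>= 0).
#' @param fdr_sig Significance threshold (default 0.05).
#' @param min_abs_log2fc Optional minimum |log2FC| (default 0, inactive).
#' @param criterion Optional custom predicate.
#' @return Logical vector of hits.
#' @export
de_hit_criterion <- function(fdr_gene, abs_log2fc, fdr_sig = 0.05,
                             min_abs_log2fc = 0, criterion = NULL) {
  if (any(!is.finite(fdr_gene)) || any(fdr_gene < 0 | fdr_gene > 1)) {
    stop("FDR values must lie in [0, 1]")
  }
  if (any(abs_log2fc < 0)) stop("absolute fold changes must be >= 0")
  if (!is.null(criterion)) return(criterion(fdr_gene, abs_log2fc))
  fdr_gene <= fdr_sig & abs_log2fc >= min_abs_log2fc
}

#' Read a sparse single-cell count matrix (MTX + barcodes + features)
#'
#' @param mtx,features,barcodes Paths to the MatrixMarket counts, the
#'   feature (gene) table and the barcode list.
#' @return Sparse `dgCMatrix` with gene row names and barcode column names.
#' @export
read_sc_counts <- function(mtx, features, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- utils::read.delim(features, header = FALSE, stringsAsFactors = FALSE)
  bc <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(nrow(feat) == nrow(m), nrow(bc) == ncol(m))
  rownames(m) <- feat[[min(2L, ncol(feat))]]  # gene symbol column if present
  colnames(m) <- bc[[1]]
  m
}
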