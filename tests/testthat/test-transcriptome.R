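test_that("gene-metric correlation recovers rank-identical genes", {
  set.seed(71)
  metric <- runif(40, 0, 30)
  expr <- rbind(G1 = rank(metric), G2 = rnorm(40), G3 = rep(1, 40))
  tab <- gene_metric_correlation(expr, metric)
  expect_equal(tab$rho[tab$gene_id == "G1"], 1)
  expect_true(is.na(tab$rho[tab$gene_id == "G3"]))
  expect_error(gene_metric_correlation(expr[, 1:39], metric), "aligned")
  expect_error(gene_metric_correlation(expr[, 1:5], metric[1:5]), "10 samples")
})

test_that("Spearman rho is invariant to monotone transforms", {
  set.seed(72)
  metric <- runif(50)
  g <- metric + rnorm(50, sd = 0.3)
  t1 <- gene_metric_correlation(rbind(G = g), metric)
  t2 <- gene_metric_correlation(rbind(G = exp(3 * g)), metric)
  expect_equal(t1$rho, t2$rho)
})

test_that("null genes rarely cross the |rho| 0.2 threshold at n = 200", {
  set.seed(73)
  metric <- runif(200)
  expr <- matrix(rnorm(200 * 200), 200, 200,
                 dimnames = list(sprintf("G%03d", 1:200), NULL))
  tab <- gene_metric_correlation(expr, metric)
  expect_gte(mean(abs(tab$rho) < 0.2), 0.95)
})

test_that("pooling identical correlations passes them through with hit calls", {
  tabs <- lapply(1:3, function(i) {
    data.frame(gene_id = c("A", "B"), rho = c(0.3, 0.05), n = 200)
  })
  pooled <- pool_gene_correlations(tabs)
  expect_equal(pooled$pooled_rho[pooled$gene_id == "A"], 0.3, tolerance = 1e-9)
  # hit rule: |rho| >= 0.2 AND fdr <= 0.001 must both hold
  expect_true(all(pooled$is_hit ==
                    (abs(pooled$pooled_rho) >= 0.2 & pooled$fdr <= 0.001)))
  expect_false(pooled$is_hit[pooled$gene_id == "B"])
  # a strong rho with a weak fdr is not a hit (few samples -> big p)
  weak <- lapply(1:2, function(i)
    data.frame(gene_id = "C", rho = 0.25, n = 12))
  expect_false(pool_gene_correlations(weak)$is_hit)
})

test_that("BH adjustment is monotone in the p values", {
  set.seed(74)
  p <- runif(100)
  fdr <- p.adjust(p, "BH")
  p2 <- p; p2[10] <- p2[10] / 10
  fdr2 <- p.adjust(p2, "BH")
  expect_lte(fdr2[10], fdr[10])
})

test_that("single-cell status assignment follows the count threshold rule", {
  counts <- matrix(c(2, 1, 0,   0, 0, 0), nrow = 3,
                   dimnames = list(c("MYC", "BCL2", "BCL6"), c("c1", "c2")))
  st <- sc_assign_status(counts)
  expect_identical(st$pattern, c("M+2+6-", "M-2-6-"))
  expect_identical(st$group, c("M+2+6-", "other"))
  # raising the MYC/BCL2 thresholds to >= 2 flips the first cell
  st2 <- sc_assign_status(counts, thresholds = c(MYC = 1, BCL2 = 1, BCL6 = 1))
  expect_identical(st2$pattern[1], "M+2-6-")
  expect_error(sc_assign_status(counts[1:2, , drop = FALSE]), "BCL6")
  # sparse input, one label per cell, groups partition cells
  sp <- Matrix::Matrix(counts, sparse = TRUE)
  st3 <- sc_assign_status(sp)
  expect_identical(st3$pattern, st$pattern)
})

test_that("wilcoxon marker test flags constructed upregulation", {
  set.seed(75)
  n_per <- 50
  counts <- rbind(
    MYC = c(rpois(n_per, 3), rpois(n_per, 3)),
    BCL2 = c(rpois(n_per, 3), rpois(n_per, 3)),
    BCL6 = c(rep(0, n_per), rpois(n_per, 3) + 1),
    TARGET = c(rpois(n_per, 8) + 1, rep(0, n_per)),
    FLAT = rpois(2 * n_per, 2)
  )
  colnames(counts) <- paste0("c", seq_len(2 * n_per))
  counts["MYC", ] <- pmax(counts["MYC", ], 1)
  counts["BCL2", ] <- pmax(counts["BCL2", ], 1)
  st <- sc_assign_status(counts)
  expect_true(all(st$group[1:n_per] == "M+2+6-"))
  res <- sc_marker_test(counts, st)
  expect_true(res$upregulated[res$gene_id == "TARGET"])
  expect_false(isTRUE(res$upregulated[res$gene_id == "FLAT"]))
  expect_error(sc_marker_test(counts[, 1:52], st[1:52, ]), "3 cells")
})

test_that("null genes are flagged upregulated at about the alpha rate", {
  set.seed(76)
  n <- 120
  counts <- matrix(rpois(300 * n, 4), nrow = 300,
                   dimnames = list(sprintf("G%03d", 1:300), NULL))
  status <- data.frame(group = rep(c("M+2+6-", "other"), each = n / 2))
  res <- sc_marker_test(counts, status)
  expect_lt(mean(res$upregulated, na.rm = TRUE), 0.10)
})

test_that("the DE hit criterion defaults and the plug-in contract hold", {
  expect_true(de_hit_criterion(0.01, 2))
  expect_false(de_hit_criterion(0.2, 2))
  expect_error(de_hit_criterion(1.5, 2), "\\[0, 1\\]")
  custom <- function(fdr, fc) fc > 1   # ignore fdr entirely
  expect_identical(de_hit_criterion(c(0.9, 0.9), c(2, 0.5), criterion = custom),
                   c(TRUE, FALSE))
})

test_that("sparse count matrices round-trip through MTX + annotation files", {
  set.seed(77)
  m <- Matrix::Matrix(matrix(rpois(60, 1), 6, 10), sparse = TRUE)
  dir <- withr::local_tempdir()
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  genes <- c("MYC", "BCL2", "BCL6", "A", "B", "C")
  write.table(cbind(paste0("ENSG", 1:6), genes),
              file.path(dir, "features.tsv"), sep = "\t",
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  write.table(paste0("BC", 1:10), file.path(dir, "barcodes.tsv"),
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  got <- read_sc_counts(file.path(dir, "counts.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"))
  expect_identical(rownames(got), genes)
  expect_identical(colnames(got), paste0("BC", 1:10))
  expect_equal(as.matrix(got), as.matrix(m), ignore_attr = TRUE)
  st <- sc_assign_status(got)
  expect_equal(nrow(st), 10)
})
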