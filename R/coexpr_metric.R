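#' Predict subpopulation extents from single-marker extents
#'
#' Under the assumption that MYC, BCL2 and BCL6 positivity are distributed
#' independently across cells, the expected extent of any of the eight
#' coexpression patterns is the product of the per-marker positive (or
#' negative) proportions. For example the M+2+6- prediction is
#' `pM/100 * p2/100 * (1 - p6/100) * 100`. Marginals are taken as
#' percentages, matching IHC scoring conventions.
#'
#' @param pM,p2,p6 Single-marker percentage extents in \[0, 100\]; vectors of
#'   equal length are accepted (one prediction per sample).
#' @return Data frame with one column per pattern (in [subpop_patterns()]
#'   order) holding predicted extents in %; rows sum to 100.
#' @export
predict_profile <- function(pM, p2, p6) {
  n <- max(length(pM), length(p2), length(p6))
  pM <- rep_len(pM, n); p2 <- rep_len(p2, n); p6 <- rep_len(p6, n)
  m <- cbind(pM, p2, p6)
  if (anyNA(m) || any(m < 0) || any(m > 100)) {
    stop("marginals must lie in [0, 100]")
  }
  f <- m / 100
  pats <- subpop_patterns()
  fl <- pattern_flags(pats)
  out <- sapply(seq_along(pats), function(j) {
    100 *
      (if (fl[j, "myc"])  f[, 1] else 1 - f[, 1]) *
      (if (fl[j, "bcl2"]) f[, 2] else 1 - f[, 2]) *
      (if (fl[j, "bcl6"]) f[, 3] else 1 - f[, 3])
  })
  out <- matrix(out, nrow = n, dimnames = list(NULL, pats))
  as.data.frame(out, check.names = FALSE)
}

#' Concordance of observed and independence-predicted extents
#'
#' For each of the eight patterns, the Spearman correlation across patients
#' between the observed extent and the extent predicted from that patient's
#' own single-marker marginals. High rho across patterns indicates that
#' coexpression in the cohort is close to stochastic/independent.
#'
#' @param profiles `profiles` data frame from [patient_extents()] (needs the
#'   8 pattern columns plus `pM`, `p2`, `p6`).
#' @return List with `rho` (named numeric, one per pattern; `NA` where the
#'   observed vector is constant) and `scatter` (long data frame of
#'   patient/pattern observed and predicted extents).
#' @export
concordance <- function(profiles) {
  if (nrow(profiles) < 3) stop("at least 3 patients are required")
  pats <- subpop_patterns()
  stopifnot(all(c(pats, "pM", "p2", "p6") %in% names(profiles)))
  pred <- predict_profile(profiles$pM, profiles$p2, profiles$p6)
  rho <- vapply(pats, function(p) {
    obs <- profiles[[p]]
    if (stats::sd(obs) == 0 || stats::sd(pred[[p]]) == 0) return(NA_real_)
    stats::cor(obs, pred[[p]], method = "spearman")
  }, numeric(1))
  scatter <- data.frame(
    patient_id = rep(profiles$patient_id, times = length(pats)),
    pattern = rep(pats, each = nrow(profiles)),
    observed = unlist(profiles[pats], use.names = FALSE),
    predicted = unlist(pred, use.names = FALSE)
  )
  list(rho = rho, scatter = scatter)
}

#' Pairwise Spearman correlation of single-marker extents across patients
#'
#' @param profiles Data frame with `pM`, `p2`, `p6` columns (percent).
#' @return Symmetric 3x3 matrix of Spearman rho with unit diagonal; entries
#'   involving a constant marginal are `NA`.
#' @export
marginal_correlations <- function(profiles) {
  if (nrow(profiles) < 3) stop("at least 3 patients are required")
  m <- as.matrix(profiles[, c("pM", "p2", "p6")])
  out <- diag(3)
  dimnames(out) <- list(c("MYC", "BCL2", "BCL6"), c("MYC", "BCL2", "BCL6"))
  for (i in 1:2) for (j in (i + 1):3) {
    out[i, j] <- out[j, i] <-
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) NA_real_
      else stats::cor(m[, i], m[, j], method = "spearman")
  }
  out
}
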