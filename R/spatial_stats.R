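#' Construct a labeled point pattern in a rectangular window
#'
#' @param x,y Coordinates in um.
#' @param labels Optional subpopulation label per point.
#' @param window `c(width, height)` in um; defaults to the bounding box of
#'   the points (origin at 0).
#' @return A `point_pattern` list with `x`, `y`, `labels`, `window`.
#' @export
point_pattern <- function(x, y, labels = NULL, window = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  if (is.null(window)) window <- c(max(x), max(y))
  window <- unname(window)
  if (any(x < 0 | x > window[1] | y < 0 | y > window[2])) {
    stop("all points must lie inside the window")
  }
  if (!is.null(labels)) stopifnot(length(labels) == length(x))
  structure(list(x = x, y = y, labels = labels, window = window),
            class = "point_pattern")
}

# Accumulate translation-corrected (or uncorrected) pair weights into
# distance bins over ordered pairs i != j, chunked to bound memory.
pair_bin_weights <- function(x, y, window, breaks, correction) {
  n <- length(x)
  W <- window[1]; H <- window[2]
  nb <- length(breaks) - 1L
  rmax <- breaks[nb + 1L]
  wsum <- numeric(nb)
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    dx <- abs(outer(x[idx], x, "-"))
    dy <- abs(outer(y[idx], y, "-"))
    d <- sqrt(dx^2 + dy^2)
    d[cbind(seq_along(idx), idx)] <- Inf   # drop self pairs
    keep <- d > breaks[1L] & d <= rmax
    if (!any(keep)) next
    bin <- findInterval(d[keep], breaks, left.open = TRUE)
    w <- if (correction == "translation") {
      (W * H) / ((W - dx[keep]) * (H - dy[keep]))
    } else rep(1, sum(keep))
    acc <- rowsum(w, bin)
    wsum[as.integer(rownames(acc))] <- wsum[as.integer(rownames(acc))] + acc[, 1]
  }
  wsum
}

#' Pair correlation function of a (labeled) point pattern
#'
#' Ring pair-counting estimate of g(r): pair weights accumulated in distance
#' bins, normalized by the squared intensity and ring areas, with translation
#' edge correction by default (edges dominate in small 1-mm cores). Under
#' complete spatial randomness g(r) = 1; g > 1 at small r indicates
#' clustering.
#'
#' @param pattern A [point_pattern()].
#' @param target_label Restrict the estimate to points carrying this label,
#'   or `"all"` (default) for every point.
#' @param breaks Distance bin boundaries in um, within \[0, 250\]
#'   (default 10-um rings up to 250 um).
#' @param correction `"translation"` (default) or `"none"`.
#' @return Data frame with `r` (bin centers), `g`, and attributes
#'   `n_points`, `correction`.
#' @export
estimate_pcf <- function(pattern, target_label = "all",
                         breaks = seq(0, 250, by = 10),
                         correction = c("translation", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern"))
  if (max(breaks) > 250) stop("radius bins beyond 250 um are not supported")
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be increasing")
  keep <- if (identical(target_label, "all")) rep(TRUE, length(pattern$x))
          else pattern$labels == target_label
  x <- pattern$x[keep]; y <- pattern$y[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 points carrying the target label")
  W <- pattern$window[1]; H <- pattern$window[2]
  A <- W * H
  wsum <- pair_bin_weights(x, y, pattern$window, breaks, correction)
  ring_area <- pi * diff(breaks^2)
  g <- (A / (n * (n - 1))) * wsum / ring_area
  out <- data.frame(r = (utils::head(breaks, -1) + breaks[-1]) / 2, g = g)
  attr(out, "n_points") <- n
  attr(out, "correction") <- correction
  out
}

# k-nearest-neighbour indices (self excluded); distance ties broken by
# lowest index (stable order()).
knn_indices <- function(x, y, k) {
  n <- length(x)
  if (k >= n) stop("k must be smaller than the number of points")
  out <- matrix(0L, n, k)
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    for (i in seq_along(idx)) {
      out[idx[i], ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

#' Neighborhood composition deviations (Delta %)
#'
#' For each cell, the composition of its k nearest neighbors over the eight
#' subpopulations is compared with the whole-pattern extents. In `relative`
#' mode the deviation is `100 * (observed - expected) / expected` (patterns
#' whose whole-pattern extent is below `floor_pct` are reported `NA` to avoid
#' division blow-ups); in `absolute` mode it is `observed - expected` in
#' percentage points, which sums to zero over patterns for every cell.
#'
#' @param pattern A labeled [point_pattern()].
#' @param k Neighborhood size (default 20 cells).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param floor_pct Minimum whole-pattern extent (%) for a defined relative
#'   deviation.
#' @param neighbors Optional precomputed [knn_indices()] matrix (positions
#'   fixed; used by the permutation null to avoid recomputing neighbours).
#' @return List with `delta` (cells x 8 matrix), `observed`, `expected`
#'   (fractions), `labels`, `mode`.
#' @export
knn_delta <- function(pattern, k = 20, mode = c("relative", "absolute"),
                      floor_pct = 0.5, neighbors = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pattern, "point_pattern"), !is.null(pattern$labels))
  n <- length(pattern$x)
  if (k >= n) stop("k must be smaller than the number of points")
  pats <- subpop_patterns()
  lab <- factor(pattern$labels, levels = pats)
  if (anyNA(lab)) stop("labels must be subpopulation patterns")
  if (is.null(neighbors)) neighbors <- knn_indices(pattern$x, pattern$y, k)

  code <- as.integer(lab)
  obs <- matrix(0, n, 8, dimnames = list(NULL, pats))
  neigh_codes <- matrix(code[neighbors], n, k)
  for (j in 1:8) obs[, j] <- rowSums(neigh_codes == j) / k
  expected <- as.numeric(table(lab)) / n
  names(expected) <- pats

  delta <- if (mode == "relative") {
    d <- 100 * sweep(sweep(obs, 2, expected, "-"), 2, expected, "/")
    d[, 100 * expected < floor_pct] <- NA_real_
    d
  } else {
    100 * sweep(obs, 2, expected, "-")
  }
  list(delta = delta, observed = obs, expected = expected,
       labels = lab, mode = mode, neighbors = neighbors)
}

#' Subpopulation interaction matrix from neighborhood deviations
#'
#' Entry (i, j) is the mean deviation of pattern j within the neighborhoods
#' of cells labeled i. Rows for patterns with no cells are `NA` (undefined),
#' never zero.
#'
#' @param delta Output of [knn_delta()].
#' @return List with `matrix` (8 x 8), `counts` (cells per focal pattern).
#' @export
interaction_matrix <- function(delta) {
  pats <- subpop_patterns()
  m <- matrix(NA_real_, 8, 8, dimnames = list(focal = pats, neighbor = pats))
  counts <- table(delta$labels)
  for (i in seq_along(pats)) {
    rows <- delta$labels == pats[i]
    if (any(rows)) m[i, ] <- colMeans(delta$delta[rows, , drop = FALSE])
  }
  list(matrix = m, counts = as.integer(counts))
}

#' Permutation null for PCF and neighborhood deviations
#'
#' Labels are permuted uniformly across the fixed cell positions (marginal
#' label counts preserved), and the homotypic PCF of the target label plus
#' the per-pattern mean deviation are re-estimated for each permutation.
#'
#' @param pattern A labeled [point_pattern()].
#' @param target_label Label whose homotypic PCF envelope is wanted.
#' @param n_sims Number of permutations (>= 1).
#' @param k Neighborhood size for the deviation statistic.
#' @param breaks PCF distance bins.
#' @param probs Envelope quantiles (default 2.5% / 97.5%).
#' @param mode Deviation mode passed to [knn_delta()].
#' @param seed Optional seed.
#' @return List with `pcf_envelope` (data frame `r`, `lo`, `hi`),
#'   `delta_envelope` (per-pattern quantiles of mean deviation) and
#'   `delta_mean` (per-pattern mean over permutations).
#' @export
null_relabel <- function(pattern, target_label, n_sims = 99, k = 20,
                         breaks = seq(0, 250, by = 10),
                         probs = c(0.025, 0.975),
                         mode = c("relative", "absolute"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_sims >= 1, !is.null(pattern$labels))
  if (!is.null(seed)) set.seed(seed)
  nb <- length(breaks) - 1L
  neighbors <- knn_indices(pattern$x, pattern$y, k)
  gmat <- matrix(NA_real_, n_sims, nb)
  dmat <- matrix(NA_real_, n_sims, 8, dimnames = list(NULL, subpop_patterns()))
  for (s in seq_len(n_sims)) {
    perm <- pattern
    perm$labels <- sample(pattern$labels)
    if (sum(perm$labels == target_label) >= 2) {
      gmat[s, ] <- estimate_pcf(perm, target_label, breaks)$g
    }
    d <- knn_delta(perm, k = k, mode = mode, neighbors = neighbors)
    dmat[s, ] <- colMeans(d$delta)
  }
  q <- apply(gmat, 2, stats::quantile, probs = probs, na.rm = TRUE)
  list(
    pcf_envelope = data.frame(r = (utils::head(breaks, -1) + breaks[-1]) / 2,
                              lo = q[1, ], hi = q[2, ]),
    delta_envelope = apply(dmat, 2, stats::quantile, probs = probs, na.rm = TRUE),
    delta_mean = colMeans(dmat, na.rm = TRUE)
  )
}

#' Ward clustering of interaction matrices
#'
#' Vectorizes a set of 8 x 8 interaction matrices, imputes undefined entries
#' as 0 (flagged), and agglomerates with Ward's minimum-variance method on
#' Euclidean distances.
#'
#' @param matrices Named list of [interaction_matrix()] outputs (or bare
#'   8 x 8 matrices).
#' @param k_clusters Number of flat clusters to cut (default 2).
#' @return List with `hclust` (the linkage), `clusters` (named assignment),
#'   `n_imputed` (undefined entries imputed per matrix). Matrices that are
#'   entirely undefined are dropped with a warning.
#' @export
cluster_profiles <- function(matrices, k_clusters = 2) {
  if (length(matrices) < 2) stop("at least 2 matrices are required")
  vecs <- lapply(matrices, function(m) {
    as.numeric(if (is.list(m)) m$matrix else m)
  })
  all_na <- vapply(vecs, function(v) all(is.na(v)), logical(1))
  if (any(all_na)) {
    warning("dropping all-undefined matrices: ",
            paste(names(matrices)[all_na], collapse = ", "))
    vecs <- vecs[!all_na]
  }
  if (length(vecs) < 2) stop("fewer than 2 usable matrices after exclusion")
  n_imputed <- vapply(vecs, function(v) sum(is.na(v)), integer(1))
  mat <- do.call(rbind, lapply(vecs, function(v) { v[is.na(v)] <- 0; v }))
  rownames(mat) <- names(vecs)
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  k_clusters <- min(k_clusters, nrow(mat))
  list(hclust = hc, clusters = stats::cutree(hc, k = k_clusters),
       n_imputed = n_imputed)
}
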