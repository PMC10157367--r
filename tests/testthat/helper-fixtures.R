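# Shared fixtures, built in code at test time.

# Minimal hand-written cell table: one patient, configurable cores.
make_cell_table <- function(patient = "P1", cores = list(c1 = 4)) {
  rows <- lapply(names(cores), function(cid) {
    n <- cores[[cid]]
    data.frame(patient_id = patient, core_id = cid, image_id = cid,
               x_um = seq_len(n), y_um = seq_len(n),
               cd20 = 10, myc = 1, bcl2 = 1, bcl6 = 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

make_thresholds <- function(image_ids, cd20 = 5, myc = 5, bcl2 = 5, bcl6 = 5) {
  do.call(rbind, lapply(image_ids, function(img) {
    data.frame(image_id = img,
               marker = c("cd20", "myc", "bcl2", "bcl6"),
               threshold = c(cd20, myc, bcl2, bcl6),
               stringsAsFactors = FALSE)
  }))
}

# Two fully segregated half-planes with 50/50 labels.
make_segregated_pattern <- function(n_per_side = 300, seed = 1) {
  set.seed(seed)
  x <- c(runif(n_per_side, 0, 450), runif(n_per_side, 550, 1000))
  y <- runif(2 * n_per_side, 0, 1000)
  labels <- rep(c("M+2+6-", "M-2-6-"), each = n_per_side)
  point_pattern(x, y, labels, window = c(1000, 1000))
}

# Random-label CSR pattern over all 8 subpopulations.
make_random_pattern <- function(n = 2000, seed = 1,
                                probs = rep(1 / 8, 8)) {
  set.seed(seed)
  pts <- sim_points(n, c(1000, 1000))
  labels <- sample(subpop_patterns(), n, replace = TRUE, prob = probs)
  point_pattern(pts$x_um, pts$y_um, labels, window = c(1000, 1000))
}

# Naive O(n^2) translation-corrected PCF, written independently of the
# package estimator (double loop; the oracle for estimate_pcf).
naive_pcf <- function(x, y, window, breaks, correction = "translation") {
  n <- length(x)
  W <- window[1]; H <- window[2]
  nb <- length(breaks) - 1
  wsum <- numeric(nb)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
      d <- sqrt(dx^2 + dy^2)
      if (d <= breaks[1] || d > breaks[nb + 1]) next
      b <- which(d > breaks[-(nb + 1)] & d <= breaks[-1])
      w <- if (correction == "translation") (W * H) / ((W - dx) * (H - dy)) else 1
      wsum[b] <- wsum[b] + w
    }
  }
  (W * H / (n * (n - 1))) * wsum / (pi * diff(breaks^2))
}

# Brute-force Paule-Mandel pooling by tau^2 grid search.
pm_grid_oracle <- function(theta, se, step = 1e-6, tau2_max = NULL) {
  k <- length(theta)
  if (is.null(tau2_max)) tau2_max <- max(var(theta) * 3, 1e-3)
  grid <- seq(0, tau2_max, by = step)
  q <- vapply(grid, function(t2) {
    w <- 1 / (se^2 + t2)
    th <- sum(w * theta) / sum(w)
    sum(w * (theta - th)^2)
  }, numeric(1))
  # Q(tau2) decreases in tau2; pick the grid point where it crosses k-1
  idx <- if (q[1] <= k - 1) 1L else which(q <= k - 1)[1]
  if (is.na(idx)) idx <- length(grid)
  t2 <- grid[idx]
  w <- 1 / (se^2 + t2)
  c(tau2 = t2, pooled = sum(w * theta) / sum(w))
}
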