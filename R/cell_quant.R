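#' Call per-cell marker positivity against per-image thresholds
#'
#' Each cell is declared positive for a marker when its mean intensity lies
#' strictly above the threshold set for that marker in that image; a cell
#' exactly at threshold is negative. Thresholds are per-image because
#' positivity cut points are set manually per image in multiplexed-IHC
#' workflows.
#'
#' @param cells Data frame with columns `patient_id`, `core_id`, `image_id`,
#'   `x_um`, `y_um` and one intensity column per marker (`cd20`, `myc`,
#'   `bcl2`, `bcl6`, optionally `ki67`).
#' @param thresholds Data frame with columns `image_id`, `marker`,
#'   `threshold`; one row per (image, marker) in use.
#' @return `cells` with appended logical columns `cd20_pos`, `myc_pos`,
#'   `bcl2_pos`, `bcl6_pos` (and `ki67_pos` if `ki67` present) plus a
#'   `pattern` column with the MYC/BCL2/BCL6 label of every cell.
#' @export
call_positivity <- function(cells, thresholds) {
  required <- c("patient_id", "core_id", "image_id", "x_um", "y_um",
                "cd20", "myc", "bcl2", "bcl6")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop("cell table lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(c("image_id", "marker", "threshold") %in% names(thresholds)))
  markers <- intersect(c("cd20", "myc", "bcl2", "bcl6", "ki67"), names(cells))
  for (m in markers) {
    thr <- thresholds[thresholds$marker == m, c("image_id", "threshold")]
    idx <- match(cells$image_id, thr$image_id)
    if (anyNA(idx)) {
      bad <- unique(cells$image_id[is.na(idx)])
      stop(sprintf("no '%s' threshold for image(s): %s",
                   m, paste(utils::head(bad, 5), collapse = ", ")))
    }
    cells[[paste0(m, "_pos")]] <- cells[[m]] > thr$threshold[idx]
  }
  cells$pattern <- label_subpopulation(cells$myc_pos, cells$bcl2_pos, cells$bcl6_pos)
  cells
}

#' Per-patient subpopulation extents from labeled cells
#'
#' Extents (% of CD20-positive cells) of the eight MYC/BCL2/BCL6 patterns are
#' computed per core over CD20-positive cells only, then averaged across a
#' patient's cores weighted by the number of CD20-positive cells per core.
#' Single-marker marginals are sums of the four matching pattern extents.
#'
#' @param flagged Output of [call_positivity()] (needs `cd20_pos`, `pattern`,
#'   `patient_id`, `core_id`).
#' @param min_cells_per_core Cores with fewer CD20-positive cells than this
#'   are flagged in the `cores` table (`low_cells = TRUE`) but still included;
#'   exclusion is the caller's decision.
#' @return List with:
#'   \describe{
#'     \item{profiles}{one row per patient: the 8 pattern extents (%), the
#'       three marginals `pM`, `p2`, `p6` (%), `n_cores`, `n_cells`
#'       (CD20-positive cells).}
#'     \item{cores}{per-core extents with CD20-positive cell counts.}
#'     \item{excluded}{patients with zero CD20-positive cells, if any.}
#'   }
#' @export
patient_extents <- function(flagged, min_cells_per_core = 50) {
  stopifnot(all(c("patient_id", "core_id", "cd20_pos", "pattern") %in% names(flagged)))
  pats <- subpop_patterns()
  b <- flagged[flagged$cd20_pos, , drop = FALSE]

  all_patients <- unique(flagged$patient_id)
  excluded <- setdiff(all_patients, unique(b$patient_id))
  if (length(excluded)) {
    warning("patient(s) with zero CD20-positive cells excluded: ",
            paste(excluded, collapse = ", "))
  }
  if (nrow(b) == 0L) {
    stop("no CD20-positive cells in the table")
  }

  key <- interaction(b$patient_id, b$core_id, drop = TRUE, sep = "\r")
  counts <- table(key, factor(b$pattern, levels = pats))
  n_core <- rowSums(counts)
  ext_core <- 100 * counts / n_core
  ids <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
  cores <- data.frame(patient_id = ids[, 1], core_id = ids[, 2],
                      n_cells = as.integer(n_core),
                      low_cells = as.integer(n_core) < min_cells_per_core,
                      stringsAsFactors = FALSE, check.names = FALSE)
  cores <- cbind(cores, as.data.frame.matrix(ext_core))

  profiles <- lapply(split(seq_len(nrow(cores)), cores$patient_id), function(i) {
    w <- cores$n_cells[i]
    ext <- colSums(as.matrix(cores[i, pats, drop = FALSE]) * w) / sum(w)
    data.frame(patient_id = cores$patient_id[i[1]],
               as.list(ext),
               pM = sum(ext[patterns_positive_for("myc")]),
               p2 = sum(ext[patterns_positive_for("bcl2")]),
               p6 = sum(ext[patterns_positive_for("bcl6")]),
               n_cores = length(i), n_cells = sum(w),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL
  list(profiles = profiles, cores = cores, excluded = excluded)
}

#' Stability of the high/low call across increasing numbers of fields
#'
#' For a sample imaged in several fields, evaluates how reliably the
#' dichotomized call (cumulative cell-weighted mean extent >= cutoff) after
#' the first k fields agrees with the call using all fields, over the
#' observed field order and random re-orderings.
#'
#' @param extents Numeric vector of per-field extents (%).
#' @param n_cells Optional per-field CD20-positive cell counts used as
#'   weights in the cumulative mean (defaults to equal weights).
#' @param cutoff_pct Dichotomization cutoff (%), default 15.
#' @param k Integer vector of field counts to evaluate (default `1:n_fields`).
#' @param n_orderings Number of random permutations appended to the observed
#'   order.
#' @param seed Optional seed for the permutations.
#' @return Data frame with one row per k: `k`, `call_observed` (call in the
#'   observed order), and `stability` (fraction of orderings whose call at k
#'   matches the all-fields call).
#' @export
field_stability <- function(extents, n_cells = NULL, cutoff_pct = 15,
                            k = seq_along(extents), n_orderings = 200,
                            seed = NULL) {
  n <- length(extents)
  if (n < 2) stop("at least two fields are required")
  if (any(k > n)) stop("k exceeds the number of fields")
  if (is.null(n_cells)) n_cells <- rep(1, n)
  stopifnot(length(n_cells) == n, all(n_cells > 0))
  if (!is.null(seed)) set.seed(seed)

  cum_call <- function(ord) {
    cummean <- cumsum(extents[ord] * n_cells[ord]) / cumsum(n_cells[ord])
    cummean >= cutoff_pct
  }
  final_call <- cum_call(seq_len(n))[n]
  orderings <- c(list(seq_len(n)),
                 replicate(n_orderings, sample.int(n), simplify = FALSE))
  calls <- vapply(orderings, cum_call, logical(n))  # n x (n_orderings+1)
  data.frame(
    k = k,
    call_observed = calls[k, 1],
    stability = rowMeans(calls[k, , drop = FALSE] == final_call)
  )
}

#' Read a cell table or threshold table from CSV
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write per-patient profiles to CSV
#' @param profiles `profiles` element of [patient_extents()].
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
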