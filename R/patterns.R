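#' Canonical MYC/BCL2/BCL6 subpopulation patterns
#'
#' The eight permutations of MYC ("M"), BCL2 ("2") and BCL6 ("6") positivity
#' within CD20-positive B cells, in the fixed order used throughout the
#' package (triple-positive first, triple-negative last).
#'
#' @return Character vector of length 8, e.g. `"M+2+6-"`.
#' @export
subpop_patterns <- function() {
  c("M+2+6+", "M+2+6-", "M+2-6+", "M+2-6-",
    "M-2+6+", "M-2+6-", "M-2-6+", "M-2-6-")
}

#' Map marker flags to a subpopulation label
#'
#' Deterministic 3-bit mapping from MYC/BCL2/BCL6 positivity to one of the
#' eight pattern labels. CD20 status is not part of the label; gating on
#' CD20 happens upstream when denominators are formed.
#'
#' @param myc,bcl2,bcl6 Logical vectors (recycled to common length).
#' @return Character vector of pattern labels.
#' @export
label_subpopulation <- function(myc, bcl2, bcl6) {
  n <- max(length(myc), length(bcl2), length(bcl6))
  myc <- rep_len(as.logical(myc), n)
  bcl2 <- rep_len(as.logical(bcl2), n)
  bcl6 <- rep_len(as.logical(bcl6), n)
  if (anyNA(myc) || anyNA(bcl2) || anyNA(bcl6)) {
    stop("marker flags must be TRUE/FALSE with no missing values")
  }
  paste0("M", ifelse(myc, "+", "-"),
         "2", ifelse(bcl2, "+", "-"),
         "6", ifelse(bcl6, "+", "-"))
}

# Parse a pattern label back into the three logical flags.
pattern_flags <- function(pattern) {
  stopifnot(all(pattern %in% subpop_patterns()))
  cbind(myc  = substr(pattern, 2, 2) == "+",
        bcl2 = substr(pattern, 4, 4) == "+",
        bcl6 = substr(pattern, 6, 6) == "+")
}

# Patterns (in canonical order) that are positive for one marker.
patterns_positive_for <- function(marker = c("myc", "bcl2", "bcl6")) {
  marker <- match.arg(marker)
  pats <- subpop_patterns()
  pats[pattern_flags(pats)[, marker]]
}
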