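## Cut-site conservation from per-residue deleteriousness profiles.
##
## Profiles follow the PROVEAN convention (more negative = more
## deleterious if altered); they are consumed as input, never computed
## here. A guide's conservation score is the mean absolute profile value
## in a small amino-acid window around the codon containing the cut, and
## the pass/fail threshold is the median score over a background
## collection of coding-sequence Cas9 sites.

#' Read per-residue conservation profiles
#'
#' @param path TSV with columns `protein_id`, `residue_index` (0-based),
#'   `score`.
#' @return named list of numeric score vectors ordered by residue.
#' @export
readConservationProfiles <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("protein_id", "residue_index", "score") %in% names(df)))
  lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$residue_index), , drop = FALSE]
    if (!identical(as.integer(d$residue_index),
                   seq_len(nrow(d)) - 1L))
      stop("profile for ", d$protein_id[1],
           " must cover residues 0..n-1 exactly once")
    if (any(!is.finite(d$score)))
      stop("non-finite conservation score for ", d$protein_id[1])
    d$score
  })
}

#' Conservation score at a cut site
#'
#' Mean of the absolute per-residue deleteriousness over the window
#' `[cutAaIndex - flankAa, cutAaIndex + flankAa]`, truncated at the
#' protein ends. Higher means a DSB-proximal substitution is predicted
#' more deleterious, i.e. the site is more conserved.
#'
#' @param profile numeric vector of per-residue scores (0-based indexing
#'   via `cutAaIndex`).
#' @param cutAaIndex 0-based amino-acid index of the codon containing the
#'   cut; NA for non-coding cuts.
#' @param flankAa residues of flank on each side (default 2).
#' @return numeric score, or NA when the cut is outside the coding
#'   sequence (the guide then fails the conservation test).
#' @export
conservationScore <- function(profile, cutAaIndex, flankAa = 2L) {
  if (is.na(cutAaIndex)) return(NA_real_)
  n <- length(profile)
  if (cutAaIndex < 0L || cutAaIndex >= n) return(NA_real_)
  lo <- max(0L, cutAaIndex - flankAa)
  hi <- min(n - 1L, cutAaIndex + flankAa)
  mean(abs(profile[(lo + 1L):(hi + 1L)]))
}

#' Conservation pass/fail threshold
#'
#' The median conservation score over a background site collection;
#' guides pass when their score strictly exceeds it.
#'
#' @param backgroundScores numeric vector of background site scores.
#' @return the median.
#' @export
conservationThreshold <- function(backgroundScores) {
  backgroundScores <- backgroundScores[!is.na(backgroundScores)]
  if (!length(backgroundScores))
    stop("background score collection is empty")
  median(backgroundScores)
}

#' Apply the conservation test
#'
#' @param score conservation score (NA fails).
#' @param threshold background median from [conservationThreshold()].
#' @return logical; TRUE iff `score > threshold`.
#' @export
conservationPass <- function(score, threshold) {
  !is.na(score) & score > threshold
}
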