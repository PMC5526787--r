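## Central S4 classes. Interval convention throughout the package:
## 0-based half-open [start, end); a cut coordinate is the boundary index
## between two bases, so the inter-DSB distance of a guide pair is
## |cut_a - cut_b| in bp and divisibility-by-3 tests are unambiguous.

#' Gene model with transcripts, exons and CDS
#'
#' Holds one gene's transcript structures in 0-based half-open genomic
#' coordinates. Exon and CDS intervals are two-column integer matrices
#' (columns `start`, `end`), stored in genomic order regardless of strand.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome / sequence name.
#' @slot transcripts named list; each element is a list with elements
#'   `transcriptId`, `strand` ("+" or "-"), `exons`, `cds`.
#' @export
setClass("GeneModel", representation(
  geneId = "character",
  chrom = "character",
  transcripts = "list"
))

.checkIntervalMatrix <- function(m, label) {
  if (!is.matrix(m) || ncol(m) != 2L)
    return(sprintf("%s must be a two-column matrix", label))
  if (nrow(m) == 0L) return(TRUE)
  if (any(m[, 2L] <= m[, 1L]))
    return(sprintf("%s has empty or inverted intervals", label))
  if (nrow(m) > 1L) {
    if (is.unsorted(m[, 1L], strictly = TRUE))
      return(sprintf("%s intervals are not sorted", label))
    if (any(m[-1L, 1L] < m[-nrow(m), 2L]))
      return(sprintf("%s intervals overlap", label))
  }
  TRUE
}

.intervalsContained <- function(inner, outer) {
  ## every inner interval must lie inside some single outer interval
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, 1L] <= inner[i, 1L] & inner[i, 2L] <= outer[, 2L])
  }, logical(1)))
}

setValidity("GeneModel", function(object) {
  for (tx in object@transcripts) {
    if (!all(c("transcriptId", "strand", "exons", "cds") %in% names(tx)))
      return("each transcript needs transcriptId, strand, exons, cds")
    if (!tx$strand %in% c("+", "-")) return("strand must be '+' or '-'")
    ok <- .checkIntervalMatrix(tx$exons, paste0(tx$transcriptId, " exons"))
    if (!isTRUE(ok)) return(ok)
    ok <- .checkIntervalMatrix(tx$cds, paste0(tx$transcriptId, " CDS"))
    if (!isTRUE(ok)) return(ok)
    if (nrow(tx$cds) > 0L && !.intervalsContained(tx$cds, tx$exons))
      return(sprintf("CDS outside exons in transcript %s", tx$transcriptId))
  }
  TRUE
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "on", object@chrom, "with",
      length(object@transcripts), "transcript(s)\n")
})

#' Stringency ladder of cost-weighted random forests
#'
#' Ten random forests trained on identical features and labels, differing
#' only in the penalty attached to a false-positive call (classifying a weak
#' guide as potent). A target's per-ladder score is the highest rung whose
#' forest calls it potent.
#'
#' @slot datasetTag "doench-like" or "chari-like".
#' @slot forests list of 10 fitted ranger forests.
#' @slot penalties the false-positive penalty ladder, strictly increasing.
#' @slot treesPerForest trees per forest.
#' @slot featureCodecVersion identifier of the featurization scheme.
#' @slot rngSeed integer seed all training randomness derives from.
#' @slot bagging logical; out-of-bag reporting requires TRUE.
#' @export
setClass("StringencyEnsemble", representation(
  datasetTag = "character",
  forests = "list",
  penalties = "numeric",
  treesPerForest = "integer",
  featureCodecVersion = "character",
  rngSeed = "integer",
  bagging = "logical"
))

setValidity("StringencyEnsemble", function(object) {
  if (length(object@forests) != length(object@penalties))
    return("one forest per penalty required")
  if (length(object@penalties) != 10L)
    return("penalty ladder must have exactly 10 rungs")
  if (any(diff(object@penalties) <= 0))
    return("penalties must be strictly increasing")
  TRUE
})

setMethod("show", "StringencyEnsemble", function(object) {
  cat("StringencyEnsemble [", object@datasetTag, "]: ",
      length(object@forests), " forests x ", object@treesPerForest,
      " trees, penalties ", paste(object@penalties, collapse = ", "),
      "\n", sep = "")
})

#' Linear model of microhomology-guided repair resolution likelihood
#'
#' Ordinary least squares of observed resolution frequency on homology
#' length, GC fraction and distance to the double-strand break. Negative
#' predictions are clamped to zero before use.
#'
#' @slot coefficients named numeric: intercept, length, gc_fraction, distance.
#' @slot fitDiagnostics list with residual summary and R-squared.
#' @slot hejCutoff lower-limit threshold on the per-site sum of predicted
#'   likelihoods; NA until [computeHejCutoff()] has been applied.
#' @slot distanceMode "sum" (default) or "min" of the two flank distances.
#' @export
setClass("RepairModel", representation(
  coefficients = "numeric",
  fitDiagnostics = "list",
  hejCutoff = "numeric",
  distanceMode = "character"
))

setMethod("show", "RepairModel", function(object) {
  cat("RepairModel: frequency ~ length + gc + distance (", object@distanceMode,
      ")\n  coefficients: ",
      paste(sprintf("%s=%.4g", names(object@coefficients),
                    object@coefficients), collapse = ", "),
      "\n  HEJ cutoff: ",
      if (is.na(object@hejCutoff)) "unset" else format(object@hejCutoff),
      "\n", sep = "")
})

#' Pooled screen container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay (constructs x samples, non-negative integers). `colData`
#' carries `replicate`, `timepoint` ("reference" or "final") and `cell_line`;
#' `rowData` carries `construct`, `gene` and a `class` label ("EG", "NEG" or
#' "other"), plus `h_guide`/`c_guide` for dual-guide libraries.
#'
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("replicate", "timepoint")
  if (!all(need %in% colnames(cd)))
    return("colData must contain 'replicate' and 'timepoint'")
  if (!all(cd$timepoint %in% c("reference", "final")))
    return("timepoint must be 'reference' or 'final'")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.na(cnt) & cnt < 0)) return("counts must be non-negative")
  ## every (replicate, final) needs a matched reference
  byrep <- split(cd$timepoint, cd$replicate)
  for (tp in byrep) {
    if ("final" %in% tp && !"reference" %in% tp)
      return("every replicate with a final sample needs a reference sample")
  }
  TRUE
})

#' Amplicon specification for dual-cut scar analysis
#'
#' @slot ampliconId identifier.
#' @slot refseq amplicon reference sequence (plain character).
#' @slot cutH 0-based boundary coordinate of the hU6-guide DSB.
#' @slot cutC 0-based boundary coordinate of the cU6-guide DSB; must exceed
#'   `cutH` and the two attribution windows must not overlap.
#' @slot window half-width (nt) of the window around each cut within which
#'   an indel is attributed to that cut.
#' @export
setClass("AmpliconSpec", representation(
  ampliconId = "character",
  refseq = "character",
  cutH = "integer",
  cutC = "integer",
  window = "integer"
))

setValidity("AmpliconSpec", function(object) {
  if (object@cutH >= object@cutC) return("cutH must be < cutC")
  if (object@cutH + object@window > object@cutC - object@window)
    return("attribution windows around the two cuts overlap")
  if (object@cutC > nchar(object@refseq))
    return("cut coordinates outside the amplicon")
  TRUE
})

setMethod("show", "AmpliconSpec", function(object) {
  cat("AmpliconSpec", object@ampliconId, ":", nchar(object@refseq),
      "bp, cuts at", object@cutH, "and", object@cutC,
      "(window +/-", paste0(object@window, ")"), "\n")
})

#' Construct an amplicon specification
#'
#' @param ampliconId identifier.
#' @param refseq amplicon reference sequence.
#' @param cutH,cutC 0-based boundary coordinates of the two DSBs
#'   (`cutH < cutC`).
#' @param window attribution half-width in nt (default 5).
#' @return an [AmpliconSpec-class] object.
#' @export
AmpliconSpec <- function(ampliconId, refseq, cutH, cutC, window = 5L) {
  new("AmpliconSpec", ampliconId = as.character(ampliconId),
      refseq = toupper(as.character(refseq)), cutH = as.integer(cutH),
      cutC = as.integer(cutC), window = as.integer(window))
}
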