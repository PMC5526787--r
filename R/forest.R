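## Stringency-laddered random forest potency model.
##
## Each 30-nt target context is decomposed into its 28 overlapping 3mers,
## encoded position-specifically (28 positions x 64 possible 3mers). For
## each training dataset, guides are labelled potent / weak by a
## top- and bottom-40% within-gene efficacy cutoff and ten forests are
## trained that differ only in the penalty attached to a false-positive
## call (weak classified as potent): 0.2, 0.4, ..., 2. A target's
## per-dataset score is the highest rung whose forest calls it potent; the
## combined score across the two datasets is the minimum of the two.

#' @importFrom ranger ranger
NULL

PENALTY_LADDER <- seq(0.2, 2, by = 0.2)

ALL_3MERS <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, stringsAsFactors = FALSE)[, 3:1]
  sort(apply(g, 1L, paste, collapse = ""))
}

#' Decompose a 30-nt context into its 28 positional 3mers
#'
#' @param context30 character vector of 30-nt ACGT sequences.
#' @return character matrix with one row per input and 28 columns
#'   (`p01`..`p28`); column i holds the 3mer at offsets \[i-1, i+2).
#' @export
featurize3mers <- function(context30) {
  context30 <- toupper(context30)
  bad <- nchar(context30) != 30L | grepl("[^ACGT]", context30)
  if (any(bad))
    stop("featurization requires 30-nt ACGT sequences; offending entry: ",
         context30[which(bad)[1]])
  m <- t(vapply(context30, function(s) {
    substring(s, 1:28, 3:30)
  }, character(28), USE.NAMES = FALSE))
  colnames(m) <- sprintf("p%02d", 1:28)
  m
}

## numeric design matrix for the forests; the column set is fixed by the
## featurization mode so train- and predict-time encodings always agree
.designMatrix <- function(context30, codecVersion) {
  mode <- if (grepl("bag", codecVersion)) "bag" else "positional"
  featurizeOneHot(context30, mode)
}

#' One-hot numeric featurization (bag or positional)
#'
#' Positional mode expands the 28 positions x 64 3mers into 1792 indicator
#' columns; bag mode counts each 3mer across positions (64 columns).
#'
#' @param context30 character vector of 30-nt sequences.
#' @param mode "positional" (default) or "bag".
#' @return numeric matrix.
#' @export
featurizeOneHot <- function(context30, mode = c("positional", "bag")) {
  mode <- match.arg(mode)
  m <- featurize3mers(context30)
  if (mode == "bag") {
    out <- t(apply(m, 1L, function(r) table(factor(r, levels = ALL_3MERS))))
    colnames(out) <- ALL_3MERS
    return(out)
  }
  out <- matrix(0, nrow(m), 28L * 64L)
  colnames(out) <- as.vector(outer(ALL_3MERS, sprintf("p%02d", 1:28),
                                   function(k, p) paste0(p, "_", k)))
  for (i in seq_len(nrow(m)))
    out[i, paste0(colnames(m), "_", m[i, ])] <- 1
  out
}

#' Label efficacy records as potent / weak / discarded
#'
#' Percentiles are the within-gene percentile rank of each guide's efficacy
#' (computed by [percentileRank()] when the table lacks an
#' `efficacy_percentile` column). Guides at or above the 60th percentile
#' are potent, at or below the 40th weak; the middle 20% is discarded from
#' training. Genes with fewer than 3 guides are excluded with a warning.
#'
#' @param records data.frame with columns `context30`, `gene_id`, and
#'   either `efficacy_percentile` or `efficacy`.
#' @return the input with added `efficacy_percentile` and `label`
#'   ("potent", "weak", "discarded"); excluded-gene rows are dropped.
#' @export
labelRecords <- function(records) {
  stopifnot(all(c("context30", "gene_id") %in% names(records)))
  sizes <- table(records$gene_id)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("excluding ", length(small),
            " gene(s) with fewer than 3 guides: ",
            paste(head(small, 5L), collapse = ", "))
    records <- records[!records$gene_id %in% small, , drop = FALSE]
  }
  if (is.null(records$efficacy_percentile)) {
    if (is.null(records$efficacy))
      stop("records need 'efficacy' or 'efficacy_percentile'")
    records$efficacy_percentile <- stats::ave(records$efficacy,
                                              records$gene_id,
                                              FUN = percentileRank)
  }
  p <- records$efficacy_percentile
  if (any(p < 0 | p > 100)) stop("percentiles must lie in [0, 100]")
  records$label <- ifelse(p >= 60, "potent",
                          ifelse(p <= 40, "weak", "discarded"))
  records
}

#' Train one stringency ladder of forests
#'
#' Ten forests are trained on identical features and labels; rung k's
#' forest carries a class weight of `penalties[k]` on the weak class, so a
#' false positive (weak called potent) costs k times a false negative in
#' the split criterion. All randomness derives from `rngSeed`.
#'
#' @param records labelled data.frame (see [labelRecords()]); rows labelled
#'   "discarded" are ignored.
#' @param datasetTag "doench-like" or "chari-like".
#' @param penalties the ladder; must have 10 strictly increasing values.
#' @param treesPerForest trees per forest (default 1000).
#' @param rngSeed integer seed (default 17).
#' @param featureMode "positional" or "bag" (see [featurizeOneHot()]).
#' @param bagging set FALSE to train on full bootstrap-free samples
#'   (disables out-of-bag reporting).
#' @return a [StringencyEnsemble-class].
#' @export
trainEnsemble <- function(records, datasetTag = "doench-like",
                          penalties = PENALTY_LADDER,
                          treesPerForest = 1000L, rngSeed = 17L,
                          featureMode = c("positional", "bag"),
                          bagging = TRUE) {
  featureMode <- match.arg(featureMode)
  if (length(penalties) != 10L || any(diff(penalties) <= 0))
    stop("penalty ladder must be 10 strictly increasing values")
  if (is.null(records$label)) records <- labelRecords(records)
  train <- records[records$label %in% c("potent", "weak"), , drop = FALSE]
  if (length(unique(train$label)) < 2L)
    stop("training requires both potent and weak examples")
  y <- factor(train$label, levels = c("weak", "potent"))
  X <- featurizeOneHot(train$context30, featureMode)
  forests <- lapply(seq_along(penalties), function(k) {
    ranger::ranger(
      x = X, y = y,
      num.trees = as.integer(treesPerForest),
      class.weights = c(weak = penalties[k], potent = 1),
      replace = bagging,
      sample.fraction = if (bagging) 1 else 0.632,
      seed = deriveSeed(rngSeed, k), num.threads = 1L)
  })
  new("StringencyEnsemble", datasetTag = datasetTag, forests = forests,
      penalties = as.numeric(penalties),
      treesPerForest = as.integer(treesPerForest),
      featureCodecVersion = paste0("3mer-", featureMode, "-v1"),
      rngSeed = as.integer(rngSeed), bagging = isTRUE(bagging))
}

## majority vote over trees with a deterministic tie rule (an exact split
## is called weak): ranger's own tie-breaking is randomized
.predictPotent <- function(forest, newdata) {
  pr <- stats::predict(forest, data = newdata, num.threads = 1L,
                       predict.all = TRUE)
  votes <- pr$predictions  # matrix obs x trees of class indices
  potentIdx <- which(forest$forest$levels == "potent")
  rowSums(votes == potentIdx) > ncol(votes) / 2
}

#' Score targets against one stringency ladder
#'
#' @param ensemble a trained [StringencyEnsemble-class].
#' @param context30 character vector of 30-nt contexts.
#' @return integer vector in 0..10: the highest rung (1-based over the
#'   penalty ladder) whose forest calls the target potent; 0 when none does.
#' @export
ensembleScore <- function(ensemble, context30) {
  newdata <- .designMatrix(context30, ensemble@featureCodecVersion)
  calls <- vapply(ensemble@forests, .predictPotent,
                  logical(length(context30)), newdata = newdata)
  calls <- matrix(calls, nrow = length(context30))
  apply(calls, 1L, function(v) {
    idx <- which(v)
    if (length(idx)) max(idx) else 0L
  })
}

#' Combine the two per-dataset ladder scores
#'
#' A target's combined score is the highest stringency level it passes in
#' both random-forest sets, i.e. the minimum of the two ladder scores.
#'
#' @param doenchScore,chariScore integer vectors in 0..10.
#' @return integer vector in 0..10.
#' @export
combinedForestScore <- function(doenchScore, chariScore) {
  stopifnot(all(doenchScore %in% 0:10), all(chariScore %in% 0:10))
  as.integer(pmin(doenchScore, chariScore))
}

#' Out-of-bag ladder scores against efficacy percentiles
#'
#' Recomputes each training guide's ladder score using only trees whose
#' bootstrap sample excluded that guide, and reports the Spearman
#' correlation between the out-of-bag score and the guide's within-gene
#' efficacy percentile.
#'
#' @param ensemble a [StringencyEnsemble-class] trained with bagging.
#' @param records the labelled records the ensemble was trained on.
#' @return list with `table` (data.frame: context30, gene_id, oob_score,
#'   efficacy_percentile), `rho` and `p_value`.
#' @export
oobPercentileReport <- function(ensemble, records) {
  if (!ensemble@bagging)
    stop("out-of-bag reporting requires an ensemble trained with bagging")
  if (is.null(records$label)) records <- labelRecords(records)
  train <- records[records$label %in% c("potent", "weak"), , drop = FALSE]
  if (nrow(train) < 2L)
    stop("need at least 2 training records for a percentile report")
  calls <- vapply(ensemble@forests, function(f) {
    f$predictions == "potent"  # ranger stores OOB predictions here
  }, logical(nrow(train)))
  oob <- apply(matrix(calls, nrow = nrow(train)), 1L, function(v) {
    idx <- which(v)
    if (length(idx)) max(idx) else 0L
  })
  tab <- data.frame(context30 = train$context30, gene_id = train$gene_id,
                    oob_score = oob,
                    efficacy_percentile = train$efficacy_percentile,
                    stringsAsFactors = FALSE)
  ct <- suppressWarnings(stats::cor.test(tab$oob_score,
                                         tab$efficacy_percentile,
                                         method = "spearman"))
  list(table = tab, rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Train both stringency ladders from efficacy tables
#'
#' @param doench,chari data.frames of efficacy records (columns `context30`,
#'   `gene_id`, `efficacy` or `efficacy_percentile`).
#' @param ... passed to [trainEnsemble()].
#' @return list with elements `doench` and `chari`
#'   ([StringencyEnsemble-class] each).
#' @export
trainCroatanForests <- function(doench, chari, ...) {
  list(doench = trainEnsemble(doench, "doench-like", ...),
       chari = trainEnsemble(chari, "chari-like", ...))
}
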