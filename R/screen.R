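## Pooled-screen depletion analysis: read-count filtering, log fold
## changes, gene-normalized percentiles, group tests, dual-construct
## decomposition and gene-level hit calling with TPR/FPR.

#' Build a ScreenExperiment from a long count table
#'
#' @param counts data.frame with columns `construct`, `sample`, `count`.
#' @param samples data.frame with columns `sample`, `replicate`,
#'   `timepoint` ("reference"/"final") and optionally `cell_line`.
#' @param constructs optional data.frame with `construct`, `gene`, `class`
#'   ("EG"/"NEG"/"other") and, for dual libraries, `h_guide`, `c_guide`.
#' @return a [ScreenExperiment-class].
#' @export
ScreenExperiment <- function(counts, samples, constructs = NULL) {
  stopifnot(all(c("construct", "sample", "count") %in% names(counts)),
            all(c("sample", "replicate", "timepoint") %in% names(samples)))
  wide <- stats::xtabs(count ~ construct + sample, data = counts)
  mat <- matrix(as.integer(wide), nrow(wide), ncol(wide),
                dimnames = dimnames(wide))
  samples <- samples[match(colnames(mat), samples$sample), , drop = FALSE]
  if (is.null(samples$cell_line)) samples$cell_line <- "cellline1"
  rd <- if (!is.null(constructs)) {
    constructs[match(rownames(mat), constructs$construct), , drop = FALSE]
  } else data.frame(construct = rownames(mat), gene = NA_character_,
                    class = "other", stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample),
    rowData = S4Vectors::DataFrame(rd, row.names = rownames(mat)))
  new("ScreenExperiment", se)
}

.repPairs <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  reps <- unique(cd$replicate)
  lapply(setNames(reps, reps), function(r) {
    list(ref = rownames(cd)[cd$replicate == r & cd$timepoint == "reference"],
         fin = rownames(cd)[cd$replicate == r & cd$timepoint == "final"])
  })
}

#' Minimum reference read-count filter
#'
#' Constructs whose reference count in a replicate falls below `threshold`
#' are dropped from that replicate (their counts become NA in both the
#' reference and final samples of the replicate).
#'
#' @param se a [ScreenExperiment-class].
#' @param threshold minimum reference read count (default 50).
#' @return the filtered ScreenExperiment.
#' @export
filterMinReference <- function(se, threshold = 50L) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  mode(cnt) <- "numeric"  # allow NA masking
  for (rp in .repPairs(se)) {
    if (!length(rp$ref)) next
    low <- cnt[, rp$ref[1]] < threshold
    low[is.na(low)] <- TRUE
    cnt[low, c(rp$ref, rp$fin)] <- NA
  }
  if (all(is.na(cnt)))
    stop("all constructs removed by the minimum-reference filter")
  SummarizedExperiment::assay(se, "counts") <- cnt
  se
}

#' Log fold changes per replicate, with averages and z-scores
#'
#' Counts are scaled to counts-per-million within each sample, then per
#' replicate `LFC = log2((cpm_final + pc) / (cpm_reference + pc))`.
#' Z-scores are computed within the configured stratum.
#'
#' @param se a (filtered) [ScreenExperiment-class].
#' @param pseudocount added to both cpm values (default 1).
#' @param zStratum "replicate" (default) or "screen": whether z-scores
#'   standardize each replicate's LFC column separately or the
#'   replicate-averaged LFC across the whole screen.
#' @param normalization "cpm" (default) or "none" (raw counts; assumes
#'   equal nominal sequencing depth).
#' @param centerOn optional character vector of control construct ids;
#'   when supplied, each replicate's LFC column is shifted so the
#'   controls' median LFC is zero. Depletion in a pooled screen is only
#'   defined relative to the library composition, so planted or biological
#'   effects are read off against neutral controls.
#' @return list with `lfc` (construct x replicate matrix), `mean_lfc`,
#'   `z` (same shape as the stratum implies), `metadata` (records the
#'   normalization and z-scoring configuration), and `rowData` copied
#'   from the experiment.
#' @export
logFoldChange <- function(se, pseudocount = 1, zStratum = c("replicate",
                                                            "screen"),
                          normalization = c("cpm", "none"),
                          centerOn = NULL) {
  zStratum <- match.arg(zStratum)
  normalization <- match.arg(normalization)
  cnt <- SummarizedExperiment::assay(se, "counts")
  mode(cnt) <- "numeric"
  cpm <- if (normalization == "cpm")
    sweep(cnt, 2L, colSums(cnt, na.rm = TRUE), "/") * 1e6
  else cnt
  rp <- .repPairs(se)
  lfc <- sapply(rp, function(p) {
    if (!length(p$ref) || !length(p$fin))
      stop("replicate lacks a matched reference/final sample pair")
    log2((cpm[, p$fin[1]] + pseudocount) / (cpm[, p$ref[1]] + pseudocount))
  })
  lfc <- matrix(lfc, nrow = nrow(cnt),
                dimnames = list(rownames(cnt), names(rp)))
  if (!is.null(centerOn)) {
    ctrl <- intersect(centerOn, rownames(lfc))
    if (!length(ctrl)) stop("no centerOn constructs found in the screen")
    shift <- apply(lfc[ctrl, , drop = FALSE], 2L, median, na.rm = TRUE)
    lfc <- sweep(lfc, 2L, shift, "-")
  }
  meanLfc <- rowMeans(lfc, na.rm = TRUE)
  meanLfc[is.nan(meanLfc)] <- NA_real_
  z <- if (zStratum == "replicate") {
    apply(lfc, 2L, function(v) (v - mean(v, na.rm = TRUE)) /
            stats::sd(v, na.rm = TRUE))
  } else {
    (meanLfc - mean(meanLfc, na.rm = TRUE)) / stats::sd(meanLfc, na.rm = TRUE)
  }
  list(lfc = lfc, mean_lfc = meanLfc, z = z,
       metadata = list(pseudocount = pseudocount,
                       normalization = normalization,
                       centered_on = if (is.null(centerOn)) "none"
                                     else "controls",
                       z_stratum = zStratum,
                       z_order = "lfc-then-average-then-z"),
       rowData = as.data.frame(SummarizedExperiment::rowData(se)))
}

#' Gene-normalized depletion percentiles per guide
#'
#' Percentile rank of the replicate-averaged LFC within each gene, with
#' the most-depleted construct receiving the highest percentile (midpoint
#' convention, average ties). Genes with a single construct are flagged
#' and excluded.
#'
#' @param result list from [logFoldChange()].
#' @param geneMap named character vector mapping construct -> gene
#'   (default: the experiment's rowData gene column).
#' @return data.frame: construct, gene, mean_lfc, depletion_percentile
#'   (NA for flagged singletons), flagged.
#' @export
genePercentile <- function(result, geneMap = NULL) {
  genes <- geneMap %||% setNames(result$rowData$gene,
                                 result$rowData$construct)
  constructs <- names(result$mean_lfc)
  df <- data.frame(construct = constructs,
                   gene = unname(genes[constructs]),
                   mean_lfc = unname(result$mean_lfc),
                   stringsAsFactors = FALSE)
  df$depletion_percentile <- NA_real_
  df$flagged <- FALSE
  for (g in unique(df$gene[!is.na(df$gene)])) {
    idx <- which(df$gene == g & !is.na(df$mean_lfc))
    if (length(idx) < 2L) {
      df$flagged[idx] <- TRUE
      next
    }
    ## more depleted (lower LFC) -> higher percentile
    df$depletion_percentile[idx] <- percentileRank(-df$mean_lfc[idx])
  }
  df
}

#' Group comparisons of depletion rates
#'
#' Two-sample comparisons use the Wilcoxon rank-sum test, matched
#' k-group comparisons the Friedman test, and monotone association
#' Spearman's rho.
#'
#' @param values numeric vector (e.g. mean LFC per construct).
#' @param grouping factor/vector of group labels (rank-sum when 2 groups
#'   survive; groups with fewer than 2 members are excluded with a
#'   warning), or numeric scores for `test = "spearman"`.
#' @param test "ranksum", "spearman", or "friedman".
#' @param blocks for "friedman": block labels (matched units).
#' @return list with the statistic, `p_value`, `n` per group, and the
#'   test name.
#' @export
groupTests <- function(values, grouping, test = c("ranksum", "spearman",
                                                  "friedman"),
                       blocks = NULL) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(grouping)
  values <- values[keep]
  grouping <- grouping[keep]
  if (test == "spearman") {
    ct <- suppressWarnings(stats::cor.test(values, as.numeric(grouping),
                                           method = "spearman"))
    return(list(test = "spearman", rho = unname(ct$estimate),
                p_value = ct$p.value, n = length(values)))
  }
  if (test == "friedman") {
    if (is.null(blocks)) stop("friedman test requires blocks")
    blocks <- blocks[keep]
    ft <- stats::friedman.test(values, groups = factor(grouping),
                               blocks = factor(blocks))
    return(list(test = "friedman", statistic = unname(ft$statistic),
                p_value = ft$p.value,
                n = table(grouping)))
  }
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep2 <- !grouping %in% small
    values <- values[keep2]
    grouping <- grouping[keep2]
    sizes <- table(grouping)
  }
  if (length(sizes) != 2L)
    stop("rank-sum comparison requires exactly 2 groups (got ",
         length(sizes), ")")
  g <- names(sizes)
  wt <- stats::wilcox.test(values[grouping == g[1]],
                           values[grouping == g[2]], exact = FALSE)
  list(test = "ranksum", statistic = unname(wt$statistic),
       p_value = wt$p.value, n = sizes)
}

#' Per-guide decomposition of dual-construct depletion
#'
#' For each essential-gene guide: the mean LFC over constructs pairing it
#' with a non-essential-gene guide, and over constructs pairing it with
#' another guide targeting the same gene. Guides lacking either partner
#' class are excluded.
#'
#' @param result list from [logFoldChange()]; `rowData` must carry
#'   `h_guide`, `c_guide`.
#' @param guideGenes named character vector guide -> gene.
#' @param guideClasses named character vector guide -> "EG"/"NEG"/"other".
#' @return data.frame: guide, gene, mean_lfc_neg_partner,
#'   mean_lfc_same_gene_partner (empty when no dual metadata exists).
#' @export
dualConstructDecomposition <- function(result, guideGenes, guideClasses) {
  rd <- result$rowData
  if (is.null(rd$h_guide) || all(is.na(rd$h_guide)))
    return(data.frame(guide = character(0), gene = character(0),
                      mean_lfc_neg_partner = numeric(0),
                      mean_lfc_same_gene_partner = numeric(0)))
  lfc <- result$mean_lfc[rd$construct]
  egGuides <- names(guideClasses)[guideClasses == "EG"]
  rows <- list()
  for (g in egGuides) {
    inH <- rd$h_guide == g
    inC <- rd$c_guide == g
    partner <- ifelse(inH, rd$c_guide, ifelse(inC, rd$h_guide, NA))
    sel <- (inH | inC) & !is.na(lfc)
    if (!any(sel)) next
    pClass <- guideClasses[partner[sel]]
    pGene <- guideGenes[partner[sel]]
    negSel <- which(sel)[pClass == "NEG"]
    sameSel <- which(sel)[pGene == guideGenes[[g]] & partner[sel] != g]
    if (!length(negSel) || !length(sameSel)) next
    rows[[g]] <- data.frame(
      guide = g, gene = guideGenes[[g]],
      mean_lfc_neg_partner = mean(lfc[negSel]),
      mean_lfc_same_gene_partner = mean(lfc[sameSel]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(guide = character(0), gene = character(0),
                      mean_lfc_neg_partner = numeric(0),
                      mean_lfc_same_gene_partner = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Gene-level hit calling with TPR/FPR per stringency
#'
#' At stringency q, the most-depleted q% of constructs (by mean LFC) are
#' flagged; a gene is a hit iff at least `minConstructs` of its constructs
#' are flagged. With EG genes as true positives and NEG genes as true
#' negatives, TPR and FPR are the hit fractions of each class; unlabeled
#' genes are reported but excluded from the rates.
#'
#' @param result list from [logFoldChange()].
#' @param stringencies quantiles in percent (default `c(10, 20, 30, 40,
#'   50)`).
#' @param minConstructs minimum depleted constructs per hit (default 2).
#' @param geneMap named construct -> gene map (default from rowData).
#' @param geneClasses named gene -> class ("EG"/"NEG"/other) vector
#'   (default derived from rowData).
#' @return list with `hits` (data.frame gene x stringency logical) and
#'   `rates` (data.frame: stringency, tpr, fpr, n_eg, n_neg).
#' @export
geneHits <- function(result, stringencies = c(10, 20, 30, 40, 50),
                     minConstructs = 2L, geneMap = NULL,
                     geneClasses = NULL) {
  rd <- result$rowData
  genes <- geneMap %||% setNames(rd$gene, rd$construct)
  if (is.null(geneClasses)) {
    geneClasses <- tapply(as.character(rd$class), rd$gene,
                          function(v) v[1])
  }
  lfc <- result$mean_lfc
  ok <- !is.na(lfc) & !is.na(genes[names(lfc)])
  lfc <- lfc[ok]
  gg <- genes[names(lfc)]
  geneIds <- sort(unique(gg))
  hits <- data.frame(gene = geneIds, stringsAsFactors = FALSE)
  rates <- list()
  for (q in stringencies) {
    thr <- quantile(lfc, q / 100, names = FALSE, type = 7)
    flagged <- lfc <= thr
    nHit <- tapply(flagged, gg, sum)
    isHit <- !is.na(nHit[geneIds]) & nHit[geneIds] >= minConstructs
    hits[[paste0("q", q)]] <- unname(isHit)
    cls <- geneClasses[geneIds]
    eg <- which(cls == "EG")
    neg <- which(cls == "NEG")
    rates[[as.character(q)]] <- data.frame(
      stringency = q,
      tpr = if (length(eg)) mean(isHit[eg]) else NA_real_,
      fpr = if (length(neg)) mean(isHit[neg]) else NA_real_,
      n_eg = length(eg), n_neg = length(neg))
  }
  list(hits = hits, rates = do.call(rbind, c(rates,
                                             list(make.row.names = FALSE))))
}

#' Count exact 20-nt prefix matches against a library index
#'
#' Thin optional counter for fixture FASTQ-like read vectors: each read's
#' first 20 nt is matched exactly against the library's guide sequences.
#'
#' @param reads character vector of reads.
#' @param library named character vector construct -> 20-nt guide sequence.
#' @return named integer vector of counts per construct.
#' @export
countGuideReads <- function(reads, library) {
  pre <- substr(toupper(reads), 1L, 20L)
  idx <- match(pre, toupper(library))
  tab <- table(factor(names(library)[idx], levels = names(library)))
  out <- as.integer(tab)
  names(out) <- names(library)
  out
}
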