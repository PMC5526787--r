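## Seed-deterministic generators for every input the toolkit consumes,
## each planting a known ground truth that the test suite recovers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.randSeq <- function(n) paste(sample(DNA_BASES4, n, replace = TRUE),
                              collapse = "")

.randCds <- function(nCodons) {
  ## ATG + random non-stop codons + TAA; length divisible by 3
  body <- character(nCodons - 2L)
  i <- 1L
  while (i <= length(body)) {
    cd <- .randSeq(3L)
    if (!cd %in% STOP_CODONS) {
      body[i] <- cd
      i <- i + 1L
    }
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

.countNGG <- function(s) {
  subj <- Biostrings::DNAString(s)
  length(Biostrings::matchPattern(Biostrings::DNAString("NGG"), subj,
                                  fixed = FALSE)) +
    length(Biostrings::matchPattern(Biostrings::DNAString("CCN"), subj,
                                    fixed = FALSE))
}

#' Simulate a small genome with multi-exon genes
#'
#' Genes are non-overlapping, alternate strands, carry a two-exon
#' transcript whose CDS length is divisible by 3 with no internal stop
#' codons, and are re-sampled until each locus contains at least
#' `minPamSites` NGG target sites.
#'
#' @param nGenes number of genes (default 40).
#' @param cdsCodons codons per CDS (default 160).
#' @param intronLen intron length in nt (default 40).
#' @param spacerLen intergenic spacer length (default 60).
#' @param minPamSites minimum NGG sites per gene locus (default 20).
#' @param seed RNG seed.
#' @param fastaPath,gffPath optional output paths; written when supplied
#'   (FASTA via Biostrings, GFF3 via rtracklayer).
#' @return list with `seqs` (named character, one chromosome), `models`
#'   (list of [GeneModel-class]) and `geneStrands`.
#' @export
simulateGenome <- function(nGenes = 40L, cdsCodons = 160L, intronLen = 40L,
                           spacerLen = 60L, minPamSites = 20L, seed = 1L,
                           fastaPath = NULL, gffPath = NULL) {
  set.seed(seed)
  chromParts <- character(0)
  cursor <- 0L
  models <- list()
  strands <- character(0)
  for (g in seq_len(nGenes)) {
    spacer <- .randSeq(spacerLen)
    repeat {
      cds <- .randCds(cdsCodons)
      if (.countNGG(cds) >= minPamSites) break
    }
    strand <- if (g %% 2L == 1L) "+" else "-"
    ## split the CDS into two exons around an intron; exon1 length is a
    ## non-multiple of 3 so the splice junction interrupts a codon
    cdsLen <- nchar(cds)
    e1 <- (cdsLen %/% 2L) + 1L
    intron <- paste0("GT", .randSeq(intronLen - 4L), "AG")
    locusPlus <- if (strand == "+") {
      paste0(substr(cds, 1L, e1), intron, substr(cds, e1 + 1L, cdsLen))
    } else {
      revcompChar(paste0(substr(cds, 1L, e1), intron,
                         substr(cds, e1 + 1L, cdsLen)))
    }
    start0 <- cursor + spacerLen
    ex1 <- c(start0, start0 + e1)
    ex2 <- c(start0 + e1 + intronLen, start0 + nchar(locusPlus))
    if (strand == "-") {
      ## genomic order after reverse-complementing the locus
      total <- nchar(locusPlus)
      ex1g <- c(start0 + total - (e1), start0 + total)
      ex2g <- c(start0, start0 + (cdsLen - e1))
      exons <- rbind(ex2g, ex1g)
    } else {
      exons <- rbind(ex1, ex2)
    }
    gid <- sprintf("gene%03d", g)
    tid <- paste0(gid, ".t1")
    models[[gid]] <- GeneModel(gid, "chrS", list(list(
      transcriptId = tid, strand = strand, exons = exons, cds = exons)))
    strands[gid] <- strand
    chromParts <- c(chromParts, spacer, locusPlus)
    cursor <- start0 + nchar(locusPlus)
  }
  chrom <- paste0(paste(chromParts, collapse = ""), .randSeq(spacerLen))
  seqs <- c(chrS = chrom)
  if (!is.null(fastaPath)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fastaPath)
  }
  if (!is.null(gffPath)) .writeGff3(models, gffPath)
  list(seqs = seqs, models = models, geneStrands = strands)
}

.writeGff3 <- function(models, path) {
  rows <- list()
  for (gm in models) {
    gspan <- range(unlist(lapply(gm@transcripts, function(tx) tx$exons)))
    st <- gm@transcripts[[1]]$strand
    add <- function(type, s0, e0, id = NA, parent = NA, phase = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        seqnames = gm@chrom, start = s0 + 1L, end = e0, strand = st,
        type = type, ID = id, Parent = parent, phase = phase,
        stringsAsFactors = FALSE)
    }
    add("gene", gspan[1], gspan[2], id = gm@geneId)
    for (tx in gm@transcripts) {
      txspan <- range(tx$exons)
      add("mRNA", txspan[1], txspan[2], id = tx$transcriptId,
          parent = gm@geneId)
      for (i in seq_len(nrow(tx$exons)))
        add("exon", tx$exons[i, 1], tx$exons[i, 2],
            id = paste0(tx$transcriptId, ".exon", i),
            parent = tx$transcriptId)
      ord <- if (tx$strand == "+") seq_len(nrow(tx$cds))
             else rev(seq_len(nrow(tx$cds)))
      done <- 0L
      for (i in ord) {
        add("CDS", tx$cds[i, 1], tx$cds[i, 2],
            id = paste0(tx$transcriptId, ".cds", i),
            parent = tx$transcriptId,
            phase = (3L - done %% 3L) %% 3L)
        done <- done + tx$cds[i, 2] - tx$cds[i, 1]
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$phase <- as.integer(df$phase)
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate an sgRNA efficacy training table
#'
#' Potency is a known sequence rule plus gaussian noise: a weight on the
#' protospacer's GC fraction and a weight on the presence of a planted
#' favorable 3mer at a fixed context position (planted into a fraction of
#' guides). Efficacy percentiles are computed within gene.
#'
#' @param nGenes genes (default 20).
#' @param guidesPerGene guides per gene (default 10).
#' @param gcWeight weight on protospacer GC fraction (default 2).
#' @param merWeight weight on the planted 3mer indicator (default 1).
#' @param plantedMer the favorable 3mer (default "TGG", context offsets
#'   17-19).
#' @param plantProb fraction of guides carrying the planted 3mer
#'   (default 0.3).
#' @param noiseSd gaussian noise on the latent potency (default 0.15).
#' @param seed RNG seed.
#' @return data.frame `context30`, `gene_id`, `efficacy`,
#'   `efficacy_percentile`; attribute `truth` records the rule.
#' @export
simulateEfficacyData <- function(nGenes = 20L, guidesPerGene = 10L,
                                 gcWeight = 2, merWeight = 1,
                                 plantedMer = "TGG", plantProb = 0.3,
                                 noiseSd = 0.15, seed = 2L) {
  set.seed(seed)
  n <- nGenes * guidesPerGene
  ctx <- vapply(seq_len(n), function(i) .randSeq(30L), character(1))
  plant <- runif(n) < plantProb
  substr(ctx[plant], 17L, 19L) <- plantedMer
  hasMer <- substr(ctx, 17L, 19L) == plantedMer
  gc <- gcFraction(substr(ctx, 5L, 24L))
  latent <- gcWeight * gc + merWeight * hasMer + rnorm(n, 0, noiseSd)
  df <- data.frame(
    context30 = ctx,
    gene_id = rep(sprintf("gene%03d", seq_len(nGenes)), each = guidesPerGene),
    efficacy = latent, stringsAsFactors = FALSE)
  df$efficacy_percentile <- stats::ave(df$efficacy, df$gene_id,
                                       FUN = percentileRank)
  attr(df, "truth") <- list(gcWeight = gcWeight, merWeight = merWeight,
                            plantedMer = plantedMer, noiseSd = noiseSd,
                            gc = gc, hasMer = hasMer, latent = latent)
  df
}

#' Simulate a repair-resolution training table
#'
#' @param n rows (default 500).
#' @param coefficients named truth vector (intercept, length, gc_fraction,
#'   distance); defaults 0.1, 0.05, 0.3, -0.01.
#' @param noiseSd gaussian noise on frequency (default 0.01).
#' @param seed RNG seed.
#' @return data.frame `length`, `gc_fraction`, `distance`, `frequency`;
#'   attribute `truth` holds the coefficients.
#' @export
simulateResolutionTable <- function(n = 500L,
                                    coefficients = c(intercept = 0.1,
                                                     length = 0.05,
                                                     gc_fraction = 0.3,
                                                     distance = -0.01),
                                    noiseSd = 0.01, seed = 5L) {
  set.seed(seed)
  len <- sample(2:12, n, replace = TRUE)
  gc <- round(runif(n), 3)
  dist <- sample(0:40, n, replace = TRUE)
  if (length(unique(len)) < 2L || length(unique(dist)) < 2L)
    stop("degenerate design: constant predictor")
  freq <- coefficients[["intercept"]] + coefficients[["length"]] * len +
    coefficients[["gc_fraction"]] * gc +
    coefficients[["distance"]] * dist + rnorm(n, 0, noiseSd)
  df <- data.frame(length = len, gc_fraction = gc, distance = dist,
                   frequency = freq)
  attr(df, "truth") <- coefficients
  df
}

#' Simulate a pooled screen count table
#'
#' Negative-binomial counts for a construct library over 3 replicates
#' with reference and final timepoints. Essential-gene (EG) constructs
#' deplete by `delta` log2 units between timepoints; non-essential (NEG)
#' constructs are null. Depletion is planted on the relative-abundance
#' scale used downstream: measured log fold changes are interpretable
#' after centering on the NEG controls.
#'
#' @param library data.frame with `construct`, `gene`, `class`
#'   ("EG"/"NEG") and optionally `h_guide`, `c_guide`. Defaults to a
#'   20 EG + 20 NEG, 5-construct-per-gene library.
#' @param delta planted EG log2 depletion (default -2).
#' @param depth mean reference reads per construct (default 1000).
#' @param dispersion negative-binomial dispersion (default 0.05; variance
#'   = mu + dispersion * mu^2).
#' @param nReplicates replicates (default 3).
#' @param seed RNG seed.
#' @return list with `counts` (long data.frame construct/sample/count),
#'   `samples`, `library`, and `truth` (per-construct planted lfc).
#' @export
simulateScreen <- function(library = NULL, delta = -2, depth = 1000,
                           dispersion = 0.05, nReplicates = 3L,
                           seed = 11L) {
  set.seed(seed)
  if (is.null(library)) library <- defaultScreenLibrary()
  planted <- ifelse(library$class == "EG", delta, 0)
  samples <- do.call(rbind, lapply(seq_len(nReplicates), function(r) {
    data.frame(sample = sprintf("rep%d_%s", r, c("reference", "final")),
               replicate = paste0("rep", r),
               timepoint = c("reference", "final"),
               cell_line = "A375like", stringsAsFactors = FALSE)
  }))
  size <- 1 / dispersion
  counts <- list()
  for (r in seq_len(nReplicates)) {
    refMu <- depth
    ref <- stats::rnbinom(nrow(library), mu = refMu, size = size)
    fin <- stats::rnbinom(nrow(library), mu = refMu * 2^planted, size = size)
    counts[[length(counts) + 1L]] <- data.frame(
      construct = library$construct,
      sample = sprintf("rep%d_reference", r), count = ref,
      stringsAsFactors = FALSE)
    counts[[length(counts) + 1L]] <- data.frame(
      construct = library$construct,
      sample = sprintf("rep%d_final", r), count = fin,
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, counts), samples = samples,
       library = library,
       truth = setNames(planted, library$construct))
}

#' Default 20 EG + 20 NEG screen library (5 constructs per gene)
#' @return data.frame `construct`, `gene`, `class`.
#' @export
defaultScreenLibrary <- function() {
  genes <- c(sprintf("EG%02d", 1:20), sprintf("NEG%02d", 1:20))
  cls <- rep(c("EG", "NEG"), each = 20L)
  do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(construct = sprintf("%s_c%d", genes[i], 1:5),
               gene = genes[i], class = cls[i], stringsAsFactors = FALSE)
  }))
}

#' Simulate per-residue conservation profiles
#'
#' PROVEAN-convention scores (negative = deleterious). A fraction of each
#' protein is a planted conserved block with strongly negative scores.
#'
#' @param geneIds protein/gene ids.
#' @param lengths residues per protein (recycled).
#' @param seed RNG seed.
#' @return named list of numeric score vectors.
#' @export
simulateConservationProfiles <- function(geneIds, lengths = 160L,
                                         seed = 7L) {
  set.seed(seed)
  lengths <- rep_len(lengths, length(geneIds))
  out <- lapply(seq_along(geneIds), function(i) {
    n <- lengths[i]
    sc <- rnorm(n, mean = -1, sd = 0.8)
    blockStart <- sample.int(max(1L, n - 30L), 1L)
    sc[blockStart:(blockStart + 29L)] <- rnorm(30L, mean = -6, sd = 1)
    sc
  })
  names(out) <- geneIds
  out
}

SCAR_CLASSES <- c("no_edit", "h_indel", "c_indel", "dual_indel",
                  "dsb_dsb", "non_dsb_dsb")

#' Simulate an aligned amplicon SAM with planted scar classes
#'
#' Each fragment is assigned a scar class from `mixture`, its edited
#' sequence and CIGAR are constructed accordingly, and both mates are
#' emitted covering the full amplicon, so mate merging is exercised
#' without discordance. A ground-truth sidecar maps fragment ids to
#' planted classes.
#'
#' @param amplicon an [AmpliconSpec-class].
#' @param n fragments (default 2000).
#' @param mixture named proportions over
#'   no_edit/h_indel/c_indel/dual_indel/dsb_dsb/non_dsb_dsb; default
#'   0.1/0.2/0.2/0.1/0.4/0.
#' @param seed RNG seed.
#' @param samPath output SAM path.
#' @param truthPath optional ground-truth TSV path.
#' @return invisible data.frame (fragment, class) of planted truth.
#' @export
simulateScarSam <- function(amplicon, n = 2000L,
                            mixture = c(no_edit = 0.1, h_indel = 0.2,
                                        c_indel = 0.2, dual_indel = 0.1,
                                        dsb_dsb = 0.4, non_dsb_dsb = 0),
                            seed = 15L, samPath, truthPath = NULL) {
  set.seed(seed)
  stopifnot(all(names(mixture) %in% SCAR_CLASSES))
  mixture <- mixture / sum(mixture)
  ref <- amplicon@refseq
  L <- nchar(ref)
  ## the class composition is the planted ground truth, so it is allocated
  ## exactly (largest-remainder rounding) and only the order is sampled
  alloc <- floor(mixture * n)
  rem <- mixture * n - alloc
  short <- n - sum(alloc)
  if (short > 0L) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    alloc[bump] <- alloc[bump] + 1L
  }
  classes <- sample(rep(names(mixture), times = alloc))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", amplicon@ampliconId, L))
  lines <- character(0)
  truth <- data.frame(fragment = sprintf("frag%05d", seq_len(n)),
                      class = classes, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ed <- .plantEdits(classes[i], amplicon)
    sq <- .applyEdits(ref, ed)
    cg <- .editsToCigar(ed, L)
    qn <- truth$fragment[i]
    lines <- c(lines,
               paste(qn, 99L, amplicon@ampliconId, 1L, 60L, cg, "=", 1L,
                     L, sq, "*", sep = "\t"),
               paste(qn, 147L, amplicon@ampliconId, 1L, 60L, cg, "=", 1L,
                     -L, sq, "*", sep = "\t"))
  }
  writeLines(c(header, lines), samPath)
  if (!is.null(truthPath)) writeTsv(truth, truthPath)
  invisible(truth)
}

## edits: data.frame(op, start, width) in 0-based ref coords, sorted
.plantEdits <- function(class, amp) {
  cutH <- amp@cutH
  cutC <- amp@cutC
  smallIndel <- function(cut) {
    if (runif(1) < 0.5) {
      w <- sample(1:2, 1L)
      data.frame(op = "D", start = cut - sample(0:1, 1L), width = w)
    } else {
      data.frame(op = "I", start = cut, width = sample(1:2, 1L))
    }
  }
  switch(class,
    no_edit = data.frame(op = character(0), start = integer(0),
                         width = integer(0)),
    h_indel = smallIndel(cutH),
    c_indel = smallIndel(cutC),
    dual_indel = rbind(smallIndel(cutH), smallIndel(cutC)),
    dsb_dsb = data.frame(op = "D", start = cutH, width = cutC - cutH),
    non_dsb_dsb = {
      ext <- sample(1:3, 2L, replace = TRUE)
      data.frame(op = "D", start = cutH - ext[1],
                 width = (cutC + ext[2]) - (cutH - ext[1]))
    })
}

.applyEdits <- function(ref, edits) {
  if (!nrow(edits)) return(ref)
  edits <- edits[order(edits$start), , drop = FALSE]
  out <- ""
  cursor <- 0L
  for (k in seq_len(nrow(edits))) {
    out <- paste0(out, substr(ref, cursor + 1L, edits$start[k]))
    if (edits$op[k] == "I") {
      out <- paste0(out, paste(sample(DNA_BASES4, edits$width[k],
                                      replace = TRUE), collapse = ""))
      cursor <- edits$start[k]
    } else {
      cursor <- edits$start[k] + edits$width[k]
    }
  }
  paste0(out, substr(ref, cursor + 1L, nchar(ref)))
}

.editsToCigar <- function(edits, L) {
  if (!nrow(edits)) return(paste0(L, "M"))
  edits <- edits[order(edits$start), , drop = FALSE]
  parts <- character(0)
  cursor <- 0L
  for (k in seq_len(nrow(edits))) {
    m <- edits$start[k] - cursor
    if (m > 0L) parts <- c(parts, paste0(m, "M"))
    parts <- c(parts, paste0(edits$width[k], edits$op[k]))
    if (edits$op[k] == "D") cursor <- edits$start[k] + edits$width[k]
    else cursor <- edits$start[k]
  }
  if (L - cursor > 0L) parts <- c(parts, paste0(L - cursor, "M"))
  paste(parts, collapse = "")
}
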