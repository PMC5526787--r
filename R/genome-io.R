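## Sequence and gene-model input, and enumeration of candidate Cas9 targets.
##
## SpCas9 geometry used throughout: 20-nt protospacer immediately 5' of an
## NGG PAM; blunt cut 3 bp 5' of the PAM, i.e. between protospacer bases 17
## and 18. The 30-nt context window is 4 nt upstream of the protospacer,
## the protospacer itself, and 6 nt downstream (the PAM is the first 3 of
## those 6).

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Read a (multi-line) FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercased sequences; names are the
#'   first whitespace token of each header.
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    any(!ch %in% IUPAC_DNA)
  }, logical(1))
  if (any(bad)) {
    ## locate the first offending line for the error message
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">") || !nzchar(ln)) next
      ch <- unique(strsplit(toupper(ln), "")[[1]])
      if (any(!ch %in% IUPAC_DNA))
        stop(sprintf("non-IUPAC residue at line %d of %s", i, path),
             call. = FALSE)
    }
    stop("non-IUPAC residue in ", path, call. = FALSE)
  }
  seqs
}

#' Construct a gene model
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param transcripts list of transcripts; each a list with `transcriptId`,
#'   `strand`, and two-column integer matrices `exons` and `cds` in 0-based
#'   half-open genomic coordinates (genomic order on both strands).
#' @return a validated [GeneModel-class].
#' @export
GeneModel <- function(geneId, chrom, transcripts) {
  transcripts <- lapply(transcripts, function(tx) {
    tx$exons <- matrix(as.integer(tx$exons), ncol = 2L,
                       dimnames = list(NULL, c("start", "end")))
    tx$cds <- matrix(as.integer(tx$cds %||% integer(0)), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
    tx
  })
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcriptId")
  new("GeneModel", geneId = geneId, chrom = chrom, transcripts = transcripts)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates (1-based closed) and BED12 coordinates (0-based
#' half-open) are both converted to the package's internal 0-based half-open
#' convention. In BED12 the name field may be `geneId|transcriptId`; a bare
#' name is used as both.
#'
#' @param path annotation file.
#' @param dialect "gff3" or "bed12".
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") .geneModelsFromGff3(path) else .geneModelsFromBed12(path)
}

.geneModelsFromGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- md$Parent  # CharacterList
  firstParent <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))

  geneIdx <- which(typ == "gene")
  txIdx <- which(typ %in% c("mRNA", "transcript"))
  models <- list()
  for (g in geneIdx) {
    gid <- ids[g]
    chrom <- as.character(GenomicRanges::seqnames(gr)[g])
    txs <- list()
    for (t in txIdx[firstParent[txIdx] == gid]) {
      tid <- ids[t]
      strand <- as.character(GenomicRanges::strand(gr)[t])
      kids <- which(firstParent == tid)
      exR <- kids[typ[kids] == "exon"]
      cdR <- kids[typ[kids] == "CDS"]
      toMat <- function(idx) {
        if (!length(idx)) return(matrix(integer(0), ncol = 2L))
        m <- cbind(GenomicRanges::start(gr)[idx] - 1L,
                   GenomicRanges::end(gr)[idx])
        m[order(m[, 1L]), , drop = FALSE]
      }
      txs[[tid]] <- list(transcriptId = tid, strand = strand,
                         exons = toMat(exR), cds = toMat(cdR))
    }
    models[[gid]] <- GeneModel(gid, chrom, txs)
  }
  models
}

.geneModelsFromBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  models <- list()
  for (i in seq_along(gr)) {
    nm <- S4Vectors::mcols(gr)$name[i]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    gid <- parts[1]
    tid <- if (length(parts) > 1L) parts[2] else parts[1]
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    strand <- as.character(GenomicRanges::strand(gr)[i])
    blocks <- S4Vectors::mcols(gr)$blocks[[i]]  # IRanges relative, 1-based
    chromStart <- GenomicRanges::start(gr)[i] - 1L  # back to 0-based
    exons <- cbind(chromStart + IRanges::start(blocks) - 1L,
                   chromStart + IRanges::end(blocks))
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    thick <- S4Vectors::mcols(gr)$thick[i]
    cds <- matrix(integer(0), ncol = 2L)
    if (length(thick) && IRanges::width(thick) > 0L) {
      ts <- IRanges::start(thick) - 1L
      te <- IRanges::end(thick)
      keep <- pmax(exons[, 1L], ts) < pmin(exons[, 2L], te)
      if (any(keep))
        cds <- cbind(pmax(exons[keep, 1L], ts), pmin(exons[keep, 2L], te))
    }
    txs <- list(list(transcriptId = tid, strand = strand,
                     exons = exons, cds = cds))
    if (is.null(models[[gid]])) {
      models[[gid]] <- GeneModel(gid, chrom, txs)
    } else {
      old <- models[[gid]]@transcripts
      old[[tid]] <- txs[[1]]
      models[[gid]] <- GeneModel(gid, chrom, old)
    }
  }
  models
}

## spliced CDS coordinate (0-based) of a genomic base within a transcript;
## NA when the base is not in CDS
.cdsPosition <- function(tx, base) {
  cds <- tx$cds
  if (nrow(cds) == 0L) return(NA_integer_)
  hit <- which(cds[, 1L] <= base & base < cds[, 2L])
  if (!length(hit)) return(NA_integer_)
  if (tx$strand == "+") {
    before <- if (hit > 1L) sum(cds[seq_len(hit - 1L), 2L] -
                                cds[seq_len(hit - 1L), 1L]) else 0L
    as.integer(before + base - cds[hit, 1L])
  } else {
    n <- nrow(cds)
    after <- if (hit < n) sum(cds[(hit + 1L):n, 2L] -
                              cds[(hit + 1L):n, 1L]) else 0L
    as.integer(after + cds[hit, 2L] - 1L - base)
  }
}

#' Enumerate candidate Cas9 target sites
#'
#' Scans both strands of each input sequence for PAM matches and emits one
#' site per hit whose 30-nt context window is fully contained in the
#' sequence and free of ambiguity codes. Cut coordinates are 0-based
#' boundary indices (blunt cut 3 bp 5' of the PAM).
#'
#' @param seqs named character vector (or DNAStringSet) of chromosome or
#'   transcript sequences.
#' @param geneModels optional list of [GeneModel-class]; when supplied each
#'   site is annotated with the transcripts whose exons span its cut and,
#'   when the cut lies in CDS, the 0-based amino-acid index of the codon
#'   containing the first base 3' of the cut (in transcript orientation).
#' @param pam PAM pattern; A/C/G/T/N only (default "NGG").
#' @return a [GenomicRanges::GRanges] over the protospacer intervals with
#'   metadata columns `site_id`, `protospacer`, `pam`, `cut_coord`,
#'   `context30`, `transcripts` (CharacterList), `gene`, `cds_aa_index`.
#' @export
enumerateTargets <- function(seqs, geneModels = list(), pam = "NGG") {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  pam <- toupper(pam)
  if (grepl("[^ACGTN]", pam))
    stop("PAM pattern may contain only A, C, G, T and N")
  out <- list()
  for (chrom in names(seqs)) {
    s <- toupper(seqs[[chrom]])
    L <- nchar(s)
    if (L < 30L) next
    subj <- Biostrings::DNAString(s)
    plen <- nchar(pam)

    ## plus strand: PAM at 0-based p; protospacer [p-20, p); context
    ## [p-24, p+6); cut boundary p-3
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(pam), subj,
                                    fixed = FALSE)
    for (p in Biostrings::start(fwd) - 1L) {
      if (p < 24L || p + 6L > L) next
      ctx <- substr(s, p - 24L + 1L, p + 6L)
      if (grepl("[^ACGT]", ctx)) next
      out[[length(out) + 1L]] <- .makeSite(chrom, "+", p - 20L,
                                           substr(s, p - 20L + 1L, p),
                                           substr(s, p + 1L, p + plen),
                                           p - 3L, ctx, geneModels)
    }

    ## minus strand: revcomp PAM at 0-based q on plus; protospacer plus
    ## coords [q+3, q+23); context plus window [q-3, q+27) revcomp'd; cut
    ## boundary q+6
    rcpam <- revcompChar(pam)
    rev <- Biostrings::matchPattern(Biostrings::DNAString(rcpam), subj,
                                    fixed = FALSE)
    for (q in Biostrings::start(rev) - 1L) {
      if (q < 3L || q + 27L > L) next
      win <- substr(s, q - 3L + 1L, q + 27L)
      if (grepl("[^ACGT]", win)) next
      proto <- revcompChar(substr(s, q + 3L + 1L, q + 23L))
      out[[length(out) + 1L]] <- .makeSite(chrom, "-", q + 3L, proto,
                                           revcompChar(substr(s, q + 1L,
                                                              q + plen)),
                                           q + 6L, revcompChar(win),
                                           geneModels)
    }
  }
  .sitesToGRanges(out)
}

.makeSite <- function(chrom, strand, protoStart0, protospacer, pamSeq,
                      cut, ctx, geneModels) {
  txHits <- character(0)
  gene <- NA_character_
  aa <- NA_integer_
  for (gm in geneModels) {
    if (gm@chrom != chrom) next
    for (tx in gm@transcripts) {
      ex <- tx$exons
      inExon <- nrow(ex) > 0L && any(ex[, 1L] < cut & cut < ex[, 2L])
      if (!inExon) next
      txHits <- c(txHits, tx$transcriptId)
      if (is.na(gene)) gene <- gm@geneId
      if (is.na(aa)) {
        ## first base 3' of the cut in transcript orientation
        base <- if (tx$strand == "+") cut else cut - 1L
        cpos <- .cdsPosition(tx, base)
        if (!is.na(cpos)) aa <- cpos %/% 3L
      }
    }
  }
  list(chrom = chrom, strand = strand, protoStart0 = protoStart0,
       protospacer = protospacer, pam = pamSeq, cut = cut, context30 = ctx,
       transcripts = txHits, gene = gene, aa = aa)
}

.sitesToGRanges <- function(sites) {
  if (!length(sites)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      site_id = character(0), protospacer = character(0),
      pam = character(0), cut_coord = integer(0), context30 = character(0),
      transcripts = IRanges::CharacterList(), gene = character(0),
      cds_aa_index = integer(0))
    return(gr)
  }
  chrom <- vapply(sites, `[[`, character(1), "chrom")
  strand <- vapply(sites, `[[`, character(1), "strand")
  p0 <- vapply(sites, `[[`, integer(1), "protoStart0")
  cut <- vapply(sites, `[[`, integer(1), "cut")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = p0 + 1L, width = 20L),
    strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    site_id = sprintf("%s:%s:%d", chrom, strand, cut),
    protospacer = vapply(sites, `[[`, character(1), "protospacer"),
    pam = vapply(sites, `[[`, character(1), "pam"),
    cut_coord = cut,
    context30 = vapply(sites, `[[`, character(1), "context30"),
    transcripts = IRanges::CharacterList(lapply(sites, `[[`, "transcripts")),
    gene = vapply(sites, `[[`, character(1), "gene"),
    cds_aa_index = vapply(sites, `[[`, integer(1), "aa"))
  gr[order(chrom, cut, strand)]
}

#' Write / read the target-site table
#'
#' TSV columns: site_id, chrom, strand, cut_coord, protospacer, pam,
#' context30, transcripts (comma-joined), gene, cds_aa_index.
#'
#' @param sites GRanges from [enumerateTargets()].
#' @param path output TSV path.
#' @export
writeTargetsTsv <- function(sites, path) {
  md <- S4Vectors::mcols(sites)
  df <- data.frame(
    site_id = md$site_id,
    chrom = as.character(GenomicRanges::seqnames(sites)),
    strand = as.character(GenomicRanges::strand(sites)),
    cut_coord = md$cut_coord,
    protospacer = md$protospacer,
    pam = md$pam,
    context30 = md$context30,
    transcripts = vapply(md$transcripts, paste, character(1), collapse = ","),
    gene = md$gene,
    cds_aa_index = md$cds_aa_index,
    stringsAsFactors = FALSE)
  writeTsv(df, path)
  invisible(path)
}

#' @rdname writeTargetsTsv
#' @return `readTargetsTsv` returns the GRanges representation.
#' @export
readTargetsTsv <- function(path) {
  df <- readTsv(path)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(
      start = ifelse(df$strand == "+", df$cut_coord - 17L,
                     df$cut_coord - 3L) + 1L,
      width = 20L),
    strand = df$strand)
  tx <- strsplit(ifelse(is.na(df$transcripts), "", df$transcripts), ",")
  tx <- lapply(tx, function(v) v[nzchar(v)])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    site_id = df$site_id, protospacer = df$protospacer, pam = df$pam,
    cut_coord = as.integer(df$cut_coord), context30 = df$context30,
    transcripts = IRanges::CharacterList(tx), gene = df$gene,
    cds_aa_index = as.integer(df$cds_aa_index))
  gr
}
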