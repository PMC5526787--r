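## Dual-cut genomic scar classification from aligned amplicon read pairs.
##
## Only CIGAR insertion/deletion operations count as edits (M mismatches
## and soft clips are ignored). Mates of a fragment are merged; a
## fragment is classified as no_edit, h_indel, c_indel, dual_indel or
## fragment_deletion, the latter subclassified dsb_dsb when a single
## deletion runs exactly from cut to cut with no other edits on the
## fragment, else non_dsb_dsb.

#' Parse aligned amplicon reads into per-fragment edit lists
#'
#' Reads a SAM (or BAM) file, extracts reference-space insertion and
#' deletion operations from each mate's CIGAR, and merges mates sharing a
#' query name into one fragment record. Fragments whose mates disagree
#' about an edit both mates cover are flagged discordant and excluded;
#' unmapped records are counted and dropped.
#'
#' @param samPath path to a SAM or BAM alignment against the amplicon.
#' @param amplicon an [AmpliconSpec-class] (used for sanity checks only).
#' @return list with `fragments` (named list; per fragment a data.frame
#'   of edits with columns `op` ("I"/"D"), `start` (0-based reference
#'   coordinate), `width`) and `stats` (counts of mapped, unmapped,
#'   discordant, skipped fragments).
#' @export
parseScarAlignments <- function(samPath, amplicon) {
  bam <- samPath
  if (grepl("\\.sam$", samPath, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(samPath, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"))
  aln <- GenomicAlignments::readGAlignments(bam, use.names = FALSE,
                                            param = param)
  md <- S4Vectors::mcols(aln)
  nUnmapped <- 0L  # readGAlignments already drops unmapped records
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  total <- tryCatch({
    cb <- Rsamtools::countBam(bam)
    cb$records
  }, error = function(e) length(aln))
  nUnmapped <- max(0L, total - length(aln))

  cig <- GenomicAlignments::cigar(aln)
  pos <- GenomicAlignments::start(aln)  # 1-based leftmost ref position
  ends <- GenomicAlignments::end(aln)
  qnames <- md$qname

  edits <- lapply(seq_along(aln), function(i) .cigarEdits(cig[i], pos[i]))
  frags <- split(seq_along(aln), qnames)

  skipped <- 0L
  discordant <- 0L
  single <- 0L
  out <- list()
  for (qn in names(frags)) {
    idx <- frags[[qn]]
    spans <- cbind(pos[idx] - 1L, ends[idx])  # 0-based half-open ref spans
    eds <- edits[idx]
    ## concordance: an edit in one mate lying inside another mate's span
    ## must be present in that mate too
    bad <- FALSE
    if (length(idx) > 1L) {
      for (a in seq_along(idx)) {
        ea <- eds[[a]]
        if (!nrow(ea)) next
        for (b in seq_along(idx)) {
          if (a == b) next
          inside <- ea$start >= spans[b, 1L] &
            (ea$start + pmax(ea$width * (ea$op == "D"), 0L)) <= spans[b, 2L]
          for (k in which(inside)) {
            hit <- any(eds[[b]]$op == ea$op[k] &
                         eds[[b]]$start == ea$start[k] &
                         eds[[b]]$width == ea$width[k])
            if (!hit) bad <- TRUE
          }
        }
      }
    }
    if (bad) {
      discordant <- discordant + 1L
      next
    }
    merged <- unique(do.call(rbind, eds))
    merged <- merged[order(merged$start, merged$op), , drop = FALSE]
    out[[qn]] <- merged
  }
  list(fragments = out,
       stats = c(fragments = length(out), records = total,
                 unmapped = nUnmapped, discordant = discordant))
}

## extract I/D operations in reference coordinates from one CIGAR
.cigarEdits <- function(cigar, pos1) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref <- pos1 - 1L  # 0-based reference cursor
  out <- list()
  for (k in seq_along(ops)) {
    op <- ops[k]
    w <- lens[k]
    if (op %in% c("M", "=", "X")) {
      ref <- ref + w
    } else if (op == "D" || op == "N") {
      out[[length(out) + 1L]] <- data.frame(op = "D", start = ref,
                                            width = w)
      ref <- ref + w
    } else if (op == "I") {
      out[[length(out) + 1L]] <- data.frame(op = "I", start = ref,
                                            width = w)
    }
    ## S, H, P consume no reference space and are not edits
  }
  if (!length(out))
    return(data.frame(op = character(0), start = integer(0),
                      width = integer(0)))
  do.call(rbind, out)
}

#' Classify one fragment's edits
#'
#' @param edits data.frame of edits (`op`, `start`, `width`) in 0-based
#'   amplicon coordinates.
#' @param amplicon an [AmpliconSpec-class].
#' @return list with `class` ("no_edit", "h_indel", "c_indel",
#'   "dual_indel", "fragment_deletion"), `subclass` ("dsb_dsb" or
#'   "non_dsb_dsb", fragment deletions only), `deletion_span` (0-based
#'   half-open, or NULL) and `stray_edits` (count of edits outside both
#'   attribution windows, diagnostics only).
#' @export
classifyFragment <- function(edits, amplicon) {
  w <- amplicon@window
  cutH <- amplicon@cutH
  cutC <- amplicon@cutC
  if (nrow(edits) == 0L)
    return(list(class = "no_edit", subclass = NA_character_,
                deletion_span = NULL, stray_edits = 0L))

  delEnd <- edits$start + ifelse(edits$op == "D", edits$width, 0L)
  ## spanning deletion: from within the h window (or before) through the
  ## c window (or beyond)
  spanning <- edits$op == "D" & edits$start <= cutH + w & delEnd >= cutC - w
  if (any(spanning)) {
    k <- which(spanning)[1]
    span <- c(edits$start[k], delEnd[k])
    exact <- nrow(edits) == 1L && edits$start[k] == cutH && delEnd[k] == cutC
    return(list(class = "fragment_deletion",
                subclass = if (exact) "dsb_dsb" else "non_dsb_dsb",
                deletion_span = span,
                stray_edits = 0L))
  }
  ## window attribution: an edit touches a cut's window if its reference
  ## footprint intersects [cut - w, cut + w]
  touches <- function(cut) {
    edits$start <= cut + w & delEnd >= cut - w
  }
  inH <- touches(cutH)
  inC <- touches(cutC)
  stray <- sum(!inH & !inC)
  cls <- if (any(inH) && any(inC)) "dual_indel"
  else if (any(inH)) "h_indel"
  else if (any(inC)) "c_indel"
  else "no_edit"
  list(class = cls, subclass = NA_character_, deletion_span = NULL,
       stray_edits = stray)
}

#' Tally scar classes and top deletion haplotypes
#'
#' @param calls list of classifications from [classifyFragment()], or a
#'   list of such lists (multi-sample mode; per-class rates are averaged
#'   across samples).
#' @param topN number of deletion haplotypes to report (default 10).
#' @return list with `fractions` (named numeric summing to 1 over
#'   classified fragments; `fragment_deletion` equals `dsb_dsb` +
#'   `non_dsb_dsb`), `n`, and `top_deletions` (data.frame: start, end,
#'   rate, ranked by frequency).
#' @export
tallyScars <- function(calls, topN = 10L) {
  multi <- length(calls) > 0L && is.list(calls[[1]]) &&
    is.list(calls[[1]][[1]])
  samples <- if (multi) calls else list(calls)
  classes <- c("no_edit", "h_indel", "c_indel", "dual_indel",
               "fragment_deletion")
  perSample <- lapply(samples, function(cl) {
    if (!length(cl)) stop("zero classified fragments")
    cls <- vapply(cl, `[[`, character(1), "class")
    sub <- vapply(cl, `[[`, character(1), "subclass")
    fr <- table(factor(cls, levels = classes)) / length(cls)
    fr <- c(as.vector(fr),
            sum(cls == "fragment_deletion" & sub == "dsb_dsb") / length(cls),
            sum(cls == "fragment_deletion" & sub == "non_dsb_dsb") /
              length(cls))
    names(fr) <- c(classes, "dsb_dsb", "non_dsb_dsb")
    dels <- Filter(function(x) !is.null(x$deletion_span), cl)
    hap <- if (length(dels)) {
      key <- vapply(dels, function(x)
        paste(x$deletion_span, collapse = "-"), character(1))
      tab <- sort(table(key), decreasing = TRUE)
      data.frame(haplotype = names(tab),
                 rate = as.vector(tab) / length(cl),
                 stringsAsFactors = FALSE)
    } else data.frame(haplotype = character(0), rate = numeric(0))
    list(fractions = fr, n = length(cl), hap = hap)
  })
  fr <- Reduce(`+`, lapply(perSample, `[[`, "fractions")) / length(perSample)
  hapAll <- do.call(rbind, lapply(perSample, `[[`, "hap"))
  top <- if (nrow(hapAll)) {
    agg <- stats::aggregate(rate ~ haplotype, hapAll,
                            FUN = function(v) sum(v) / length(perSample))
    agg <- agg[order(-agg$rate, agg$haplotype), , drop = FALSE]
    sp <- do.call(rbind, strsplit(agg$haplotype, "-"))
    data.frame(start = as.integer(sp[, 1L]), end = as.integer(sp[, 2L]),
               rate = agg$rate)[seq_len(min(topN, nrow(agg))), ,
                                drop = FALSE]
  } else data.frame(start = integer(0), end = integer(0), rate = numeric(0))
  list(fractions = fr, n = sum(vapply(perSample, `[[`, numeric(1), "n")),
       top_deletions = top)
}

#' Classify every fragment in an alignment file
#'
#' @param samPath SAM/BAM path.
#' @param amplicon an [AmpliconSpec-class].
#' @return list with `calls` (named list of classifications), `stats`
#'   from [parseScarAlignments()].
#' @export
classifyScars <- function(samPath, amplicon) {
  parsed <- parseScarAlignments(samPath, amplicon)
  calls <- lapply(parsed$fragments, classifyFragment, amplicon = amplicon)
  list(calls = calls, stats = parsed$stats)
}
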