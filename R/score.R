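## Consolidated 1-9 CRoatan guide score.
##
## Guides are first grouped by the stringency level they passed in the
## combined random-forest analysis (A, B, C; forest score 0 is excluded),
## then ranked within group by how many of the conservation and
## frameshift-likelihood tests they pass: group A spans scores 1-3,
## group B 4-6, group C 7-9.

DEFAULT_BANDS <- list(A = 1:3, B = 4:6, C = 7:10)

#' Assign a stringency group from the combined forest score
#'
#' @param forestScore integer vector in 0..10.
#' @param bands named list of integer vectors for groups A, B, C; must be
#'   disjoint and cover 1..10. Score 0 is always "excluded".
#' @return character vector in "A", "B", "C", "excluded".
#' @export
assignGroup <- function(forestScore, bands = DEFAULT_BANDS) {
  stopifnot(all(forestScore %in% 0:10))
  if (!identical(sort(names(bands)), c("A", "B", "C")))
    stop("bands must be named A, B, C")
  all_ <- unlist(bands)
  if (anyDuplicated(all_) || !setequal(all_, 1:10))
    stop("band config must partition 1..10 without overlap")
  lookup <- character(10)
  for (g in names(bands)) lookup[bands[[g]]] <- g
  ifelse(forestScore == 0L, "excluded", lookup[pmax(forestScore, 1L)])
}

#' Consolidate group and test outcomes into the 1-9 score
#'
#' `score = 3 * g + tests_passed + 1` with g = 0, 1, 2 for groups A, B, C
#' and tests_passed the number of the conservation and FSM tests passed.
#'
#' @param group character vector in "A", "B", "C".
#' @param conservationPass,fsmPass logical vectors.
#' @return integer vector in 1..9.
#' @export
consolidateScore <- function(group, conservationPass, fsmPass) {
  if (any(group == "excluded"))
    stop("excluded guides (forest score 0) have no consolidated score")
  g <- match(group, c("A", "B", "C")) - 1L
  if (any(is.na(g))) stop("group must be one of A, B, C")
  as.integer(3L * g + as.integer(conservationPass) + as.integer(fsmPass) + 1L)
}

#' Score a table of guides end to end
#'
#' @param sites GRanges from [enumerateTargets()] (or a data.frame with
#'   columns `site_id`, `context30`, `gene`, `cds_aa_index`, `cut_coord`).
#' @param ensembles list with `doench` and `chari`
#'   [StringencyEnsemble-class] objects.
#' @param repairModel a [RepairModel-class] (HEJ cutoff set if desired).
#' @param profiles named list of conservation profiles (by gene/protein id).
#' @param consThreshold conservation threshold from
#'   [conservationThreshold()].
#' @param fsmThreshold strict FSM-likelihood bound (default 0.66).
#' @param bands group band configuration.
#' @param flankAa conservation window flank (default 2).
#' @return data.frame with one row per guide: site_id, gene, cut_coord,
#'   doench_score, chari_score, forest_score, group, cons_score,
#'   cons_pass, fsm_likelihood, fsm_pass, croatan_score (NA for excluded
#'   guides).
#' @export
scoreGuides <- function(sites, ensembles, repairModel, profiles,
                        consThreshold, fsmThreshold = 0.66,
                        bands = DEFAULT_BANDS, flankAa = 2L) {
  df <- if (methods::is(sites, "GRanges")) {
    md <- S4Vectors::mcols(sites)
    data.frame(site_id = md$site_id, context30 = md$context30,
               gene = md$gene, cds_aa_index = md$cds_aa_index,
               cut_coord = md$cut_coord,
               strand = as.character(GenomicRanges::strand(sites)),
               protospacer = md$protospacer,
               transcripts = vapply(md$transcripts, paste, character(1),
                                    collapse = ","),
               stringsAsFactors = FALSE)
  } else as.data.frame(sites)
  ds <- ensembleScore(ensembles$doench, df$context30)
  cs <- ensembleScore(ensembles$chari, df$context30)
  df$doench_score <- ds
  df$chari_score <- cs
  df$forest_score <- combinedForestScore(ds, cs)
  df$group <- assignGroup(df$forest_score, bands)
  df$cons_score <- vapply(seq_len(nrow(df)), function(i) {
    g <- df$gene[i]
    if (is.na(g) || is.null(profiles[[g]])) return(NA_real_)
    conservationScore(profiles[[g]], df$cds_aa_index[i], flankAa)
  }, numeric(1))
  df$cons_pass <- conservationPass(df$cons_score, consThreshold)
  ## within the 30-nt context the cut boundary sits at offset 21
  ## (4-nt flank + 17 protospacer bases 5' of the blunt cut); a wider
  ## microhomology context may be supplied via mh_context / mh_cut columns
  fsm <- if (!is.null(df$mh_context)) {
    mapply(function(ctx, cut) assessFsm(repairModel, ctx, cut,
                                        fsmThreshold = fsmThreshold),
           df$mh_context, df$mh_cut, SIMPLIFY = FALSE)
  } else {
    lapply(df$context30, function(ctx)
      assessFsm(repairModel, ctx, 21L, fsmThreshold = fsmThreshold))
  }
  df$fsm_likelihood <- vapply(fsm, `[[`, numeric(1), "fsm_likelihood")
  df$fsm_pass <- vapply(fsm, `[[`, logical(1), "passes_fsm_test")
  df$croatan_score <- NA_integer_
  ok <- df$group != "excluded"
  if (any(ok))
    df$croatan_score[ok] <- consolidateScore(df$group[ok], df$cons_pass[ok],
                                             df$fsm_pass[ok])
  df
}

#' Rank guides for a gene and return the top slate
#'
#' Sorted by consolidated score (desc), then combined forest score (desc),
#' then 5'-most cut in transcript orientation, then site id; excluded
#' guides are dropped. Shortfalls are reported in an attribute, never
#' padded.
#'
#' @param scored data.frame from [scoreGuides()] (one gene).
#' @param guidesPerGene slate size (default 10).
#' @param geneStrand "+" or "-"; orients the positional tie-break
#'   (default "+").
#' @return the top rows with a `rank` column; attribute `shortfall` gives
#'   the number of requested guides that could not be filled.
#' @export
designGeneSlate <- function(scored, guidesPerGene = 10L, geneStrand = "+") {
  stopifnot(nrow(scored) >= 1L)
  scored <- scored[!is.na(scored$croatan_score), , drop = FALSE]
  pos <- if (geneStrand == "+") scored$cut_coord else -scored$cut_coord
  ord <- order(-scored$croatan_score, -scored$forest_score, pos,
               scored$site_id)
  out <- scored[ord, , drop = FALSE]
  out <- head(out, guidesPerGene)
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  attr(out, "shortfall") <- max(0L, guidesPerGene - nrow(out))
  out
}

#' Design slates for every gene in a scored table
#'
#' @param scored data.frame from [scoreGuides()] covering several genes.
#' @param guidesPerGene slate size per gene.
#' @param geneStrands optional named character vector of gene strands.
#' @return data.frame of concatenated per-gene slates.
#' @export
designLibrarySlates <- function(scored, guidesPerGene = 10L,
                                geneStrands = NULL) {
  parts <- lapply(split(scored, scored$gene), function(d) {
    st <- geneStrands[[d$gene[1]]] %||% "+"
    designGeneSlate(d, guidesPerGene, st)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}
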