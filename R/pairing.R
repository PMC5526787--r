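## Dual-guide pairing: off-target reranking of the top-20 slate, heuristic
## pair scoring over the top 10, exact maximum weight matching, and
## construct assembly for the dual-promoter (hU6/cU6) cassette.
##
## Pair-scoring rules, applied in order: every pair starts at 0;
## overlapping pairs are assigned a final score of 0 (terminal); pairs
## less than 10 kb apart whose inter-DSB distance is not divisible by 3
## are assigned 2.5 if they target the same transcripts; scores are then
## incremented by 1 if the pair's guide scores are imbalanced (one below
## 7 and one above 7).

#' Count seed + PAM off-target occurrences
#'
#' Default off-target risk for a guide: the number of exact occurrences of
#' its 3'-proximal 12-nt seed followed by NGG elsewhere in the genome
#' (both strands; the site's own occurrence is not counted).
#'
#' @param protospacers character vector of 20-nt protospacers.
#' @param genomeSeqs named character vector of genome sequences.
#' @return integer vector of off-target match counts.
#' @export
seedOfftargetCounts <- function(protospacers, genomeSeqs) {
  if (methods::is(genomeSeqs, "XStringSet"))
    genomeSeqs <- as.character(genomeSeqs)
  vapply(protospacers, function(p) {
    seed <- substr(toupper(p), 9L, 20L)
    pat <- Biostrings::DNAString(paste0(seed, "NGG"))
    total <- 0L
    for (s in genomeSeqs) {
      subj <- Biostrings::DNAString(toupper(s))
      total <- total +
        length(Biostrings::matchPattern(pat, subj, fixed = FALSE)) +
        length(Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                        subj, fixed = FALSE))
    }
    max(0L, total - 1L)  # discount the on-target occurrence
  }, integer(1), USE.NAMES = FALSE)
}

#' Rerank a top-20 slate by off-target risk and keep 10
#'
#' Guides are re-sorted by ascending off-target risk, then descending
#' consolidated score, then site id, and the first `keep` are returned.
#'
#' @param slate data.frame with columns `site_id`, `protospacer`,
#'   `croatan_score` (at most 20 rows).
#' @param genomeSeqs genome sequences for the default seed + PAM counter,
#'   or NULL when `risk` is supplied.
#' @param risk optional precomputed risk vector (pluggable scorer).
#' @param keep slate size to retain (default 10).
#' @return the reranked slate with an `offtarget_risk` column.
#' @export
offtargetRerank <- function(slate, genomeSeqs = NULL, risk = NULL,
                            keep = 10L) {
  stopifnot(nrow(slate) <= 20L)
  if (is.null(risk)) {
    if (is.null(genomeSeqs))
      stop("supply either genomeSeqs or a precomputed risk vector")
    risk <- seedOfftargetCounts(slate$protospacer, genomeSeqs)
  }
  slate$offtarget_risk <- risk
  slate <- slate[order(risk, -slate$croatan_score, slate$site_id), ,
                 drop = FALSE]
  out <- head(slate, keep)
  if (nrow(out) < 2L)
    stop("fewer than 2 guides survive off-target reranking; pairing is ",
         "impossible")
  out
}

.protoInterval <- function(strand, cut) {
  ## protospacer occupies [cut-17, cut+3) on plus-strand guides and
  ## [cut-3, cut+17) on minus-strand guides (0-based half-open)
  if (strand == "+") c(cut - 17L, cut + 3L) else c(cut - 3L, cut + 17L)
}

#' Heuristic score for one guide pair
#'
#' @param a,b lists or one-row data.frames with `cut_coord`, `strand`,
#'   `croatan_score` and `transcripts` (character vector of transcript
#'   ids covering the cut).
#' @param maxDist distance bound in bp (default 10000).
#' @return numeric pair score.
#' @export
pairScore <- function(a, b, maxDist = 10000L) {
  ia <- .protoInterval(a$strand, a$cut_coord)
  ib <- .protoInterval(b$strand, b$cut_coord)
  if (max(ia[1], ib[1]) < min(ia[2], ib[2]))
    return(0)  # overlapping target intervals: terminal zero
  d <- abs(a$cut_coord - b$cut_coord)
  txA <- unlist(a$transcripts)
  txB <- unlist(b$transcripts)
  base <- if (d < maxDist && d %% 3L != 0L &&
              length(intersect(txA, txB)) > 0L) 2.5 else 0
  sa <- a$croatan_score
  sb <- b$croatan_score
  imbalanced <- (min(sa, sb) < 7) && (max(sa, sb) > 7)
  base + if (imbalanced) 1 else 0
}

#' Build the pairwise score matrix for a slate
#'
#' @param slate data.frame with columns `site_id`, `strand`, `cut_coord`,
#'   `croatan_score`, `transcripts` (list column or comma-joined string).
#' @param maxDist passed to [pairScore()].
#' @return symmetric numeric matrix with guide ids as dimnames; diagonal
#'   is NA (unused).
#' @export
buildPairMatrix <- function(slate, maxDist = 10000L) {
  ids <- slate$site_id
  if (anyDuplicated(ids)) stop("duplicate guide ids in slate")
  n <- nrow(slate)
  tx <- slate$transcripts
  if (is.character(tx)) tx <- strsplit(tx, ",")
  rows <- lapply(seq_len(n), function(i) list(
    strand = slate$strand[i], cut_coord = slate$cut_coord[i],
    croatan_score = slate$croatan_score[i], transcripts = tx[[i]]))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairScore(rows[[i]], rows[[j]], maxDist)
  }
  m
}

#' Exact maximum weight matching on a general graph
#'
#' Dynamic programming over vertex subsets: exact for the slate sizes used
#' here (up to ~20 vertices). Vertices may stay unmatched; ties are broken
#' toward the lexicographically earliest pairing by vertex order.
#'
#' @param weights symmetric numeric matrix (NA diagonal allowed).
#' @return list with `pairs` (two-column matrix of dimnames ids, rows
#'   ordered by first member) and `total` weight.
#' @export
maxWeightMatching <- function(weights) {
  n <- nrow(weights)
  stopifnot(n == ncol(weights), n >= 2L)
  if (n > 22L) stop("exact matching supported up to 22 vertices")
  w <- weights
  w[is.na(w)] <- 0
  if (max(abs(w - t(w))) > 1e-9) stop("weight matrix must be symmetric")
  nS <- bitwShiftL(1L, n)
  best <- rep(-Inf, nS)
  choice <- rep(-1L, nS)  # partner chosen for the lowest set bit; 0 = skip
  best[1L] <- 0
  for (S in seq_len(nS - 1L)) {
    i <- 0L
    while (!bitwAnd(S, bitwShiftL(1L, i))) i <- i + 1L
    rest <- bitwAnd(S, bitwNot(bitwShiftL(1L, i)))
    ## leave i unmatched, or pair i with j; on equal weight prefer
    ## pairing (weights are non-negative, and a slate should pair up
    ## fully even through zero-score edges), then the smallest j
    b <- best[rest + 1L]
    c_ <- 0L
    for (j in (i + 1L):(n - 1L)) {
      if (j > n - 1L) break
      if (!bitwAnd(rest, bitwShiftL(1L, j))) next
      cand <- w[i + 1L, j + 1L] +
        best[bitwAnd(rest, bitwNot(bitwShiftL(1L, j))) + 1L]
      if (cand > b + 1e-12 || (c_ == 0L && cand >= b - 1e-12)) {
        b <- cand
        c_ <- j + 1L
      }
    }
    best[S + 1L] <- b
    choice[S + 1L] <- c_
  }
  ## reconstruct
  S <- nS - 1L
  pairs <- NULL
  while (S > 0L) {
    i <- 0L
    while (!bitwAnd(S, bitwShiftL(1L, i))) i <- i + 1L
    j <- choice[S + 1L]
    if (j == 0L) {
      S <- bitwAnd(S, bitwNot(bitwShiftL(1L, i)))
    } else {
      pairs <- rbind(pairs, c(i + 1L, j))
      S <- bitwAnd(S, bitwNot(bitwShiftL(1L, i)))
      S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    }
  }
  ids <- rownames(weights) %||% as.character(seq_len(n))
  if (is.null(pairs)) {
    return(list(pairs = matrix(character(0), ncol = 2L), total = 0))
  }
  total <- sum(w[pairs])
  out <- cbind(ids[pairs[, 1L]], ids[pairs[, 2L]])
  out <- out[order(out[, 1L]), , drop = FALSE]
  list(pairs = out, total = total)
}

#' Generate a barcode pool with a minimum Hamming distance
#'
#' Deterministic greedy selection from seed-shuffled random DNA words.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt (default 8).
#' @param minDist minimum pairwise Hamming distance (default 3).
#' @param seed RNG seed.
#' @return character vector of `n` barcodes.
#' @export
makeBarcodes <- function(n, length = 8L, minDist = 3L, seed = 100L) {
  set.seed(seed)
  pool <- character(0)
  tries <- 0L
  while (length(pool) < n) {
    tries <- tries + 1L
    if (tries > 200000L)
      stop("barcode pool exhausted: cannot satisfy the distance constraint")
    cand <- paste(sample(DNA_BASES4, length, replace = TRUE), collapse = "")
    if (all(vapply(pool, function(b) {
      sum(strsplit(b, "")[[1]] != strsplit(cand, "")[[1]]) >= minDist
    }, logical(1))))
      pool <- c(pool, cand)
  }
  pool
}

#' Assemble dual-guide constructs from a matching
#'
#' The higher-scoring guide of each pair takes the hU6 position (ties by
#' lexicographic site id); each construct receives a unique barcode.
#'
#' @param matching result of [maxWeightMatching()].
#' @param slate the slate data.frame the matrix was built from.
#' @param barcodes character vector, at least one per construct.
#' @param gene gene id recorded on each construct.
#' @param pairMatrix optional matrix to record each pair's score.
#' @return data.frame: gene, h_guide, c_guide, barcode, pair_score.
#' @export
assembleConstructs <- function(matching, slate, barcodes, gene = NA,
                               pairMatrix = NULL) {
  np <- nrow(matching$pairs)
  if (np == 0L)
    return(data.frame(gene = character(0), h_guide = character(0),
                      c_guide = character(0), barcode = character(0),
                      pair_score = numeric(0)))
  if (length(barcodes) < np) stop("barcode pool exhausted")
  if (anyDuplicated(barcodes[seq_len(np)]))
    stop("barcodes must be unique within a library")
  sc <- setNames(slate$croatan_score, slate$site_id)
  rows <- lapply(seq_len(np), function(k) {
    a <- matching$pairs[k, 1L]
    b <- matching$pairs[k, 2L]
    ## hU6 gets the stronger guide
    if (sc[[b]] > sc[[a]] || (sc[[b]] == sc[[a]] && b < a)) {
      tmp <- a; a <- b; b <- tmp
    }
    data.frame(gene = gene, h_guide = a, c_guide = b,
               barcode = barcodes[k],
               pair_score = if (!is.null(pairMatrix)) pairMatrix[a, b]
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Enumerate all ordered cross-combinations of a guide set
#'
#' Combinatorial library mode: every guide is placed in both promoter
#' positions against every guide (including itself), yielding n^2 ordered
#' pairs.
#'
#' @param guideIds character vector of guide ids.
#' @return data.frame with columns `h_guide`, `c_guide`.
#' @export
combinatorialPairs <- function(guideIds) {
  g <- expand.grid(c_guide = guideIds, h_guide = guideIds,
                   stringsAsFactors = FALSE)
  g[, c("h_guide", "c_guide")]
}
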