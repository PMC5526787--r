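# Shared fixtures, built in code and cached per test run. Forest training
# is the expensive step, so the suite trains one small ladder pair and
# reuses it wherever a trained ensemble is needed.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# efficacy fixture with a train / held-out split (every 5th guide held out)
efficacyFixture <- function() {
  cached("efficacy", {
    eff <- simulateEfficacyData(nGenes = 40L, guidesPerGene = 10L, seed = 3L)
    lab <- labelRecords(eff)
    lab$heldout <- seq_len(nrow(lab)) %% 5L == 0L
    lab
  })
}

smallEnsemble <- function() {
  cached("ensemble", {
    lab <- efficacyFixture()
    trainEnsemble(lab[!lab$heldout, ], datasetTag = "doench-like",
                  treesPerForest = 150L, rngSeed = 17L)
  })
}

# intercept-only repair model: every microhomology pair scores `value`
flatRepairModel <- function(value = 0.2) {
  methods::new("RepairModel",
               coefficients = c(intercept = value, length = 0,
                                gc_fraction = 0, distance = 0),
               fitDiagnostics = list(), hejCutoff = NA_real_,
               distanceMode = "sum")
}

fittedRepairModel <- function() {
  cached("repair", fitRepairModel(simulateResolutionTable(seed = 5L)))
}

# brute-force microhomology oracle: enumerate every matching (u, d, len)
# triple under the constraints, then drop triples contained in a longer
# triple with the same copy alignment
oracleMicrohomologies <- function(s, cut, minLen, window) {
  s <- toupper(s)
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  loU <- max(0L, cut - window)
  hiD <- min(L, cut + window)
  triples <- list()
  for (u in seq(loU, cut - 1L)) for (d in seq(cut, hiD - 1L)) {
    maxlen <- 0L
    while (u + maxlen < cut && d + maxlen < hiD &&
           ch[u + maxlen + 1L] == ch[d + maxlen + 1L])
      maxlen <- maxlen + 1L
    for (len in seq_len(maxlen))
      triples[[length(triples) + 1L]] <- c(u = u, d = d, len = len)
  }
  if (!length(triples)) return(NULL)
  tm <- do.call(rbind, triples)
  keep <- vapply(seq_len(nrow(tm)), function(i) {
    u <- tm[i, "u"]; d <- tm[i, "d"]; len <- tm[i, "len"]
    !any(tm[, "d"] - tm[, "u"] == d - u &
           tm[, "u"] <= u & tm[, "u"] + tm[, "len"] >= u + len &
           tm[, "len"] > len)
  }, logical(1))
  out <- tm[keep, , drop = FALSE]
  out[order(out[, "d"] - out[, "u"], cut - (out[, "u"] + out[, "len"])), ,
      drop = FALSE]
}

# brute-force maximum over all perfect matchings (and near-perfect for odd
# n): recursive enumeration
oracleMatching <- function(w) {
  w[is.na(w)] <- 0
  n <- nrow(w)
  rec <- function(avail) {
    if (length(avail) < 2L) return(0)
    i <- avail[1]
    rest <- avail[-1]
    best <- rec(rest)  # i unmatched
    for (j in rest)
      best <- max(best, w[i, j] + rec(setdiff(rest, j)))
    best
  }
  rec(seq_len(n))
}

# greedy matching: repeatedly take the heaviest remaining edge
greedyMatchingWeight <- function(w) {
  w[is.na(w)] <- 0
  total <- 0
  repeat {
    if (all(w <= 0)) break
    idx <- which(w == max(w), arr.ind = TRUE)[1, ]
    total <- total + w[idx[1], idx[2]]
    w[c(idx[1], idx[2]), ] <- -Inf
    w[, c(idx[1], idx[2])] <- -Inf
  }
  total
}

# minimal synthetic guide row for pair scoring
guideRow <- function(id, cut, score, transcripts = "tx1", strand = "+") {
  list(site_id = id, strand = strand, cut_coord = cut,
       croatan_score = score, transcripts = transcripts)
}

writeSamFile <- function(lines, refName, refLen, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen),
               lines), path)
  path
}

scarAmplicon <- function(seed = 1L) {
  cached(paste0("amplicon", seed), {
    AmpliconSpec("ampA", randomDna(300L, seed = 900L + seed), 100L, 200L)
  })
}
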