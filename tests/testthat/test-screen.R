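screenFixture <- function(seed = 10L, delta = -2, depth = 1000) {
  sim <- simulateScreen(seed = seed, delta = delta, depth = depth)
  se <- ScreenExperiment(sim$counts, sim$samples, sim$library)
  list(sim = sim, se = se)
}

test_that("the minimum-reference filter drops per replicate", {
  counts <- data.frame(
    construct = rep(c("c1", "c2", "c3"), times = 4L),
    sample = rep(c("r1_ref", "r1_fin", "r2_ref", "r2_fin"), each = 3L),
    count = c(49L, 200L, 300L,   90L, 80L, 70L,
              60L, 201L, 301L,   91L, 81L, 71L))
  samples <- data.frame(
    sample = c("r1_ref", "r1_fin", "r2_ref", "r2_fin"),
    replicate = c("r1", "r1", "r2", "r2"),
    timepoint = c("reference", "final", "reference", "final"))
  se <- ScreenExperiment(counts, samples)
  filt <- filterMinReference(se, 50L)
  cnt <- SummarizedExperiment::assay(filt, "counts")
  expect_true(is.na(cnt["c1", "r1_ref"]))  # 49 in reference: dropped
  expect_true(is.na(cnt["c1", "r1_fin"]))  # from that whole replicate
  expect_false(is.na(cnt["c1", "r2_ref"]))  # 60 passes in replicate 2
  expect_false(any(is.na(cnt[c("c2", "c3"), ])))

  ident <- filterMinReference(se, 0L)
  expect_equal(SummarizedExperiment::assay(ident, "counts")["c1", "r1_ref"],
               49)
})

test_that("filter survivors match a per-replicate comprehension oracle", {
  fx <- screenFixture(seed = 10L, depth = 80)  # low depth: some below 50
  filt <- filterMinReference(fx$se, 50L)
  cnt0 <- SummarizedExperiment::assay(fx$se, "counts")
  cnt <- SummarizedExperiment::assay(filt, "counts")
  for (r in c("rep1", "rep2", "rep3")) {
    ref <- paste0(r, "_reference")
    fin <- paste0(r, "_final")
    dropped <- rownames(cnt0)[cnt0[, ref] < 50L]
    expect_true(length(dropped) > 0L)
    expect_true(all(is.na(cnt[dropped, c(ref, fin)])))
    kept <- setdiff(rownames(cnt0), dropped)
    expect_false(any(is.na(cnt[kept, c(ref, fin)])))
  }
  expect_error(filterMinReference(fx$se, 1e9), "all constructs removed")
})

test_that("log fold changes have the stated closed forms", {
  counts <- data.frame(
    construct = rep(c("a", "b"), 2L),
    sample = rep(c("r1_ref", "r1_fin"), each = 2L),
    count = c(100L, 100L, 50L, 150L))
  samples <- data.frame(sample = c("r1_ref", "r1_fin"), replicate = "r1",
                        timepoint = c("reference", "final"))
  se <- ScreenExperiment(counts, samples)
  res <- logFoldChange(se, pseudocount = 0)
  # library sizes equal: construct a halves -> LFC -1
  expect_equal(unname(res$lfc["a", "r1"]), -1)
  expect_equal(unname(res$lfc["b", "r1"]), log2(1.5))

  # identical reference and final counts give LFC 0 everywhere
  counts0 <- transform(counts, count = c(100L, 60L, 100L, 60L))
  res0 <- logFoldChange(ScreenExperiment(counts0, samples))
  expect_true(all(res0$lfc == 0))

  # antisymmetry under swapping timepoints
  samplesSw <- transform(samples, timepoint = rev(timepoint))
  resSw <- logFoldChange(ScreenExperiment(counts, samplesSw),
                         pseudocount = 0)
  expect_equal(unname(resSw$lfc[, "r1"]), unname(-res$lfc[, "r1"]))
})

test_that("a missing matched reference errors", {
  counts <- data.frame(construct = "a", sample = "r1_fin", count = 10L)
  samples <- data.frame(sample = "r1_fin", replicate = "r1",
                        timepoint = "final")
  expect_error(ScreenExperiment(counts, samples), "reference")
})

test_that("planted depletion is recovered after control centering", {
  fx <- screenFixture(seed = 11L, delta = -2)
  se <- filterMinReference(fx$se, 50L)
  neg <- fx$sim$library$construct[fx$sim$library$class == "NEG"]
  res <- logFoldChange(se, centerOn = neg)
  eg <- fx$sim$library$construct[fx$sim$library$class == "EG"]
  expect_lt(abs(mean(res$mean_lfc[eg], na.rm = TRUE) - (-2)), 0.2)
  expect_lt(abs(mean(res$mean_lfc[neg], na.rm = TRUE)), 0.1)
  # z-scores standardize within replicate
  expect_lt(abs(mean(res$z[, 1], na.rm = TRUE)), 1e-8)
  expect_equal(stats::sd(res$z[, 1], na.rm = TRUE), 1)
})

test_that("gene percentiles use the midpoint convention", {
  res <- list(mean_lfc = setNames(c(-3, -2, -1, 0, 1), paste0("c", 1:5)),
              rowData = data.frame(construct = paste0("c", 1:5),
                                   gene = "g1"))
  out <- genePercentile(res)
  expect_equal(out$depletion_percentile, c(90, 70, 50, 30, 10))

  tied <- list(mean_lfc = setNames(rep(-1, 4), paste0("c", 1:4)),
               rowData = data.frame(construct = paste0("c", 1:4),
                                    gene = "g1"))
  expect_equal(genePercentile(tied)$depletion_percentile, rep(50, 4))

  # permutation invariance
  perm <- list(mean_lfc = res$mean_lfc[c(3, 1, 5, 2, 4)],
               rowData = res$rowData[c(3, 1, 5, 2, 4), ])
  outp <- genePercentile(perm)
  expect_equal(setNames(outp$depletion_percentile, outp$construct)[
    out$construct], setNames(out$depletion_percentile, out$construct))

  single <- list(mean_lfc = setNames(-1, "c1"),
                 rowData = data.frame(construct = "c1", gene = "g1"))
  outs <- genePercentile(single)
  expect_true(outs$flagged)
  expect_true(is.na(outs$depletion_percentile))
})

test_that("group tests behave at the null and at perfect association", {
  x <- rnorm(40)
  p <- groupTests(c(x, x), rep(c("a", "b"), each = 40L))$p_value
  expect_gt(p, 0.9)  # identical groups

  sp <- groupTests(1:20, 1:20, test = "spearman")
  expect_equal(sp$rho, 1)

  fr <- groupTests(c(1, 2, 3, 1.1, 2.1, 3.1),
                   grouping = rep(c("g1", "g2", "g3"), 2L),
                   test = "friedman", blocks = rep(c("b1", "b2"), each = 3L))
  expect_lt(fr$p_value, 0.5)
  expect_true(!is.null(fr$n))

  expect_warning(
    groupTests(rnorm(42), c(rep("a", 20), rep("b", 21), "c")),
    "n < 2")
})

test_that("a one-sigma shift is detected in at least 95 of 100 seeds", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1200L + s)
    a <- rnorm(50)
    b <- rnorm(50) + 1
    p <- groupTests(c(a, b), rep(c("a", "b"), each = 50L))$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("dual-construct decomposition summarizes partner classes", {
  rowData <- data.frame(
    construct = c("k1", "k2", "k3", "k4"),
    gene = c("E1", "E1", "E1", "E1"),
    class = "EG",
    h_guide = c("e1a", "e1a", "e1a", "e1b"),
    c_guide = c("n1", "n2", "e1b", "n1"),
    stringsAsFactors = FALSE)
  res <- list(mean_lfc = setNames(c(-1, -1, -2, -1.5), rowData$construct),
              rowData = rowData)
  guideGenes <- c(e1a = "E1", e1b = "E1", n1 = "N1", n2 = "N2")
  guideClasses <- c(e1a = "EG", e1b = "EG", n1 = "NEG", n2 = "NEG")
  out <- dualConstructDecomposition(res, guideGenes, guideClasses)
  e1a <- out[out$guide == "e1a", ]
  expect_equal(e1a$mean_lfc_neg_partner, -1)
  expect_equal(e1a$mean_lfc_same_gene_partner, -2)

  # planted synergy: same-gene partners deplete more for most guides
  set.seed(13)
  guides <- c(sprintf("e%02d", 1:10), sprintf("n%02d", 1:10))
  gg <- setNames(c(rep(sprintf("EG%02d", 1:5), each = 2L),
                   rep("NEGX", 10L)), guides)
  gc <- setNames(rep(c("EG", "NEG"), each = 10L), guides)
  combos <- expand.grid(h = guides[1:10], c = guides, stringsAsFactors = FALSE)
  combos <- combos[combos$h != combos$c, ]
  lfcv <- ifelse(gg[combos$c] == gg[combos$h] & gc[combos$c] == "EG",
                 -3, -2) + rnorm(nrow(combos), 0, 0.1)
  rowDataS <- data.frame(construct = sprintf("cc%03d", seq_len(nrow(combos))),
                         gene = gg[combos$h], class = "EG",
                         h_guide = combos$h, c_guide = combos$c,
                         stringsAsFactors = FALSE)
  resS <- list(mean_lfc = setNames(lfcv, rowDataS$construct),
               rowData = rowDataS)
  outS <- dualConstructDecomposition(resS, gg, gc)
  frac <- mean(outS$mean_lfc_same_gene_partner < outS$mean_lfc_neg_partner)
  expect_gte(frac, 0.9)

  # no dual metadata: empty report, no error
  res2 <- list(mean_lfc = setNames(-1, "x"),
               rowData = data.frame(construct = "x", gene = "g",
                                    class = "EG", h_guide = NA,
                                    c_guide = NA))
  expect_equal(nrow(dualConstructDecomposition(res2, gg, gc)), 0L)
})

test_that("gene hits require the two-construct minimum", {
  # one gene with a single extreme construct must not be called
  lfc <- c(g1_a = -10, g1_b = 0, g1_c = 0,
           g2_a = -9, g2_b = -8, g2_c = 0,
           g3_a = 0.5, g3_b = 0.6, g3_c = 0.4, g3_d = 0.2)
  rowData <- data.frame(construct = names(lfc),
                        gene = sub("_.*", "", names(lfc)),
                        class = c(rep("EG", 6L), rep("NEG", 4L)),
                        stringsAsFactors = FALSE)
  res <- list(mean_lfc = lfc, rowData = rowData)
  out <- geneHits(res, stringencies = c(10, 20, 30), minConstructs = 2L)
  expect_false(out$hits[out$hits$gene == "g1", "q20"])  # single construct
  expect_false(out$hits[out$hits$gene == "g2", "q20"])  # ranks 2-3 of 10
  expect_true(out$hits[out$hits$gene == "g2", "q30"])   # both now inside
  expect_false(out$hits[out$hits$gene == "g1", "q30"])

  # q = 100% saturates: every gene with >= 2 constructs becomes a hit
  sat <- geneHits(res, stringencies = 100, minConstructs = 2L)
  expect_true(all(sat$hits$q100))

  # hit sets grow monotonically with stringency
  mono <- geneHits(res, stringencies = c(10, 20, 30, 40, 50))
  hm <- as.matrix(mono$hits[, -1])
  expect_true(all(hm[, -1] >= hm[, -ncol(hm)]))
})

test_that("the planted screen separates EG and NEG hit rates", {
  fx <- screenFixture(seed = 14L, delta = -2)
  se <- filterMinReference(fx$se, 50L)
  neg <- fx$sim$library$construct[fx$sim$library$class == "NEG"]
  res <- logFoldChange(se, centerOn = neg)
  out <- geneHits(res)
  expect_true(all(out$rates$tpr > out$rates$fpr))
})

test_that("the prefix counter matches exact 20-nt guides", {
  lib <- c(c1 = "ACGTACGTACGTACGTACGT", c2 = "TTTTAAAACCCCGGGGTTTT")
  reads <- c(paste0(lib[1], "AAA"), paste0(lib[1], "CCC"),
             paste0(lib[2], "G"), "ACGTACGTACGTACGTACGA")
  expect_equal(countGuideReads(reads, lib), c(c1 = 2L, c2 = 1L))
})
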