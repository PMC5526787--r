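test_that("FASTA reading handles multi-record, empty and wrapped files", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">seq1 description here", "ACGTACGT",
               ">seq2", "ggggcccc"), fa)
  seqs <- readFastaSeqs(fa)
  expect_length(seqs, 2L)
  expect_named(seqs, c("seq1", "seq2"))
  expect_equal(unname(seqs["seq2"]), "GGGGCCCC")  # uppercased

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(readFastaSeqs(empty), 0L)

  # a record wrapped at 60 characters equals its one-line rewrite
  long <- randomDna(150L, seed = 41L)
  wrapped <- tempfile(fileext = ".fa")
  writeLines(c(">w", substring(long, seq(1, 150, 60),
                               pmin(seq(60, 210, 60), 150))), wrapped)
  oneline <- tempfile(fileext = ".fa")
  writeLines(c(">w", long), oneline)
  expect_identical(readFastaSeqs(wrapped), readFastaSeqs(oneline))
})

test_that("FASTA reader rejects non-IUPAC residues, naming the line", {
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">bad", "ACQT"), bad)
  expect_error(readFastaSeqs(bad), "line 4")
})

test_that("GFF3 coordinates convert to 0-based half-open", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t11\t40\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tsrc\texon\t11\t40\t.\t+\t.\tID=e1;Parent=g1.t1",
               "chr1\tsrc\tCDS\t11\t40\t.\t+\t.\tID=c1;Parent=g1.t1"),
             gff)
  models <- readGeneModels(gff, "gff3")
  tx <- models$g1@transcripts[["g1.t1"]]
  expect_equal(unname(tx$exons[1, ]), c(10L, 40L))
  expect_equal(unname(tx$cds[1, ]), c(10L, 40L))
})

test_that("BED12 blocks become exon intervals and match the GFF3 encoding", {
  # two-exon gene: exons [10,40) and [60,90), CDS [15,40)+[60,80)
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 10, 90, "g2|g2.t1", 0, "+", 15, 80,
                     "0", 2, "30,30", "0,50"), collapse = "\t"), bed)
  mb <- readGeneModels(bed, "bed12")
  txb <- mb$g2@transcripts[["g2.t1"]]
  expect_equal(nrow(txb$exons), 2L)
  expect_equal(unname(txb$exons), matrix(c(10L, 60L, 40L, 90L), ncol = 2))
  expect_equal(unname(txb$cds), matrix(c(15L, 60L, 40L, 80L), ncol = 2))

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t11\t90\t.\t+\t.\tID=g2",
               "chr1\tsrc\tmRNA\t11\t90\t.\t+\t.\tID=g2.t1;Parent=g2",
               "chr1\tsrc\texon\t11\t40\t.\t+\t.\tID=e1;Parent=g2.t1",
               "chr1\tsrc\texon\t61\t90\t.\t+\t.\tID=e2;Parent=g2.t1",
               "chr1\tsrc\tCDS\t16\t40\t.\t+\t.\tID=c1;Parent=g2.t1",
               "chr1\tsrc\tCDS\t61\t80\t.\t+\t.\tID=c2;Parent=g2.t1"),
             gff)
  mg <- readGeneModels(gff, "gff3")
  txg <- mg$g2@transcripts[["g2.t1"]]
  expect_equal(txg$exons, txb$exons)
  expect_equal(txg$cds, txb$cds)
  expect_equal(txg$strand, txb$strand)
})

test_that("CDS outside exons fails gene-model validation", {
  expect_error(
    GeneModel("gX", "chr1", list(list(
      transcriptId = "tX", strand = "+",
      exons = matrix(c(0L, 50L), ncol = 2),
      cds = matrix(c(40L, 70L), ncol = 2)))),
    "CDS outside exons")
})

test_that("a forced PAM yields one site with canonical cut geometry", {
  s <- c(chr1 = paste0(strrep("A", 24L), "AGG", strrep("A", 3L)))
  gr <- enumerateTargets(s)
  expect_length(gr, 1L)
  md <- S4Vectors::mcols(gr)
  expect_equal(md$cut_coord, 21L)  # cut between positions 20 and 21
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  expect_equal(md$pam, "AGG")
  expect_equal(nchar(md$context30), 30L)
  # context contains the protospacer at offset 4 (0-based)
  expect_equal(substr(md$context30, 5L, 24L), md$protospacer)
})

test_that("sequences without any GG/CC dinucleotide yield no sites", {
  s <- c(chr1 = paste(rep(c("A", "G", "T", "C"), 20L), collapse = ""))
  expect_false(grepl("GG|CC", s))
  expect_length(enumerateTargets(s), 0L)
})

test_that("enumeration matches a regex-scan oracle on random sequence", {
  s <- randomDna(200L, seed = 1L)
  gr <- enumerateTargets(c(chrA = s))
  md <- S4Vectors::mcols(gr)

  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  oracle <- list()
  plus <- gregexpr("(?=[ACGT]GG)", s, perl = TRUE)[[1]]
  for (p in as.integer(plus) - 1L) {
    if (p < 24L || p + 6L > nchar(s)) next
    oracle[[length(oracle) + 1L]] <-
      list(id = sprintf("chrA:+:%d", p - 3L),
           ctx = substr(s, p - 23L, p + 6L))
  }
  minus <- gregexpr("(?=CC[ACGT])", s, perl = TRUE)[[1]]
  for (q in as.integer(minus) - 1L) {
    if (q < 3L || q + 27L > nchar(s)) next
    oracle[[length(oracle) + 1L]] <-
      list(id = sprintf("chrA:-:%d", q + 6L),
           ctx = rc(substr(s, q - 2L, q + 27L)))
  }
  oids <- sort(vapply(oracle, `[[`, character(1), "id"))
  expect_equal(sort(md$site_id), oids)
  octx <- vapply(oracle, `[[`, character(1), "ctx")
  names(octx) <- vapply(oracle, `[[`, character(1), "id")
  expect_equal(md$context30, unname(octx[md$site_id]))
})

test_that("reverse-complementing the input mirrors the site set", {
  s <- randomDna(180L, seed = 77L)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g1 <- enumerateTargets(c(x = s))
  g2 <- enumerateTargets(c(x = rc))
  m1 <- S4Vectors::mcols(g1)
  m2 <- S4Vectors::mcols(g2)
  expect_equal(length(g1), length(g2))
  expect_setequal(m1$context30, m2$context30)
  # strands flip and cut coordinates mirror: cut' = L - cut
  key1 <- sort(paste(m1$strand0 <- as.character(GenomicRanges::strand(g1)),
                     m1$cut_coord))
  key2 <- sort(paste(chartr("+-", "-+",
                            as.character(GenomicRanges::strand(g2))),
                     L - m2$cut_coord))
  expect_equal(key1, key2)
})

test_that("every emitted context30 relocates to its coordinates", {
  s <- randomDna(250L, seed = 5L)
  gr <- enumerateTargets(c(x = s))
  md <- S4Vectors::mcols(gr)
  for (i in seq_along(gr)) {
    cut <- md$cut_coord[i]
    if (as.character(GenomicRanges::strand(gr))[i] == "+") {
      win <- substr(s, cut - 21L + 1L, cut + 9L)
      expect_equal(md$context30[i], win)
    } else {
      win <- substr(s, cut - 9L + 1L, cut + 21L)
      expect_equal(md$context30[i], as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(win))))
    }
  }
})

test_that("sites are annotated with transcripts and amino-acid index", {
  # plus-strand single-exon CDS starting at 0; cut at boundary c maps to
  # codon c %/% 3
  sim <- simulateGenome(nGenes = 4L, cdsCodons = 80L, seed = 9L)
  gr <- enumerateTargets(sim$seqs, sim$models)
  md <- S4Vectors::mcols(gr)
  coding <- !is.na(md$cds_aa_index)
  expect_gt(sum(coding), 0L)
  expect_true(all(lengths(md$transcripts[coding]) > 0L))
  # verify one plus-strand site by hand against its gene model
  gm <- sim$models[[1]]
  tx <- gm@transcripts[[1]]
  idx <- which(coding & md$gene == gm@geneId &
                 as.character(GenomicRanges::strand(gr)) == "+")[1]
  expect_false(is.na(idx))
  cut <- md$cut_coord[idx]
  cds <- tx$cds
  hit <- which(cds[, 1] <= cut & cut < cds[, 2])
  before <- if (hit > 1L) sum(cds[1:(hit - 1L), 2] - cds[1:(hit - 1L), 1])
            else 0L
  expect_equal(md$cds_aa_index[idx],
               unname((before + cut - cds[hit, 1]) %/% 3L))
})

test_that("target TSV round-trips through write and read", {
  sim <- simulateGenome(nGenes = 3L, seed = 4L)
  gr <- enumerateTargets(sim$seqs, sim$models)
  path <- tempfile(fileext = ".tsv")
  writeTargetsTsv(gr, path)
  back <- readTargetsTsv(path)
  expect_equal(S4Vectors::mcols(back)$site_id,
               S4Vectors::mcols(gr)$site_id)
  expect_equal(S4Vectors::mcols(back)$context30,
               S4Vectors::mcols(gr)$context30)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
})

test_that("non-N ambiguity codes in the PAM pattern are rejected", {
  expect_error(enumerateTargets(c(x = randomDna(60L, seed = 2L)),
                                pam = "NRG"),
               "only A, C, G, T and N")
})
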