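test_that("a planted repeat is found with the right deletion geometry", {
  # AAGTC at [2,7) and [12,17); cut at 9
  s <- "GGAAGTCTTACCAAGTCGGG"
  mh <- enumerateMicrohomologies(s, 9L, minLen = 5L)
  expect_equal(nrow(mh), 1L)
  expect_equal(mh$homology_seq, "AAGTC")
  expect_equal(mh$dist_upstream, 2L)
  expect_equal(mh$dist_downstream, 3L)
  expect_equal(mh$deletion_length,
               mh$dist_upstream + mh$dist_downstream + mh$length)
})

test_that("minLen above the longest repeat yields an empty list", {
  s <- "ACGTGCATCGATGCCGTAAC"
  mh <- enumerateMicrohomologies(s, 10L, minLen = 12L)
  expect_equal(nrow(mh), 0L)
})

test_that("enumeration matches the brute-force substring oracle", {
  for (seed in c(4L, 40L, 41L)) {
    s <- randomDna(60L, seed = seed)
    cut <- 30L
    mh <- enumerateMicrohomologies(s, cut, minLen = 2L, window = 30L)
    orc <- oracleMicrohomologies(s, cut, minLen = 2L, window = 30L)
    orc <- orc[orc[, "len"] >= 2L, , drop = FALSE]
    expect_equal(nrow(mh), nrow(orc))
    got <- mh[order(mh$deletion_length, mh$dist_upstream), ]
    exp_del <- orc[, "d"] - orc[, "u"]
    ord <- order(exp_del, cut - (orc[, "u"] + orc[, "len"]))
    expect_equal(got$deletion_length, unname(exp_del[ord]))
    expect_equal(got$length, unname(orc[ord, "len"]))
    expect_equal(got$dist_upstream,
                 unname(cut - (orc[ord, "u"] + orc[ord, "len"])))
  }
})

test_that("deletion length depends only on copy positions", {
  # the same two copies seen from any cut between them give the same
  # deletion length
  s <- paste0(randomDna(10L, seed = 6L), "CAGT", "AATT", "CAGT",
              randomDna(10L))
  hits <- lapply(14L:18L, function(cut)
    enumerateMicrohomologies(s, cut, minLen = 4L))
  dels <- lapply(hits, function(h)
    h$deletion_length[h$homology_seq == "CAGT"])
  expect_true(all(vapply(dels, function(d) 8L %in% d, logical(1))))
})

test_that("OLS fit recovers planted coefficients", {
  tab <- simulateResolutionTable(n = 500L, noiseSd = 0.01, seed = 5L)
  truth <- attr(tab, "truth")
  m <- fitRepairModel(tab)
  expect_true(all(abs(m@coefficients - truth) <= 0.1 * abs(truth)))

  tab0 <- simulateResolutionTable(n = 120L, noiseSd = 0, seed = 5L)
  m0 <- suppressWarnings(fitRepairModel(tab0))
  expect_true(all(abs(m0@coefficients - attr(tab0, "truth")) < 1e-8))
})

test_that("degenerate designs are rejected with named predictors", {
  tab <- simulateResolutionTable(n = 50L, seed = 5L)
  tab$length <- 5L
  expect_error(fitRepairModel(tab), "length")
  expect_error(fitRepairModel(tab[1:5, ]), "at least 10")
})

test_that("prediction is the clamped linear combination", {
  m <- flatRepairModel(0.2)
  pairs <- data.frame(homology_seq = "AA", length = 0L, gc_fraction = 0,
                      dist_upstream = 0L, dist_downstream = 0L,
                      deletion_length = 2L)
  expect_equal(predictResolution(m, pairs), 0.2)  # intercept only

  m2 <- flatRepairModel(-0.5)  # negative intercept clamps to zero
  expect_equal(predictResolution(m2, pairs), 0)

  # 30 pairs against hand-computed dot products
  fit <- fittedRepairModel()
  set.seed(30)
  pp <- data.frame(homology_seq = "NN",
                   length = sample(2:8, 30L, replace = TRUE),
                   gc_fraction = runif(30),
                   dist_upstream = sample(0:10, 30L, replace = TRUE),
                   dist_downstream = sample(0:10, 30L, replace = TRUE))
  pp$deletion_length <- pp$dist_upstream + pp$dist_downstream + pp$length
  co <- fit@coefficients
  byhand <- pmax(0, co[["intercept"]] + co[["length"]] * pp$length +
                   co[["gc_fraction"]] * pp$gc_fraction +
                   co[["distance"]] * (pp$dist_upstream +
                                         pp$dist_downstream))
  expect_equal(predictResolution(fit, pp), byhand)
  expect_true(all(predictResolution(fit, pp) >= 0))
})

test_that("min-distance mode changes only the distance covariate", {
  tab <- simulateResolutionTable(seed = 5L)
  m <- fitRepairModel(tab, distanceMode = "min")
  pairs <- data.frame(homology_seq = "AC", length = 2L, gc_fraction = 0.5,
                      dist_upstream = 3L, dist_downstream = 9L,
                      deletion_length = 14L)
  co <- m@coefficients
  expect_equal(predictResolution(m, pairs),
               pmax(0, co[["intercept"]] + 2 * co[["length"]] +
                      0.5 * co[["gc_fraction"]] + 3 * co[["distance"]]))
})

test_that("FSM likelihood follows the frame of the deletion lengths", {
  m <- flatRepairModel(0.2)
  # single repeat, deletion length 6 (divisible by 3): AGT at [2,5), [5,8)
  s1 <- paste0("CG", "AGT", "AGT", "CCTTAGC")
  a1 <- assessFsm(m, s1, 5L, minLen = 3L, window = 4L)
  expect_equal(a1$fsm_likelihood, 0)
  expect_false(a1$passes_fsm_test)

  # single repeat, deletion length 7: AGTC at [1,5) ... [8,12)
  s2 <- paste0("G", "AGTC", "TTA", "AGTC", "GGAAC")
  a2 <- assessFsm(m, s2, 6L, minLen = 4L, window = 6L)
  expect_equal(a2$fsm_likelihood, 1)
  expect_true(a2$passes_fsm_test)

  # no pairs above minLen: likelihood undefined, test fails
  a3 <- assessFsm(m, "ACGTGCATTGCA", 6L, minLen = 6L)
  expect_true(is.na(a3$fsm_likelihood))
  expect_false(a3$passes_fsm_test)
})

test_that("the FSM threshold is a strict inequality", {
  m <- flatRepairModel(0.1)
  ctx <- randomDna(80L, seed = 44L)
  a <- assessFsm(m, ctx, 40L)
  expect_true(a$fsm_likelihood > 0 && a$fsm_likelihood < 1)
  atThreshold <- assessFsm(m, ctx, 40L, fsmThreshold = a$fsm_likelihood)
  expect_false(atThreshold$passes_fsm_test)  # equality must fail
  below <- assessFsm(m, ctx, 40L,
                     fsmThreshold = a$fsm_likelihood - 1e-9)
  expect_true(below$passes_fsm_test)
})

test_that("FSM and in-frame fractions partition the likelihood mass", {
  m <- fittedRepairModel()
  for (seed in c(8L, 9L)) {
    ctx <- randomDna(70L, seed = seed)
    pairs <- enumerateMicrohomologies(ctx, 35L)
    sc <- predictResolution(m, pairs)
    if (sum(sc) == 0) next
    fsm <- sum(sc[pairs$deletion_length %% 3L != 0L]) / sum(sc)
    inframe <- sum(sc[pairs$deletion_length %% 3L == 0L]) / sum(sc)
    a <- assessFsm(m, ctx, 35L)
    expect_equal(a$fsm_likelihood, fsm)
    expect_equal(fsm + inframe, 1)
    expect_true(a$fsm_likelihood >= 0 && a$fsm_likelihood <= 1)
  }
})

test_that("the HEJ cutoff is the median background likelihood sum", {
  m <- flatRepairModel(0.1)
  bg <- vapply(1:3, function(i) randomDna(60L, seed = 50L + i),
               character(1))
  sums <- vapply(bg, function(ctx)
    sum(predictResolution(m, enumerateMicrohomologies(ctx, 30L))),
    numeric(1))
  m2 <- computeHejCutoff(m, bg, rep(30L, 3L))
  expect_equal(m2@hejCutoff, median(unname(sums)))

  # all-identical backgrounds give that value
  m3 <- computeHejCutoff(m, rep(bg[1], 5L), rep(30L, 5L))
  expect_equal(m3@hejCutoff, unname(sums[1]))
  expect_error(computeHejCutoff(m, character(0)), "empty")
})

test_that("cutoff over a large background matches a sort oracle", {
  m <- fittedRepairModel()
  set.seed(6)
  bg <- vapply(1:200, function(i) randomDna(60L), character(1))
  sums <- vapply(bg, function(ctx)
    sum(predictResolution(m, enumerateMicrohomologies(ctx, 30L))),
    numeric(1))
  m2 <- computeHejCutoff(m, bg, rep(30L, 200L))
  srt <- sort(unname(sums))
  expect_equal(m2@hejCutoff, (srt[100] + srt[101]) / 2)
})

test_that("the hej_sum gate fails targets below the cutoff", {
  m <- flatRepairModel(0.1)
  ctx <- randomDna(70L, seed = 60L)
  a <- assessFsm(m, ctx, 35L)
  m@hejCutoff <- a$hej_sum + 1  # cutoff above this site's sum
  gated <- assessFsm(m, ctx, 35L)
  expect_false(gated$passes_fsm_test)
  expect_equal(gated$fsm_likelihood, a$fsm_likelihood)
})
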