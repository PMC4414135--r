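test_that("simulated panels have forced composition and seeded assignment", {
  cfg <- synthConfig(seed = 3L, nArrayMirs = 10L, nLocusMirs = 4L,
                     nDiff = 3L)
  pan <- simulatePanel(cfg)
  expect_length(mirIds(pan), 10L)
  expect_equal(locusCount(pan, "14q32"), 4L)
  # locus members lie in one contiguous window on one chromosome
  gr <- panelRanges(pan)
  inL <- locusLabels(pan) == "14q32"
  expect_true(all(as.character(GenomicRanges::seqnames(gr))[inL] == "chr14"))

  cfg0 <- synthConfig(seed = 3L, nArrayMirs = 10L, nLocusMirs = 0L,
                      nDiff = 3L)
  pan0 <- simulatePanel(cfg0)
  expect_equal(locusCount(pan0, "14q32"), 0L)
  d0 <- plantDifferentialSet(pan0, "14q32", 0, 3, seed = 1L)
  # with no locus members, downstream fraction is 0%
  expect_equal(locusFraction(d0, pan0, "14q32")$percent, 0)

  cfgA <- synthConfig(seed = 101L); cfgB <- synthConfig(seed = 202L)
  panA <- simulatePanel(cfgA); panB <- simulatePanel(cfgB)
  expect_equal(locusCount(panA, "14q32"), locusCount(panB, "14q32"))
  expect_false(identical(names(which(locusLabels(panA) == "14q32")),
                         names(which(locusLabels(panB) == "14q32"))))

  expect_error(synthConfig(nArrayMirs = 5L, nLocusMirs = 9L), "exceed")
})

test_that("same seed and config give bit-identical fixtures", {
  cfg <- synthConfig(seed = 42L, nArrayMirs = 50L, nLocusMirs = 8L,
                     nDiff = 10L, nGenes = 200L, nPathways = 9L,
                     pathwaySizeRange = c(10L, 20L), nProbes = 60L,
                     nSuppressedPerMir = 10L)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(mirIds(b1$panel), mirIds(b2$panel))
  expect_identical(mirIds(b1$surgical), mirIds(b2$surgical))
  expect_identical(scoreTable(b1$scores), scoreTable(b2$scores))
  expect_identical(SummarizedExperiment::assay(b1$expression, "log2"),
                   SummarizedExperiment::assay(b2$expression, "log2"))
  expect_identical(b1$survival, b2$survival)
  expect_identical(b1$groundTruth, b2$groundTruth)
})

test_that("differential sampling at equal odds reduces to SRS in the mean", {
  base <- synthConfig(nArrayMirs = 30L, nLocusMirs = 10L, nDiff = 10L,
                      locusEnrichmentOdds = 1)
  pan <- simulatePanel(base)
  lab <- locusLabels(pan)
  counts <- vapply(1:1000, function(s) {
    cfg <- base; cfg@seed <- s
    d <- simulateDifferential(pan, cfg)
    sum(lab[mirIds(d)] == "14q32")
  }, 0L)
  m <- 10 * 10 / 30  # hypergeometric mean
  v <- 10 * (10 / 30) * (20 / 30) * (20 / 29)
  expect_lt(abs(mean(counts) - m), 3 * sqrt(v / 1000))
})

test_that("extreme odds push the whole differential set into the locus", {
  cfg <- synthConfig(nArrayMirs = 30L, nLocusMirs = 10L, nDiff = 8L,
                     locusEnrichmentOdds = 1e9, seed = 5L)
  pan <- simulatePanel(cfg)
  d <- simulateDifferential(pan, cfg)
  expect_true(all(locusLabels(pan)[mirIds(d)] == "14q32"))
})

test_that("simulated pathways honour sizes, labels and GMT round-trip", {
  cfg <- synthConfig(nGenes = 100L, nPathways = 7L,
                     pathwaySizeRange = c(5L, 5L), seed = 9L)
  pw <- simulatePathways(cfg)
  expect_length(pw, 7L)
  expect_true(all(vapply(geneSets(pw), length, 0L) == 5L))
  labCounts <- table(functionalGroups(pw))
  expect_lte(max(labCounts) - min(labCounts), 1L)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(pw, gmt)
  back <- readGmt(gmt)
  expect_identical(geneSets(back), geneSets(pw))
  expect_identical(functionalGroups(back), functionalGroups(pw))
})

test_that("planted targeting concentrates above-threshold targets", {
  cfg <- synthConfig(seed = 21L, nGenes = 500L, nPathways = 3L,
                     pathwaySizeRange = c(30L, 40L),
                     targetingConcentration = 1,
                     backgroundTargetRate = 0.05)
  pw <- simulatePathways(cfg)
  ts <- simulateTargetScores("mirX", pw, cfg,
                             planted = list(mirX = "PW01"))
  tg <- thresholdTargets(ts, 0.6)$mirX
  expect_gt(length(tg), 0L)
  expect_true(all(tg %in% geneSets(pw)$PW01))

  expect_error(
    simulateTargetScores("mirX", pw, cfg, planted = list(mirX = "PW99")),
    "unknown pathway")
})

test_that("planted pathway enrichment has power at the default effect", {
  hits <- vapply(1:40, function(s) {
    cfg <- synthConfig(seed = s, nGenes = 1000L, nPathways = 4L,
                       pathwaySizeRange = c(40L, 60L))
    pw <- simulatePathways(cfg)
    ts <- simulateTargetScores("mirX", pw, cfg,
                               planted = list(mirX = "PW01"))
    tg <- thresholdTargets(ts, 0.6)$mirX
    pathwayHypergeom(tg, geneSets(pw)$PW01, geneUniverse(ts))$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("noise-free transfection data recover the planted sets exactly", {
  cfg <- synthConfig(seed = 13L, nProbes = 300L, nSuppressedPerMir = 30L,
                     noiseSd = 0, suppressionLog2fc = log2(1.4))
  planted <- simulateSuppressedSets(cfg, mirs = c("mirA", "mirB"))
  te <- simulateTransfection(cfg, planted)
  for (m in names(planted)) {
    res <- samTest(te, treated = m, control = "NT", s0 = 1)
    expect_setequal(selectSuppressed(res, fcMin = 1.4), planted[[m]])
  }
})

test_that("planted shared-set structure matches the design over seeds", {
  fr <- vapply(1:60, function(s) {
    cfg <- synthConfig(seed = s, nProbes = 3000L,
                       nSuppressedPerMir = 150L, sharedFraction = 0.31)
    sets <- simulateSuppressedSets(cfg, mirs = paste0("m", 1:4))
    sharedFraction(vennCounts(sets))
  }, 0)
  # per-element sharing is Bernoulli(0.31) over ~370 union members
  u <- 4 * 150 / (1 + 2 * 0.31)
  se <- sqrt(0.31 * 0.69 / u) / sqrt(60)
  expect_lt(abs(mean(fr) - 0.31), 3 * se)
})

test_that("fully censored survival cohorts give a flat KM curve", {
  cfg <- synthConfig(seed = 8L, nPatientsPerGroup = 12L, censorRate = 1)
  sv <- simulateSurvival(cfg)
  expect_equal(sum(sv$event), 0L)
  cv <- kmCurve(sv)
  expect_equal(survivalAt(cv, cfg@followupHorizon), 1)
})

test_that("survival generator plants a recoverable group effect", {
  pvals <- vapply(1:20, function(s) {
    cfg <- synthConfig(seed = s, hazardRatio = 3)
    sv <- simulateSurvival(cfg)
    grp <- medianSplit(sv, paste0("mir", 1:4))
    expect_identical(unname(grp[sv$id]), sv$true_group)
    st <- survivalStratified(sv, paste0("mir", 1:4))
    st$logrank@p
  }, 0)
  expect_gt(mean(pvals < 0.05), 0.5)
})
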