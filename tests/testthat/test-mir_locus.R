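test_that("panel construction enforces identifiers and coordinates", {
  pan <- tiny_panel()
  expect_s4_class(pan, "MirPanel")
  expect_length(mirIds(pan), 10L)
  expect_equal(locusCount(pan, "14q32"), 4L)

  bad <- data.frame(mir_id = c("a", "a"), chrom = "chr1", start = 1,
                    end = 2, locus_label = "")
  expect_error(mirPanel(bad), "duplicate")
  bad2 <- data.frame(mir_id = "a", chrom = "chr1", start = 10, end = 5,
                     locus_label = "")
  expect_error(mirPanel(bad2), "coordinates")
})

test_that("panel TSV and GFF3 encodings load identically", {
  pan <- tiny_panel()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writePanel(pan, tsv)
  writePanelGFF3(pan, gff)
  fromTsv <- readPanel(tsv)
  fromGff <- readPanel(gff)
  expect_equal(mirIds(fromTsv), mirIds(pan))
  expect_equal(sort(mirIds(fromGff)), sort(mirIds(pan)))
  expect_equal(locusLabels(fromGff)[mirIds(pan)], locusLabels(pan))
  expect_equal(as.character(GenomicRanges::seqnames(panelRanges(fromGff))),
               as.character(GenomicRanges::seqnames(panelRanges(pan))))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mir_id\tchrom\tstart\tend\tlocus_label", empty)
  expect_error(readPanel(empty), "empty")
})

test_that("locus fractions reproduce the printed dataset configurations", {
  # 14 of 39 -> 36%, 5 of 29 -> 17%, zero -> 0%
  cfg <- synthConfig(seed = 11L)
  pan <- simulatePanel(cfg)
  s14 <- plantDifferentialSet(pan, "14q32", 14, 39, seed = 2L)
  expect_equal(locusFraction(s14, pan, "14q32")$percent, 36)
  s5 <- plantDifferentialSet(pan, "14q32", 5, 29, seed = 3L)
  expect_equal(locusFraction(s5, pan, "14q32")$percent, 17)
  s0 <- plantDifferentialSet(pan, "14q32", 0, 12, seed = 4L)
  expect_equal(locusFraction(s0, pan, "14q32")$percent, 0)

  stray <- differentialMirSet(c(mirIds(pan)[1], "not-on-panel"))
  expect_error(locusFraction(stray, pan, "14q32"), "absent from panel")
})

test_that("exact hypergeometric tail matches brute-force enumeration", {
  expect_equal(exactLocusTest(3, 3, 4, 10), 4 / 120)
  expect_equal(exactLocusTest(3, 3, 4, 10), oracle_hyper_upper(3, 3, 4, 10))
  expect_equal(exactLocusTest(0, 5, 3, 12), 1)
  expect_equal(exactLocusTest(4, 6, 10, 10), 1)  # whole panel in locus
  expect_error(exactLocusTest(5, 3, 4, 10), "inconsistent")

  # monotone non-increasing in k
  p <- vapply(0:5, exactLocusTest, 0, n = 5, K = 6, N = 14)
  expect_true(all(diff(p) <= 0))
})

test_that("permutation p converges to the exact tail and is reproducible", {
  pan <- tiny_panel()
  diff3 <- differentialMirSet(c("m01", "m02", "m03"))  # all in locus
  res <- permutationLocusTest(diff3, pan, "14q32", nPerm = 2e4, seed = 5L)
  expect_equal(res@observed, 3L)
  pex <- exactLocusTest(3, 3, 4, 10)
  expect_lt(abs(pEmpirical(res) - pex),
            3 * sqrt(pex * (1 - pex) / 2e4) + 2 / 2e4)
  expect_equal(pExact(res), pex)

  res2 <- permutationLocusTest(diff3, pan, "14q32", nPerm = 2e4, seed = 5L)
  expect_identical(pEmpirical(res2), pEmpirical(res))

  # observed k = 0: every replicate ties or exceeds
  none <- differentialMirSet(c("m05", "m06"))
  r0 <- permutationLocusTest(none, pan, "14q32", nPerm = 500, seed = 1L)
  expect_equal(r0@exceedCount, 500)
  expect_equal(pEmpirical(r0), 1)

  expect_error(permutationLocusTest(diff3, pan, "1p36", nPerm = 10),
               "absent from panel")
})

test_that("a panel entirely inside the locus gives p_empirical = 1", {
  pan <- mirPanel(data.frame(mir_id = paste0("m", 1:5), chrom = "chr14",
                             start = 1:5 * 100, end = 1:5 * 100 + 10,
                             locus_label = "14q32"))
  d <- differentialMirSet(paste0("m", 1:3))
  r <- permutationLocusTest(d, pan, "14q32", nPerm = 200, seed = 2L)
  expect_equal(r@observed, 3L)
  expect_equal(pEmpirical(r), 1)
  expect_equal(pExact(r), 1)
})
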