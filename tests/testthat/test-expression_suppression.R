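test_that("quantile normalization: fixed point, rank means, ties, idempotence", {
  ident <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(quantileNormalize(ident), ident)

  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # tie rule: tied entries get the mean of the tied ranks' reference values
  tied <- cbind(a = c(5, 5, 3), b = c(1, 2, 4))
  qt <- quantileNormalize(tied)
  expect_equal(unname(qt[, "a"]), c(4, 4, 2))
  expect_equal(unname(qt[, "b"]), c(2, 3.5, 4.5))

  set.seed(4)
  r <- matrix(rnorm(60), 15, 4)
  q1 <- quantileNormalize(r)
  expect_equal(quantileNormalize(q1), q1)                 # idempotent
  ref <- sort(q1[, 1])
  for (j in 2:4) expect_equal(sort(q1[, j]), ref)          # same multiset
  for (j in 1:4) expect_equal(rank(q1[, j]), rank(r[, j])) # ranks kept

  r[3, 2] <- NA
  expect_error(quantileNormalize(r), "impute")
  expect_error(quantileNormalize(m[, 1, drop = FALSE]), "2 columns")
})

test_that("SAM d-statistic and fold change follow the definition", {
  m <- rbind(p1 = c(0, 0, 2, 2),        # the hand-worked probe
             p2 = c(5, 6, 5, 6),
             p3 = c(1, 3, 2, 2))
  te <- transfectionExperiment(m, condition = c("miR", "miR", "NT", "NT"),
                               replicate = c(1, 2, 1, 2))
  res <- samTest(te, "miR", "NT", s0 = 1)
  tb <- samTable(res)
  expect_equal(tb$d[tb$probe_id == "p1"], -2)
  expect_equal(tb$fold_change[tb$probe_id == "p1"], 0.25)
  expect_equal(res@nRelabelings, 6L)

  # identical treated and control values: d = 0 everywhere, nothing called
  same <- rbind(a = c(1, 2, 1, 2), b = c(4, 4, 4, 4))
  te2 <- transfectionExperiment(same, condition = c("t", "t", "NT", "NT"),
                                replicate = c(1, 2, 1, 2))
  r2 <- samTest(te2, "t", "NT", s0 = 1)
  expect_true(all(samTable(r2)$d == 0))
  expect_false(any(samTable(r2)$called_down))

  const <- rbind(a = c(1, 1, 1, 1), b = c(2, 2, 2, 2))
  te3 <- transfectionExperiment(const, condition = c("t", "t", "NT", "NT"),
                                replicate = c(1, 2, 1, 2))
  expect_error(samTest(te3, "t", "NT"), "s0 > 0")
  expect_error(samTest(te3, "t", "missing"), "replicates")
})

test_that("q-values match an exhaustive-relabeling oracle and are monotone", {
  set.seed(7)
  m <- matrix(rnorm(40, 8), 10, 4,
              dimnames = list(paste0("p", 1:10), NULL))
  m[1:2, 1:2] <- m[1:2, 1:2] - 3  # two strongly suppressed probes
  te <- transfectionExperiment(m, condition = c("t", "t", "NT", "NT"),
                               replicate = c(1, 2, 1, 2))
  res <- samTest(te, "t", "NT", s0 = 0.5)
  tb <- samTable(res)

  # oracle: recompute the rule directly from all 6 balanced relabelings
  relab <- utils::combn(4, 2)
  dObs <- oracle_sam_d(m, 1:2, 3:4, s0 = 0.5)
  absd <- sort(abs(dObs), decreasing = TRUE)
  false_counts <- sapply(seq_len(6), function(b) {
    db <- abs(oracle_sam_d(m, relab[, b], setdiff(1:4, relab[, b]),
                           s0 = 0.5))
    vapply(absd, function(t) sum(db >= t - 1e-12), 0)
  })
  fdrHat <- pmin(apply(false_counts, 1, median) / seq_along(absd), 1)
  qOracle <- rev(cummin(rev(fdrHat)))
  got <- tb$q_value[order(abs(tb$d), decreasing = TRUE)]
  expect_equal(got, unname(qOracle))
  expect_true(all(diff(got) >= 0))  # non-increasing in |d|
})

test_that("suppressed-set selection respects both gates and nests", {
  tb <- data.frame(
    probe_id = paste0("p", 1:5),
    d = c(-5, -4, -1, 2, -6),
    fold_change = c(0.4, 1 / 1.4, 0.9, 1.5, 0.5),
    q_value = c(0.01, 0.02, 0.01, 0.01, 0.2),
    called_down = FALSE)
  res <- new("SamResult", table = tb, treated = "t", control = "c",
             s0 = 1, nRelabelings = 6L)
  sel <- selectSuppressed(res, fcMin = 1.4)
  expect_setequal(sel, c("p1", "p2"))  # boundary 1/1.4 included; q gate holds
  expect_length(selectSuppressed(res, fcMin = 1e9), 0L)
  # monotone: larger fcMin never grows the set
  s1 <- selectSuppressed(res, fcMin = 1.2)
  s2 <- selectSuppressed(res, fcMin = 2.0)
  expect_true(all(s2 %in% s1))
  # probe at exactly 2-fold down is included at the pathway gate
  tb2 <- tb; tb2$fold_change[1] <- 0.5
  res2 <- new("SamResult", table = tb2, treated = "t", control = "c",
              s0 = 1, nRelabelings = 6L)
  expect_true("p1" %in% selectPathwayInput(res2, fcMin = 2.0))
  expect_true(all(selectPathwayInput(res) %in% selectSuppressed(res)))
})

test_that("Venn pattern counts equal brute-force classification", {
  disj <- list(A = c("x1", "x2"), B = c("y1"), C = c("z1", "z2", "z3"))
  vd <- patternCounts(vennCounts(disj))
  expect_equal(sum(vd[grepl("&", names(vd))]), 0L)
  expect_equal(vd[["A"]], 2L)

  same <- list(A = c("x", "y"), B = c("x", "y"))
  vs <- patternCounts(vennCounts(same))
  expect_equal(vs[["A&B"]], 2L)
  expect_equal(vs[["A"]] + vs[["B"]], 0L)

  set.seed(11)
  for (k in 3:4) {
    sets <- stats::setNames(
      lapply(seq_len(k), function(i) sample(paste0("e", 1:40),
                                            sample(5:25, 1))),
      paste0("S", seq_len(k)))
    got <- patternCounts(vennCounts(sets))
    want <- oracle_venn(sets)
    expect_equal(got[names(want)], want)
    expect_equal(sum(got), length(unique(unlist(sets))))  # conservation
  }
  expect_error(vennCounts(list(A = "x")), "2 to 4")
})

test_that("pairwise overlap chi-squared matches hand-computed expecteds", {
  A <- paste0("g", 1:30); B <- paste0("g", 11:50)
  t <- pairwiseOverlapChisq(A, B, N = 100)
  expect_lt(abs(t$chisq - 12.698), 1e-3)
  expect_lt(abs(t$p - 3.65e-4), 1e-5)
  expect_equal(unname(t$table[1, 1]), 20)

  # perfect-association limit: A = B of size N/2 gives chi2 = N
  H <- paste0("h", 1:50)
  expect_equal(pairwiseOverlapChisq(H, H, N = 100)$chisq, 100)

  expect_error(pairwiseOverlapChisq(character(0), B, N = 100), "exact")
  expect_error(pairwiseOverlapChisq(A, B, N = 40), "population")

  # on enriched overlaps (the use case) the chi-squared p tracks the
  # exact hypergeometric tail within chi-squared asymptotics
  set.seed(3)
  gap <- replicate(25, {
    N <- 600
    A <- sample(paste0("g", 1:N), 200)
    B <- c(sample(A, 90), sample(setdiff(paste0("g", 1:N), A), 110))
    pc <- pairwiseOverlapChisq(A, B, N)$p
    pe <- pairwiseOverlapChisq(A, B, N, exact = TRUE)$p
    abs(log10(pc) - log10(pe))
  })
  expect_true(all(gap <= 0.3))
})

test_that("overlap chi-squared p-values are calibrated on independent sets", {
  set.seed(19)
  ps <- replicate(300, {
    N <- 400
    A <- sample(paste0("g", 1:N), sample(80:160, 1))
    B <- sample(paste0("g", 1:N), sample(80:160, 1))
    pairwiseOverlapChisq(A, B, N)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
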