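test_that("target thresholding is correct at the boundaries and monotone", {
  ts <- targetScores(data.frame(
    mir = rep(c("a", "b"), each = 3),
    gene = rep(c("g1", "g2", "g3"), 2),
    score = c(0.2, 0.6, 1.0, 0.59, 0.61, 0.0)))
  expect_equal(sort(thresholdTargets(ts, 0)$a), c("g1", "g2", "g3"))
  expect_equal(thresholdTargets(ts, 1)$a, "g3")
  expect_equal(thresholdTargets(ts, 0.6)$b, "g2")  # boundary included

  set.seed(1)
  big <- targetScores(data.frame(mir = "m", gene = paste0("g", 1:200),
                                 score = runif(200)))
  sizes <- vapply(seq(0, 1, by = 0.1),
                  function(t) length(thresholdTargets(big, t)$m), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("hypergeometric enrichment matches enumeration and edge cases", {
  uni <- paste0("g", 1:20)
  cell <- pathwayHypergeom(uni[1:5], uni[c(1:4, 10)], uni)
  expect_equal(cell$k, 4L)
  expect_equal(cell$p, 76 / 15504)
  expect_equal(cell$p, oracle_hyper_upper(4, 5, 5, 20))

  expect_equal(pathwayHypergeom(character(0), uni[1:5], uni)$p, 1)
  expect_equal(pathwayHypergeom(uni[1:7], uni, uni)$p, 1)
  expect_error(pathwayHypergeom("g1", "g1", character(0)), "empty")
})

test_that("Fisher combination: identity, closed form, and invariances", {
  grid <- seq(0.01, 1, length.out = 100)
  for (p in grid)
    expect_lt(abs(combineFisher(p)$p - p), 1e-12)

  two <- combineFisher(c(0.1, 0.1))
  expect_equal(two$X2, -2 * (log(0.1) + log(0.1)))
  expect_equal(two$df, 4L)
  expect_equal(two$p, oracle_chisq4_upper(two$X2))
  expect_lt(abs(two$p - 0.0561), 5e-4)

  expect_equal(combineFisher(c(1, 1, 1))$p, 1)
  expect_equal(combineFisher(c(0.3, 0.02, 0.77))$p,
               combineFisher(c(0.77, 0.3, 0.02))$p)
  # weakly decreasing when any member decreases
  expect_lt(combineFisher(c(0.05, 0.2))$p, combineFisher(c(0.1, 0.2))$p)
  expect_error(combineFisher(c(0.5, 0)), "floor")
  expect_error(combineFisher(numeric(0)), "at least one")
})

test_that("heatmap matrix holds -log10 p and masks by combined alpha", {
  cells <- data.frame(
    mir = rep(c("m1", "m2"), each = 2),
    pathway = rep(c("P1", "P2"), 2),
    k = 1, K = 2, n = 3, N = 10,
    p = c(0.05, 1, 0.2, 0.01))
  comb <- combinePathways(cells)
  hm <- heatmapMatrix(cells, comb, alpha = 1)  # retain everything
  expect_setequal(colnames(hm$matrix), c("P1", "P2"))
  expect_equal(hm$matrix["m1", "P1"], -log10(0.05))
  expect_equal(hm$matrix["m1", "P2"], 0)
  expect_lt(abs(hm$matrix["m1", "P1"] - 1.301), 1e-3)
  # restrictive alpha drops non-significant combined columns
  hm2 <- heatmapMatrix(cells, comb, alpha = 0.05)
  expect_true(all(hm2$pathways %in% comb$pathway[comb$p <= 0.05]))
})

test_that("row clustering matches a hand agglomeration", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(4, 0), r4 = c(10, 10))
  cl <- clusterRows(m)
  # hand average-linkage: {r1,r2} at 1; +r3 at (4 + sqrt(17))/2;
  # +r4 at mean of the three singleton distances
  expect_equal(cl$height,
               c(1, (4 + sqrt(17)) / 2,
                 (sqrt(200) + sqrt(181) + sqrt(136)) / 3))
  expect_setequal(abs(cl$merge[1, ]), c(1, 2))

  dup <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1))
  cld <- clusterRows(dup)
  expect_true(all(cld$height == 0))

  near <- rbind(x = c(0, 0), y = c(0, 0), z = c(5, 5))
  cln <- clusterRows(near)
  expect_setequal(abs(cln$merge[1, ]), c(1, 2))  # identical rows first
  expect_error(clusterRows(m[1, , drop = FALSE]), "2 rows")
})

test_that("functional-group assignment is total, safe and round-trips", {
  pw <- pathwayCollection(list(P1 = c("a", "b"), P2 = c("c", "d"),
                               P3 = c("e", "f")))
  expect_true(all(functionalGroups(pw) == "unassigned"))

  mapped <- assignGroups(pw, c(P1 = "AIM", P2 = "ICS"))
  expect_equal(unname(functionalGroups(mapped)[c("P1", "P2", "P3")]),
               c("AIM", "ICS", "unassigned"))
  expect_warning(assignGroups(pw, c(P9 = "AIM")), "unknown pathway")
  expect_error(assignGroups(pw, c(P1 = "XYZ")), "unknown functional group")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeGroupMap(c(P1 = "AIM", P2 = "CSS"), f)
  expect_identical(readGroupMap(f), c(P1 = "AIM", P2 = "CSS"))
})

test_that("AIM ranking follows (count, score, id) with correct dominance", {
  pw <- pathwayCollection(
    list(A1 = "g1", A2 = "g2", A3 = "g3", I1 = "g4"),
    groups = c(A1 = "AIM", A2 = "AIM", A3 = "AIM", I1 = "ICS"))
  cells <- data.frame(
    mir = rep(c("mA", "mB", "mC"), each = 4),
    pathway = rep(c("A1", "A2", "A3", "I1"), 3),
    p = c(0.01, 0.02, 0.03, 1e-9,   # mA: 3 AIM hits
          1e-12, 1, 1, 1,           # mB: 1 AIM hit, huge score
          0.04, 0.04, 1, 1))        # mC: 2 AIM hits
  rk <- rankByAim(cells, pw)
  expect_equal(rk$mir, c("mA", "mC", "mB"))
  expect_equal(rk$rank, 1:3)

  one <- rankByAim(cells[cells$mir == "mB", ], pw)
  expect_equal(one$rank, 1L)

  # oracle: exhaustive comparison by the stated sort keys
  key <- function(d) order(-d$n_significant_aim, -d$aim_score, d$mir)
  unranked <- rk[order(rk$mir), c("mir", "n_significant_aim", "aim_score")]
  expect_equal(unranked$mir[key(unranked)], rk$mir)
})

test_that("pathway network applies the minimum-microRNA degree filter", {
  cells <- data.frame(
    mir = c("m1", "m2", "m3", "m1", "m2"),
    pathway = c("P1", "P1", "P1", "P2", "P3"),
    p = c(0.01, 0.01, 0.04, 0.02, 0.2))
  all1 <- pathwayNetwork(cells, minMirs = 1L)
  expect_equal(nrow(all1), 4L)  # the p = 0.2 edge is not significant
  net <- pathwayNetwork(cells, minMirs = 2L)
  expect_equal(unique(net$pathway), "P1")
  expect_equal(unique(net$degree), 3L)
  none <- pathwayNetwork(cells[cells$p > 0.1, , drop = FALSE])
  expect_equal(nrow(none), 0L)
})
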