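#' @include AllClasses.R AllGenerics.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
NULL

#' Construct a TransfectionExperiment
#'
#' @param log2values numeric probes-by-samples matrix of log2 intensities
#'   with probe ids as rownames.
#' @param condition character vector (one per column): transfected
#'   microRNA or the non-targeting control label.
#' @param replicate integer vector (one per column).
#' @return a [TransfectionExperiment-class].
#' @export
transfectionExperiment <- function(log2values, condition, replicate) {
  log2values <- as.matrix(log2values)
  if (length(condition) != ncol(log2values) ||
      length(replicate) != ncol(log2values))
    stop("condition/replicate must have one entry per sample column")
  if (is.null(rownames(log2values)))
    rownames(log2values) <- paste0("probe_", seq_len(nrow(log2values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2values),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.integer(replicate)))
  new("TransfectionExperiment", se)
}

#' Condition labels of a TransfectionExperiment
#' @param x a [TransfectionExperiment-class]
#' @return character vector of per-sample condition labels.
#' @export
conditions <- function(x) SummarizedExperiment::colData(x)$condition

#' Quantile normalization across arrays
#'
#' Forces every column to share the same value distribution: each column's
#' sorted values are replaced by the across-column means of the sorted
#' values at each rank, preserving within-column ranks; tied entries
#' receive the mean of their tied rank positions' reference values.
#' The transform is idempotent, and a matrix whose columns are already
#' identical is a fixed point. Delegates to
#' [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param x numeric matrix (probes x samples, >= 2 columns) or a
#'   [TransfectionExperiment-class].
#' @param ... unused.
#' @return an object of the same class as `x`, normalized.
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (ncol(x) < 2L) stop("need at least 2 columns to normalize across")
  if (anyNA(x))
    stop("missing values present; impute explicitly before normalization")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize-matrix-method
#' @export
setMethod("quantileNormalize", "TransfectionExperiment", function(x, ...) {
  m <- quantileNormalize(SummarizedExperiment::assay(x, "log2"))
  cd <- SummarizedExperiment::colData(x)
  transfectionExperiment(m, cd$condition, cd$replicate)
})

# all balanced relabelings of the pooled samples: every way of choosing
# |treated| of the pooled columns as pseudo-treated (the identity among
# them). With duplicate arrays (2 vs 2) this is the full set of 6.
.balancedRelabelings <- function(nTreated, nControl) {
  utils::combn(nTreated + nControl, nTreated)
}

.samD <- function(m, treatIdx, ctrlIdx, s0) {
  n1 <- length(treatIdx); n2 <- length(ctrlIdx)
  mt <- rowMeans(m[, treatIdx, drop = FALSE])
  mc <- rowMeans(m[, ctrlIdx, drop = FALSE])
  ssT <- rowSums((m[, treatIdx, drop = FALSE] - mt)^2)
  ssC <- rowSums((m[, ctrlIdx, drop = FALSE] - mc)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  s <- sqrt(a * (ssT + ssC))
  list(d = (mt - mc) / (s + s0), diff = mt - mc, s = s)
}

#' SAM-style permutation differential expression
#'
#' Significance-analysis-of-microarrays statistic for one contrast: per
#' probe, `d = (mean_treated - mean_control) / (s + s0)` with `s` the
#' pooled standard error and `s0` an exchangeability constant (default:
#' the median of the per-probe standard errors, a robust deterministic
#' choice). False discovery rates are estimated from balanced label
#' permutations: at each probe's `|d|` threshold, the q-value is the
#' median permutation false-call count divided by the observed call count,
#' capped at 1 and made monotone non-increasing in the `|d|` ranking.
#' With duplicate arrays (2 vs 2) all 6 balanced relabelings are
#' enumerated exhaustively instead of sampling, so q-value granularity is
#' set by the per-relabeling false-call medians.
#'
#' @param x a [TransfectionExperiment-class] (normalized).
#' @param treated condition label of the transfected microRNA.
#' @param control condition label of the non-targeting control.
#' @param s0 exchangeability constant; `NULL` (default) uses the median
#'   per-probe pooled standard error. Must be > 0 when probes can be
#'   constant across samples (e.g. noise-free data).
#' @param fdr FDR level used only to set the `called_down` flag (default
#'   0.05).
#' @return a [SamResult-class].
#' @export
samTest <- function(x, treated, control, s0 = NULL, fdr = 0.05) {
  cond <- conditions(x)
  tIdx <- which(cond == treated)
  cIdx <- which(cond == control)
  if (length(tIdx) < 2L || length(cIdx) < 2L)
    stop("both conditions need >= 2 replicates (treated: ", length(tIdx),
         ", control: ", length(cIdx), ")")
  m <- SummarizedExperiment::assay(x, "log2")[, c(tIdx, cIdx), drop = FALSE]
  n1 <- length(tIdx); n2 <- length(cIdx)
  obs <- .samD(m, seq_len(n1), n1 + seq_len(n2), s0 = 0)
  if (is.null(s0)) s0 <- stats::median(obs$s)
  if (any(obs$s + s0 == 0))
    stop("constant probe(s) give s + s0 = 0; supply s0 > 0")
  d <- (obs$diff) / (obs$s + s0)
  fc <- 2^obs$diff

  relab <- .balancedRelabelings(n1, n2)
  B <- ncol(relab)
  absd <- abs(d)
  ord <- order(absd, decreasing = TRUE)
  thresholds <- absd[ord]
  # false-call count per relabeling at each observed |d| threshold
  falseCalls <- matrix(0, nrow = length(d), ncol = B)
  for (b in seq_len(B)) {
    tb <- relab[, b]
    cb <- setdiff(seq_len(n1 + n2), tb)
    db <- abs(.samD(m, tb, cb, s0 = s0)$d)
    dbSorted <- sort(db)
    # count of permuted |d| >= threshold, for each threshold
    falseCalls[, b] <- length(db) -
      findInterval(thresholds - 1e-12, dbSorted)
  }
  medFalse <- apply(falseCalls, 1L, stats::median)
  fdrHat <- pmin(medFalse / seq_along(thresholds), 1)
  # q at rank r = min FDR over all thresholds at least as liberal
  q <- rev(cummin(rev(fdrHat)))
  qOut <- numeric(length(d))
  qOut[ord] <- q

  tb <- data.frame(probe_id = rownames(m), d = d, fold_change = fc,
                   q_value = qOut,
                   called_down = qOut <= fdr & d < 0,
                   row.names = NULL)
  new("SamResult", table = tb, treated = treated, control = control,
      s0 = s0, nRelabelings = as.integer(B))
}

#' @rdname samTest
#' @param x a `SamResult`
#' @export
setMethod("samTable", "SamResult", function(x) x@table)

setMethod("show", "SamResult", function(object) {
  tb <- object@table
  cat("SamResult: ", object@treated, " vs ", object@control, ", ",
      nrow(tb), " probes, s0 = ", format(object@s0, digits = 3),
      ", ", object@nRelabelings, " balanced relabelings\n", sep = "")
  cat("  called down at q <= 0.05:", sum(tb$called_down), "\n")
})

# comparisons on the log2 scale with a small tolerance so that planted
# shifts of exactly log2(fc) survive floating-point round trips
.FC_TOL <- 1e-9

#' Select suppressed probes
#'
#' Probes down-regulated at least `fcMin`-fold (treated/control
#' `<= 1/fcMin`) at estimated FDR `<= fdrMax`.
#'
#' @param res a [SamResult-class].
#' @param fcMin minimum (linear) fold suppression, default 1.4.
#' @param fdrMax FDR ceiling, default 0.05.
#' @return character vector of probe ids.
#' @export
selectSuppressed <- function(res, fcMin = 1.4, fdrMax = 0.05) {
  tb <- samTable(res)
  down <- log2(tb$fold_change) <= -log2(fcMin) + .FC_TOL
  tb$probe_id[down & tb$q_value <= fdrMax]
}

#' Select the stricter gene set handed to pathway analysis
#'
#' Applies the more stringent fold-change gate (>= 2.0-fold suppression by
#' default, boundary included) used before pathway over-representation;
#' always a subset of the [selectSuppressed()] call set when `fcMin` is
#' larger.
#'
#' @param res a [SamResult-class].
#' @param fcMin minimum fold suppression, default 2.0.
#' @param fdrMax FDR ceiling, default 0.05.
#' @return character vector of probe ids.
#' @export
selectPathwayInput <- function(res, fcMin = 2.0, fdrMax = 0.05) {
  selectSuppressed(res, fcMin = fcMin, fdrMax = fdrMax)
}

.patternName <- function(labels, memb) paste(labels[memb], collapse = "&")

#' Venn membership-pattern counts
#'
#' Classifies every element of the union of 2 to 4 sets into its
#' membership pattern (one of the `2^k - 1` non-empty Venn regions) and
#' counts each pattern. Also reports the count common to all sets and the
#' fraction of the union belonging to two or more sets.
#'
#' @param sets named list of 2-4 character vectors.
#' @return an [OverlapResult-class] (pairwise slot empty; see
#'   [overlapAnalysis()] to fill it).
#' @export
vennCounts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("vennCounts supports 2 to 4 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  labels <- names(sets)
  sets <- lapply(sets, unique)
  un <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, nrow = 1L)
  patterns <- unlist(lapply(seq_len(k), function(r)
    utils::combn(k, r, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(patterns, function(idx) {
    inPat <- rep(TRUE, length(un))
    for (j in seq_len(k)) {
      inPat <- inPat & (memb[, j] == (j %in% idx))
    }
    sum(inPat)
  }, 0L)
  names(counts) <- vapply(patterns, function(idx)
    .patternName(labels, idx), "")
  new("OverlapResult", labels = labels, patternCounts = counts,
      pairwise = data.frame(), populationSize = NA_real_)
}

#' @rdname vennCounts
#' @param x an `OverlapResult`
#' @export
setMethod("patternCounts", "OverlapResult", function(x) x@patternCounts)

#' @rdname vennCounts
#' @export
setMethod("pairwiseTests", "OverlapResult", function(x) x@pairwise)

#' Shared fraction of an overlap
#'
#' Fraction of the union belonging to two or more of the sets.
#'
#' @param x an [OverlapResult-class].
#' @return a number in `[0, 1]`.
#' @export
sharedFraction <- function(x) {
  cnt <- x@patternCounts
  multi <- vapply(strsplit(names(cnt), "&", fixed = TRUE), length, 0L) >= 2L
  total <- sum(cnt)
  if (total == 0L) return(0)
  sum(cnt[multi]) / total
}

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult over sets:", paste(object@labels, collapse = ", "),
      "\n")
  cat("  union size:", sum(object@patternCounts),
      sprintf("(%.0f%% in >= 2 sets)\n", 100 * sharedFraction(object)))
  if (nrow(object@pairwise))
    cat("  pairwise chi-squared tests over population N =",
        object@populationSize, "\n")
})

#' Pairwise overlap chi-squared test
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table
#' cross-classifying a population of `N` probes by membership in sets A
#' and B. `N` must be supplied explicitly: it is the total number of
#' probes detected across all arrays, a quantity the caller knows and this
#' function cannot infer.
#'
#' @param A,B character vectors (probe sets).
#' @param N population size, `>= |A union B|`.
#' @param exact if `TRUE`, use the exact hypergeometric (one-sided
#'   Fisher) test instead; recommended when expected cells are small.
#' @return list with `table` (the 2x2 matrix), `chisq`, `df`, `p`.
#' @examples
#' pairwiseOverlapChisq(paste0("g", 1:30), paste0("g", 11:50), N = 100)
#' @export
pairwiseOverlapChisq <- function(A, B, N, exact = FALSE) {
  A <- unique(A); B <- unique(B)
  nAB <- length(intersect(A, B))
  nA <- length(A); nB <- length(B)
  nUnion <- nA + nB - nAB
  if (nUnion > N)
    stop("population size N (", N, ") smaller than |A union B| (",
         nUnion, ")")
  tab <- matrix(c(nAB, nA - nAB, nB - nAB, N - nUnion), nrow = 2L,
                dimnames = list(inA = c("yes", "no"),
                                inB = c("yes", "no")))
  if (exact) {
    ft <- stats::fisher.test(tab, alternative = "greater")
    return(list(table = tab, chisq = NA_real_, df = NA_integer_,
                p = ft$p.value))
  }
  expct <- outer(rowSums(tab), colSums(tab)) / N
  if (any(expct == 0))
    stop("an expected cell is zero (degenerate margins); ",
         "use exact = TRUE")
  chisq <- sum((tab - expct)^2 / expct)
  list(table = tab, chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Full co-repression overlap analysis
#'
#' Combines [vennCounts()] with all pairwise chi-squared overlap tests
#' over an explicit probe population.
#'
#' @param sets named list of 2-4 probe sets.
#' @param N population size (total probes detected across all arrays).
#' @param exact use the exact test for the pairwise comparisons.
#' @return an [OverlapResult-class] with the pairwise slot filled.
#' @export
overlapAnalysis <- function(sets, N, exact = FALSE) {
  res <- vennCounts(sets)
  labels <- res@labels
  prs <- utils::combn(length(labels), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- labels[prs[1, j]]; b <- labels[prs[2, j]]
    t <- pairwiseOverlapChisq(sets[[a]], sets[[b]], N = N, exact = exact)
    data.frame(a = a, b = b, n_a = length(unique(sets[[a]])),
               n_b = length(unique(sets[[b]])),
               n_ab = length(intersect(sets[[a]], sets[[b]])),
               chisq = t$chisq, p = t$p)
  })
  res@pairwise <- do.call(rbind, rows)
  res@populationSize <- N
  res
}
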