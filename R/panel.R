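#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a MirPanel
#'
#' @param records data.frame with columns `mir_id`, `chrom`, `start`, `end`,
#'   `locus_label` (`""` or `NA` for microRNAs outside any labelled locus),
#'   or a `GRanges` with `mir_id` and `locus` metadata columns.
#' @param name panel name.
#' @return a [MirPanel-class].
#' @examples
#' pan <- mirPanel(data.frame(
#'   mir_id = c("miR-127-5p", "miR-21-5p"),
#'   chrom = c("chr14", "chr17"),
#'   start = c(100906500, 59841266),
#'   end = c(100906521, 59841287),
#'   locus_label = c("14q32", "")))
#' locusCount(pan, "14q32")
#' @export
mirPanel <- function(records, name = "panel") {
  if (is(records, "GRanges")) {
    gr <- records
  } else {
    records <- as.data.frame(records)
    need <- c("mir_id", "chrom", "start", "end", "locus_label")
    miss <- setdiff(need, names(records))
    if (length(miss))
      stop("panel records missing column(s): ", paste(miss, collapse = ", "))
    st <- suppressWarnings(as.numeric(records$start))
    en <- suppressWarnings(as.numeric(records$end))
    bad <- which(is.na(st) | is.na(en) | st > en | st < 1)
    if (length(bad))
      stop("malformed coordinates at record(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (require 1 <= start <= end)")
    locus <- as.character(records$locus_label)
    locus[is.na(locus)] <- ""
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(records$chrom),
      ranges = IRanges::IRanges(start = st, end = en),
      mir_id = as.character(records$mir_id),
      locus = locus)
  }
  new("MirPanel", ranges = gr, panelName = name)
}

#' @describeIn mirPanel number of microRNAs on the panel
#' @param x a `MirPanel`
#' @export
setMethod("length", "MirPanel", function(x) length(x@ranges))

#' @rdname mirPanel
#' @export
setMethod("mirIds", "MirPanel",
          function(x) S4Vectors::mcols(x@ranges)$mir_id)

#' @rdname mirPanel
#' @export
setMethod("locusLabels", "MirPanel", function(x) {
  lab <- S4Vectors::mcols(x@ranges)$locus
  names(lab) <- S4Vectors::mcols(x@ranges)$mir_id
  lab
})

#' @rdname mirPanel
#' @export
setMethod("panelName", "MirPanel", function(x) x@panelName)

#' @rdname mirPanel
#' @param locus locus label to count
#' @export
setMethod("locusCount", "MirPanel", function(x, locus)
  sum(locusLabels(x) == locus))

setMethod("show", "MirPanel", function(object) {
  lab <- locusLabels(object)
  labelled <- table(lab[lab != ""])
  cat("MirPanel '", object@panelName, "' with ", length(object),
      " microRNAs\n", sep = "")
  if (length(labelled))
    cat("  locus members:",
        paste(names(labelled), labelled, sep = "=", collapse = ", "), "\n")
})

#' Ranges of a panel
#'
#' @param panel a [MirPanel-class]
#' @return the underlying `GRanges`.
#' @export
panelRanges <- function(panel) panel@ranges

#' Construct a differential microRNA set
#'
#' @param mirIds character vector of microRNA identifiers.
#' @param datasetLabel dataset name, e.g. `"surgical"` or `"SBRT"`.
#' @param direction contrast tag.
#' @return a [DifferentialMirSet-class].
#' @export
differentialMirSet <- function(mirIds, datasetLabel = "dataset",
                               direction = "up_in_oligometastasis") {
  new("DifferentialMirSet", mirIds = as.character(mirIds),
      datasetLabel = datasetLabel, direction = direction)
}

#' @rdname differentialMirSet
#' @param x a `DifferentialMirSet`
#' @export
setMethod("mirIds", "DifferentialMirSet", function(x) x@mirIds)

#' @rdname differentialMirSet
#' @export
setMethod("datasetLabel", "DifferentialMirSet", function(x) x@datasetLabel)

#' @rdname differentialMirSet
#' @export
setMethod("length", "DifferentialMirSet", function(x) length(x@mirIds))

setMethod("show", "DifferentialMirSet", function(object) {
  cat("DifferentialMirSet '", object@datasetLabel, "' (",
      object@direction, "): ", length(object@mirIds), " microRNAs\n",
      sep = "")
})

.checkDiffInPanel <- function(diff, panel) {
  miss <- setdiff(mirIds(diff), mirIds(panel))
  if (length(miss))
    stop("differential-set member(s) absent from panel: ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(TRUE)
}

#' Fraction of a differential set inside a genomic locus
#'
#' Counts the members of a differential microRNA set whose panel record
#' carries the given locus label, and expresses the count as a percentage of
#' the set size (rounded half-up to the nearest integer, matching how such
#' fractions are conventionally reported, e.g. 14 of 39 -> 36%).
#'
#' @param diff a [DifferentialMirSet-class].
#' @param panel the companion [MirPanel-class]; every set member must be on
#'   the panel.
#' @param locus locus label, e.g. `"14q32"`.
#' @return list with `count`, `total` and `percent`.
#' @export
locusFraction <- function(diff, panel, locus) {
  .checkDiffInPanel(diff, panel)
  lab <- locusLabels(panel)
  count <- sum(lab[mirIds(diff)] == locus)
  total <- length(diff)
  # round half-up (base round() is half-to-even)
  percent <- floor(100 * count / total + 0.5)
  list(count = count, total = total, percent = percent)
}

#' Exact hypergeometric locus-enrichment tail
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a uniformly drawn size-n subset of an N-microRNA panel with K
#' locus members contains at least k of them. This is the exact marginal of
#' the whole-set resampling null used by [permutationLocusTest()] and serves
#' as its analytic oracle.
#'
#' @param k observed locus-member count in the set.
#' @param n set size.
#' @param K locus members on the panel.
#' @param N panel size.
#' @return the tail probability.
#' @examples
#' exactLocusTest(3, 3, 4, 10)  # C(4,3) / C(10,3) = 1/30
#' @export
exactLocusTest <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N)
    stop("inconsistent counts: require 0 <= k <= n <= N and K <= N")
  if (k > K) return(0)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Permutation test for genomic-locus enrichment
#'
#' Tests whether a differential microRNA set contains more members of a
#' prespecified genomic locus than expected when sets of the same size are
#' drawn uniformly without replacement from the array panel. Each replicate
#' resamples the whole set and counts locus members; replicates tying the
#' observed count are counted as exceedances, and the empirical p-value uses
#' the add-one estimator `(exceedances + 1) / (n_perm + 1)` so that a zero
#' exceedance count at, say, 1e6 replicates reports ~1e-6 rather than 0.
#' The exact hypergeometric tail ([exactLocusTest()]) is returned alongside.
#'
#' @param diff a [DifferentialMirSet-class].
#' @param panel the companion [MirPanel-class].
#' @param locus locus label; must be present on the panel.
#' @param nPerm number of permutation replicates (default 1e6).
#' @param seed RNG seed for the replicates.
#' @return a [PermutationResult-class].
#' @export
permutationLocusTest <- function(diff, panel, locus, nPerm = 1e6,
                                 seed = 1L) {
  .checkDiffInPanel(diff, panel)
  lab <- locusLabels(panel)
  K <- sum(lab == locus)
  if (K == 0L)
    stop("locus '", locus, "' absent from panel; the test would be degenerate")
  N <- length(panel)
  n <- length(diff)
  k <- sum(lab[mirIds(diff)] == locus)
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  # locus members mapped to indices 1..K so a replicate's count is a
  # cheap comparison on the sampled indices
  set.seed(seed)
  exceed <- 0L
  if (k == 0L) {
    exceed <- nPerm  # every replicate count >= 0
  } else {
    for (i in seq_len(nPerm)) {
      if (sum(sample.int(N, n) <= K) >= k) exceed <- exceed + 1L
    }
  }
  new("PermutationResult",
      locusLabel = locus, observed = as.integer(k), setSize = as.integer(n),
      panelLocusCount = as.integer(K), panelSize = as.integer(N),
      nPerm = nPerm, exceedCount = as.numeric(exceed),
      pEmpirical = (exceed + 1) / (nPerm + 1),
      pExact = exactLocusTest(k, n, K, N), seed = as.integer(seed))
}

#' @rdname permutationLocusTest
#' @param x a `PermutationResult`
#' @export
setMethod("pEmpirical", "PermutationResult", function(x) x@pEmpirical)

#' @rdname permutationLocusTest
#' @export
setMethod("pExact", "PermutationResult", function(x) x@pExact)

setMethod("show", "PermutationResult", function(object) {
  cat("Locus-enrichment permutation test (", object@locusLabel, ")\n",
      sep = "")
  cat(sprintf("  observed %d of %d in locus (panel: %d of %d)\n",
              object@observed, object@setSize, object@panelLocusCount,
              object@panelSize))
  pe <- object@pEmpirical
  ptxt <- if (object@exceedCount == 0 && object@nPerm >= 1e4)
    "< 0.0001" else format(pe, digits = 3)
  cat(sprintf("  empirical p = %s (%d replicates), exact p = %s\n",
              ptxt, object@nPerm, format(object@pExact, digits = 3)))
})
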