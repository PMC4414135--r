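#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TargetScores object
#'
#' @param scores data.frame with columns `mir`, `gene`, `score` (in
#'   `[0, 1]`).
#' @param universe optional explicit gene universe; defaults to the union
#'   of scored genes. The universe is the denominator population of every
#'   hypergeometric pathway test.
#' @return a [TargetScores-class].
#' @export
targetScores <- function(scores, universe = NULL) {
  scores <- as.data.frame(scores)[, c("mir", "gene", "score")]
  scores$mir <- as.character(scores$mir)
  scores$gene <- as.character(scores$gene)
  if (is.null(universe)) universe <- unique(scores$gene)
  new("TargetScores", scores = scores, universe = as.character(universe))
}

#' @rdname targetScores
#' @param x a `TargetScores`
#' @export
setMethod("scoreTable", "TargetScores", function(x) x@scores)

#' @rdname targetScores
#' @export
setMethod("geneUniverse", "TargetScores", function(x) x@universe)

setMethod("show", "TargetScores", function(object) {
  cat("TargetScores:", nrow(object@scores), "scored pairs,",
      length(unique(object@scores$mir)), "microRNAs,",
      length(object@universe), "genes in universe\n")
})

#' Construct a PathwayCollection
#'
#' @param sets named list of gene-identifier vectors.
#' @param groups optional named character vector of functional-group labels
#'   (`AIM`, `ICS`, `CSS`, `unassigned`); defaults to all `unassigned`.
#' @return a [PathwayCollection-class].
#' @export
pathwayCollection <- function(sets, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(rep("unassigned", length(sets)), names(sets))
  new("PathwayCollection", sets = lapply(sets, as.character),
      groups = groups[names(sets)])
}

#' @rdname pathwayCollection
#' @param x a `PathwayCollection`
#' @export
setMethod("geneSets", "PathwayCollection", function(x) x@sets)

#' @rdname pathwayCollection
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x) names(x@sets))

#' @rdname pathwayCollection
#' @export
setMethod("functionalGroups", "PathwayCollection", function(x) x@groups)

#' @rdname pathwayCollection
#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection:", length(object@sets), "pathways (",
      paste(names(table(object@groups)), table(object@groups),
            sep = "=", collapse = ", "), ")\n")
})

#' Attach functional-group labels to pathways
#'
#' Mirrors the manual curation step in which significantly enriched
#' pathways are distributed into functional groups: adhesion/invasion/
#' motility (AIM), intracellular signaling (ICS) and cancer-specific
#' signaling (CSS). Pathways absent from the mapping stay `unassigned`;
#' mapping entries for unknown pathway ids raise a warning, not an error.
#'
#' @param pathways a [PathwayCollection-class].
#' @param mapping named character vector `pathway_id -> group`, e.g. from
#'   [readGroupMap()].
#' @return the relabelled [PathwayCollection-class].
#' @export
assignGroups <- function(pathways, mapping) {
  unknown <- setdiff(names(mapping), pathwayIds(pathways))
  if (length(unknown))
    warning("group mapping refers to unknown pathway id(s): ",
            paste(utils::head(unknown, 5), collapse = ", "))
  bad <- setdiff(unique(mapping), .FUNCTIONAL_GROUPS)
  if (length(bad))
    stop("unknown functional group(s): ", paste(bad, collapse = ", "))
  groups <- stats::setNames(rep("unassigned", length(pathways)),
                            pathwayIds(pathways))
  keep <- intersect(names(mapping), names(groups))
  groups[keep] <- mapping[keep]
  pathwayCollection(geneSets(pathways), groups = groups)
}

#' Threshold predicted targets
#'
#' A gene is a target of a microRNA when its interaction score is at or
#' above `tau` (0.6 by default, the conventional microT cut-off).
#'
#' @param scores a [TargetScores-class].
#' @param tau threshold in `[0, 1]`.
#' @return named list: for each microRNA, its target gene set.
#' @export
thresholdTargets <- function(scores, tau = 0.6) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  tb <- scoreTable(scores)
  keep <- tb$score >= tau
  split(tb$gene[keep], factor(tb$mir[keep], levels = unique(tb$mir)))
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail probability that a target set's overlap with a pathway gene
#' set is at least as large as observed, under uniform sampling without
#' replacement from the gene universe:
#' `P(X >= k)`, `X ~ Hypergeometric(N = |universe|, K = |pathway|,
#' n = |targets|)`, `k = |targets intersect pathway|`.
#'
#' @param targets character vector of target genes (subset of universe).
#' @param pathway character vector of pathway genes (subset of universe).
#' @param universe the gene universe.
#' @return list (one enrichment cell): `k`, `K`, `n`, `N`, `p`.
#' @export
pathwayHypergeom <- function(targets, pathway, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty gene universe")
  targets <- unique(intersect(targets, universe))
  pathway <- unique(intersect(pathway, universe))
  k <- length(intersect(targets, pathway))
  n <- length(targets)
  K <- length(pathway)
  p <- if (k == 0L) 1
       else stats::phyper(k - 1, m = K, n = N - K, k = n,
                          lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Per-(microRNA, pathway) enrichment table
#'
#' Runs [pathwayHypergeom()] for every microRNA target set against every
#' pathway.
#'
#' @param targetsByMir named list of target gene sets (see
#'   [thresholdTargets()]).
#' @param pathways a [PathwayCollection-class].
#' @param universe gene universe for the tests.
#' @return data.frame with columns `mir`, `pathway`, `k`, `K`, `n`, `N`,
#'   `p`.
#' @export
enrichmentTable <- function(targetsByMir, pathways, universe) {
  mirs <- names(targetsByMir)
  pids <- pathwayIds(pathways)
  sets <- geneSets(pathways)
  rows <- vector("list", length(mirs) * length(pids))
  i <- 0L
  for (m in mirs) {
    for (q in pids) {
      cell <- pathwayHypergeom(targetsByMir[[m]], sets[[q]], universe)
      i <- i + 1L
      rows[[i]] <- data.frame(mir = m, pathway = q, k = cell$k, K = cell$K,
                              n = cell$n, N = cell$N, p = cell$p)
    }
  }
  do.call(rbind, rows)
}

#' Fisher's combined probability method
#'
#' Aggregates independent p-values via `X2 = -2 * sum(log(p))` compared to
#' a chi-squared distribution with `2 * length(p)` degrees of freedom. For
#' a single p-value the combination is the identity. Values are floored at
#' 1e-300 before the log so that underflowed (but positive) inputs remain
#' usable; a p-value of exactly zero is an error (floor upstream).
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return list with `X2`, `df`, `p` and `neglog10` (= -log10 of the
#'   combined p).
#' @examples
#' combineFisher(c(0.1, 0.1))  # X2 = 9.21, df = 4, p ~ 0.0561
#' @export
combineFisher <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one p-value")
  if (any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]; floor zero values before combining")
  pvalues <- pmax(pvalues, 1e-300)
  X2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  p <- stats::pchisq(X2, df = df, lower.tail = FALSE)
  p <- max(p, 1e-300)
  list(X2 = X2, df = df, p = p, neglog10 = -log10(p))
}

#' Combine per-microRNA pathway p-values across microRNAs
#'
#' For each pathway, applies [combineFisher()] to the per-microRNA
#' hypergeometric p-values, giving one cross-microRNA significance per
#' pathway (the column summary of the enrichment heatmap).
#'
#' @param cells enrichment table from [enrichmentTable()].
#' @return data.frame with columns `pathway`, `n_mirs`, `X2`, `df`, `p`,
#'   `neglog10`.
#' @export
combinePathways <- function(cells) {
  out <- lapply(split(cells, cells$pathway), function(d) {
    cf <- combineFisher(d$p)
    data.frame(pathway = d$pathway[1], n_mirs = nrow(d), X2 = cf$X2,
               df = cf$df, p = cf$p, neglog10 = cf$neglog10)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$p), , drop = FALSE]
}

#' Build the enrichment heatmap matrix
#'
#' Arranges per-cell `-log10(p)` values as a microRNA-by-pathway matrix,
#' keeping only pathways whose Fisher-combined p-value is at or below
#' `alpha`, together with a per-cell significance mask at the same level.
#'
#' @param cells enrichment table from [enrichmentTable()].
#' @param combined combined table from [combinePathways()].
#' @param alpha significance level (default 0.05).
#' @return list with `matrix` (-log10 p values), `significant` (logical
#'   mask, per-cell p <= alpha) and `pathways` (retained ids).
#' @export
heatmapMatrix <- function(cells, combined, alpha = 0.05) {
  keep <- combined$pathway[combined$p <= alpha]
  cells <- cells[cells$pathway %in% keep, , drop = FALSE]
  mirs <- unique(cells$mir)
  m <- matrix(0, nrow = length(mirs), ncol = length(keep),
              dimnames = list(mirs, keep))
  sig <- matrix(FALSE, nrow = length(mirs), ncol = length(keep),
                dimnames = list(mirs, keep))
  if (nrow(cells)) {
    idx <- cbind(match(cells$mir, mirs), match(cells$pathway, keep))
    m[idx] <- -log10(pmax(cells$p, 1e-300))
    sig[idx] <- cells$p <= alpha
  }
  list(matrix = m, significant = sig, pathways = keep)
}

#' Hierarchically cluster heatmap rows
#'
#' One-way agglomerative clustering of the matrix rows (Euclidean
#' distance, average linkage) as used to order microRNAs in enrichment
#' heatmaps. Deterministic; a constant matrix is valid (all distances
#' zero).
#'
#' @param m numeric matrix with at least 2 rows.
#' @param method linkage method passed to [stats::hclust()].
#' @return list with `order` (leaf order), `labels`, `merge` and `height`
#'   from the agglomeration.
#' @export
clusterRows <- function(m, method = "average") {
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = method)
  list(order = hc$order, labels = rownames(m), merge = hc$merge,
       height = hc$height)
}

#' Rank microRNAs by AIM-pathway burden
#'
#' Orders microRNAs by how many adhesion/invasion/motility (AIM) pathways
#' they significantly target and, within that, by the summed significance
#' (-log10 p over the significant AIM pathways). Ties are broken by
#' identifier, lexicographically.
#'
#' @param cells enrichment table from [enrichmentTable()].
#' @param pathways a [PathwayCollection-class] with groups assigned.
#' @param alpha per-cell significance level (default 0.05).
#' @return data.frame with columns `mir`, `n_significant_aim`, `aim_score`,
#'   `rank`, ordered by rank.
#' @export
rankByAim <- function(cells, pathways, alpha = 0.05) {
  grp <- functionalGroups(pathways)
  aim <- names(grp)[grp == "AIM"]
  per <- lapply(split(cells, cells$mir), function(d) {
    sel <- d$pathway %in% aim & d$p <= alpha
    data.frame(mir = d$mir[1],
               n_significant_aim = sum(sel),
               aim_score = sum(-log10(pmax(d$p[sel], 1e-300))))
  })
  res <- do.call(rbind, per)
  ord <- order(-res$n_significant_aim, -res$aim_score, res$mir)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Export the pathway co-targeting network
#'
#' Edge table of significant (pathway, microRNA) associations restricted to
#' pathways targeted by at least `minMirs` microRNAs — the co-suppression
#' network of pathways altered by two or more microRNAs.
#'
#' @param cells enrichment table from [enrichmentTable()].
#' @param alpha per-cell significance level (default 0.05).
#' @param minMirs minimum number of significantly associated microRNAs for
#'   a pathway to enter the network (default 2).
#' @return data.frame with columns `pathway`, `mir`, `p`, `degree` (number
#'   of microRNAs associated with that pathway).
#' @export
pathwayNetwork <- function(cells, alpha = 0.05, minMirs = 2L) {
  sig <- cells[cells$p <= alpha, c("pathway", "mir", "p"), drop = FALSE]
  if (!nrow(sig))
    return(data.frame(pathway = character(0), mir = character(0),
                      p = numeric(0), degree = integer(0)))
  deg <- table(sig$pathway)
  keep <- names(deg)[deg >= minMirs]
  out <- sig[sig$pathway %in% keep, , drop = FALSE]
  out$degree <- as.integer(deg[out$pathway])
  out <- out[order(out$pathway, out$mir), , drop = FALSE]
  rownames(out) <- NULL
  out
}
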