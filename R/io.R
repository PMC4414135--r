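#' @include AllClasses.R panel.R
NULL

# ---- panel ------------------------------------------------------------

#' Read and write microRNA array panels
#'
#' The TSV layout is tab-separated with header
#' `mir_id  chrom  start  end  locus_label`. A GFF3 alternative is accepted
#' for coordinates (read through rtracklayer), with the identifier in the
#' `ID` attribute and the locus label in a `locus` attribute; records
#' without `locus` are treated as unlabelled. The format is chosen by file
#' extension (`.gff`, `.gff3` vs anything else).
#'
#' @param path file path.
#' @param name panel name attached to the result.
#' @return [readPanel()] returns a [MirPanel-class].
#' @export
readPanel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    if (!"ID" %in% names(mc))
      stop("GFF3 panel must carry an ID attribute per record")
    locus <- if ("locus" %in% names(mc)) mc$locus else rep("", length(gr))
    locus[is.na(locus)] <- ""
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mir_id = mc$ID,
                                                 locus = locus)
    return(mirPanel(gr, name = name))
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse panel file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("panel file is empty: ", path)
  mirPanel(df, name = name)
}

#' @rdname readPanel
#' @param panel a [MirPanel-class] to write.
#' @export
writePanel <- function(panel, path) {
  gr <- panelRanges(panel)
  df <- data.frame(mir_id = mirIds(panel),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   locus_label = unname(locusLabels(panel)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readPanel
#' @export
writePanelGFF3 <- function(panel, path) {
  gr <- panelRanges(panel)
  out <- gr
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = "oligomiR", type = "miRNA",
    ID = mirIds(panel), locus = unname(locusLabels(panel)))
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a plain-text microRNA list
#'
#' One identifier per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param datasetLabel label attached to the resulting set.
#' @return a [DifferentialMirSet-class].
#' @export
readMirList <- function(path, datasetLabel = basename(path)) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[x != "" & !startsWith(x, "#")]
  if (!length(x)) stop("no identifiers in ", path)
  differentialMirSet(x, datasetLabel = datasetLabel)
}

#' @rdname readMirList
#' @param set a [DifferentialMirSet-class]
#' @export
writeMirList <- function(set, path) {
  writeLines(mirIds(set), path)
  invisible(path)
}

# ---- pathways (GMT) ---------------------------------------------------

#' Read and write pathway collections in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated as
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. The description field
#' carries the functional-group label (`AIM`, `ICS`, `CSS`); anything else
#' (including the conventional `"na"`) maps to `unassigned`, so files from
#' other tools load cleanly. Writing stores the group as the description,
#' making the round trip lossless.
#'
#' @param path GMT file path.
#' @return [readGmt()] returns a [PathwayCollection-class].
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(utils::head(bad, 5), collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  groups <- ifelse(desc %in% c("AIM", "ICS", "CSS"), desc, "unassigned")
  names(groups) <- ids
  pathwayCollection(sets, groups = groups)
}

#' @rdname readGmt
#' @param pathways a [PathwayCollection-class] to write.
#' @export
writeGmt <- function(pathways, path) {
  ids <- pathwayIds(pathways)
  grp <- functionalGroups(pathways)
  lines <- vapply(ids, function(id)
    paste(c(id, grp[[id]], geneSets(pathways)[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# ---- target scores ----------------------------------------------------

#' Read and write microRNA target-score tables
#'
#' Tab-separated with header `mir  gene  score`; scores in `[0, 1]`. The
#' gene universe of the loaded object is the union of scored genes unless
#' `universe` is supplied.
#'
#' @param path TSV path.
#' @param universe optional explicit gene universe.
#' @return [readTargetScores()] returns a [TargetScores-class].
#' @export
readTargetScores <- function(path, universe = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("mir", "gene", "score")
  if (!all(need %in% names(df)))
    stop("target-score table needs columns mir, gene, score")
  targetScores(df, universe = universe)
}

#' @rdname readTargetScores
#' @param scores a [TargetScores-class] to write.
#' @export
writeTargetScores <- function(scores, path) {
  utils::write.table(scoreTable(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- expression -------------------------------------------------------

#' Read and write transfection expression matrices
#'
#' Probes-by-samples TSV of log2 intensities. The header row gives sample
#' labels in the form `condition:replicate` (e.g. `miR-544a:1`, `NT:2`);
#' the first column holds probe identifiers.
#'
#' @param path TSV path.
#' @return [readExpression()] returns a [TransfectionExperiment-class].
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (anyNA(m))
    stop("expression matrix contains missing values; impute before loading")
  lab <- colnames(m)
  sp <- strsplit(lab, ":", fixed = TRUE)
  if (any(vapply(sp, length, 0L) != 2L))
    stop("sample labels must have the form condition:replicate")
  transfectionExperiment(m,
    condition = vapply(sp, `[[`, "", 1L),
    replicate = as.integer(vapply(sp, `[[`, "", 2L)))
}

#' @rdname readExpression
#' @param x a [TransfectionExperiment-class] to write.
#' @export
writeExpression <- function(x, path) {
  m <- SummarizedExperiment::assay(x, "log2")
  cd <- SummarizedExperiment::colData(x)
  colnames(m) <- paste(cd$condition, cd$replicate, sep = ":")
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- survival ---------------------------------------------------------

#' Read and write survival tables
#'
#' Tab-separated with columns `id`, `time_months`, `event` (0/1) and one
#' `expr_<mir>` column per microRNA used for stratification.
#'
#' @param path TSV path.
#' @return [readSurvival()] returns a data.frame.
#' @export
readSurvival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns id, time_months, event")
  if (any(df$time_months < 0)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' @rdname readSurvival
#' @param records survival data.frame to write.
#' @export
writeSurvival <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- functional-group mapping ----------------------------------------

#' Read and write pathway functional-group mappings
#'
#' Two-column TSV with header `pathway_id  group`; groups are `AIM`, `ICS`
#' or `CSS`.
#'
#' @param path TSV path.
#' @return [readGroupMap()] returns a named character vector.
#' @export
readGroupMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!all(c("pathway_id", "group") %in% names(df)))
    stop("group map needs columns pathway_id, group")
  stats::setNames(as.character(df$group), as.character(df$pathway_id))
}

#' @rdname readGroupMap
#' @param map named character vector (names = pathway ids).
#' @export
writeGroupMap <- function(map, path) {
  utils::write.table(
    data.frame(pathway_id = names(map), group = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
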