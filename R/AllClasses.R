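#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
NULL

#' MirPanel: the assayed microRNA universe with locus annotation
#'
#' A `MirPanel` holds one record per microRNA present on a profiling array,
#' with genomic coordinates and an optional genomic-locus label (for example
#' `"14q32"` for members of the DLK1-DIO3 cluster). The panel is the sampling
#' frame for the locus-enrichment permutation null: replicate differential
#' sets are resampled from it.
#'
#' @slot ranges a [GenomicRanges::GRanges] with metadata columns `mir_id`
#'   (unique identifier) and `locus` (locus label, `""` when unassigned).
#' @slot panelName single string naming the array.
#'
#' @seealso [mirPanel()], [readPanel()], [permutationLocusTest()]
#' @export
setClass("MirPanel",
  representation(ranges = "GRanges", panelName = "character"))

setValidity("MirPanel", function(object) {
  msg <- character(0)
  gr <- object@ranges
  if (length(gr) == 0L)
    msg <- c(msg, "panel must contain at least one microRNA record")
  mc <- names(S4Vectors::mcols(gr))
  if (!all(c("mir_id", "locus") %in% mc))
    msg <- c(msg, "ranges must carry 'mir_id' and 'locus' metadata columns")
  else {
    ids <- S4Vectors::mcols(gr)$mir_id
    if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicate mir_id: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (anyNA(ids)) msg <- c(msg, "mir_id may not be NA")
  }
  if (length(object@panelName) != 1L)
    msg <- c(msg, "panelName must be a single string")
  if (length(msg)) msg else TRUE
})

#' DifferentialMirSet: microRNAs up-regulated in one dataset
#'
#' Plain container for a differential microRNA list (for example the
#' oligometastasis-up sets from a surgical or an SBRT cohort). Members must
#' belong to the companion [MirPanel-class]; that containment is checked by
#' the functions that consume both objects.
#'
#' @slot mirIds character vector of unique microRNA identifiers.
#' @slot datasetLabel single string, e.g. `"surgical"` or `"SBRT"`.
#' @slot direction fixed tag describing the contrast; defaults to
#'   `"up_in_oligometastasis"`.
#' @export
setClass("DifferentialMirSet",
  representation(mirIds = "character", datasetLabel = "character",
                 direction = "character"),
  prototype(direction = "up_in_oligometastasis"))

setValidity("DifferentialMirSet", function(object) {
  msg <- character(0)
  if (length(object@mirIds) == 0L) msg <- c(msg, "mirIds must be non-empty")
  if (anyDuplicated(object@mirIds)) msg <- c(msg, "mirIds must be unique")
  if (length(object@datasetLabel) != 1L)
    msg <- c(msg, "datasetLabel must be a single string")
  if (length(msg)) msg else TRUE
})

#' SynthConfig: parameters of the synthetic-data generator
#'
#' Bundles every knob of the planted-ground-truth simulator. Defaults mirror
#' the study conditions the pipeline is meant to emulate: a 377-microRNA
#' array with a 20-member cluster locus, differential sets of 39 microRNAs
#' enriched for the locus, duplicate transfection arrays, and survival
#' cohorts of 24 patients per expression group. See [synthConfig()] for the
#' meaning, unit and default of each slot.
#'
#' @export
setClass("SynthConfig",
  representation(
    seed = "integer",
    nArrayMirs = "integer", nLocusMirs = "integer",
    nDiff = "integer", locusEnrichmentOdds = "numeric",
    nGenes = "integer", nPathways = "integer",
    pathwaySizeRange = "integer",
    targetingConcentration = "numeric", backgroundTargetRate = "numeric",
    nProbes = "integer", nSuppressedPerMir = "integer",
    nReplicates = "integer",
    suppressionLog2fc = "numeric", noiseSd = "numeric",
    sharedFraction = "numeric",
    nPatientsPerGroup = "integer", hazardRatio = "numeric",
    censorRate = "numeric", followupHorizon = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  chk1 <- function(x, nm) if (length(slot(object, x)) != 1L ||
                              anyNA(slot(object, x)))
    paste0(nm, " must be a single non-missing value") else NULL
  for (s in setdiff(slotNames(object), "pathwaySizeRange"))
    msg <- c(msg, chk1(s, s))
  if (length(object@pathwaySizeRange) != 2L ||
      anyNA(object@pathwaySizeRange))
    msg <- c(msg, "pathwaySizeRange must be two integers (min, max)")
  if (!length(msg)) {
    if (object@nLocusMirs > object@nArrayMirs)
      msg <- c(msg, "nLocusMirs must not exceed nArrayMirs")
    if (object@nDiff > object@nArrayMirs)
      msg <- c(msg, "nDiff must not exceed nArrayMirs")
    if (object@nLocusMirs < 0L || object@nArrayMirs < 1L || object@nDiff < 1L)
      msg <- c(msg, "counts must be positive (nLocusMirs may be zero)")
    if (object@locusEnrichmentOdds < 1)
      msg <- c(msg, "locusEnrichmentOdds must be >= 1")
    for (f in c("targetingConcentration", "backgroundTargetRate",
                "sharedFraction", "censorRate")) {
      v <- slot(object, f)
      if (v < 0 || v > 1) msg <- c(msg, paste0(f, " must lie in [0, 1]"))
    }
    if (any(object@pathwaySizeRange < 2L) ||
        object@pathwaySizeRange[1] > object@pathwaySizeRange[2])
      msg <- c(msg, "pathwaySizeRange must satisfy 2 <= min <= max")
    if (object@pathwaySizeRange[2] > object@nGenes)
      msg <- c(msg, "pathway sizes cannot exceed the gene universe")
    if (object@nReplicates < 1L)
      msg <- c(msg, "nReplicates must be >= 1")
    if (object@hazardRatio <= 0) msg <- c(msg, "hazardRatio must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@followupHorizon <= 0)
      msg <- c(msg, "followupHorizon must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' TargetScores: predicted microRNA-to-gene interaction scores
#'
#' Long-format table of predicted interaction confidences in `[0, 1]`,
#' emulating the output of a sequence-based target predictor; interactions
#' scoring at or above a threshold (0.6 by default) are treated as targets.
#'
#' @slot scores data.frame with columns `mir`, `gene`, `score`.
#' @slot universe character vector: the gene universe for enrichment tests
#'   (a superset of all scored genes).
#' @export
setClass("TargetScores",
  representation(scores = "data.frame", universe = "character"))

setValidity("TargetScores", function(object) {
  msg <- character(0)
  sc <- object@scores
  if (!all(c("mir", "gene", "score") %in% names(sc)))
    msg <- c(msg, "scores needs columns mir, gene, score")
  else {
    if (any(sc$score < 0 | sc$score > 1, na.rm = TRUE) || anyNA(sc$score))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (!all(sc$gene %in% object@universe))
      msg <- c(msg, "gene universe must contain every scored gene")
  }
  if (length(msg)) msg else TRUE
})

#' PathwayCollection: gene sets with functional-group labels
#'
#' Named gene sets (KEGG-style pathways) each carrying one functional-group
#' label: `AIM` (adhesion/invasion/motility), `ICS` (intracellular
#' signaling), `CSS` (cancer-specific signaling) or `unassigned`.
#'
#' @slot sets named list of character vectors (gene identifiers); names are
#'   pathway ids.
#' @slot groups named character vector parallel to `sets`.
#' @export
setClass("PathwayCollection",
  representation(sets = "list", groups = "character"))

.FUNCTIONAL_GROUPS <- c("AIM", "ICS", "CSS", "unassigned")

setValidity("PathwayCollection", function(object) {
  msg <- character(0)
  if (length(object@sets) == 0L) msg <- c(msg, "at least one pathway required")
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "pathway ids must be unique non-empty names")
  if (any(vapply(object@sets, length, 0L) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  if (length(object@groups) != length(object@sets) ||
      !identical(names(object@groups), nm))
    msg <- c(msg, "groups must be named parallel to sets")
  else if (!all(object@groups %in% .FUNCTIONAL_GROUPS))
    msg <- c(msg, paste0("groups must be one of ",
                         paste(.FUNCTIONAL_GROUPS, collapse = "/")))
  if (length(msg)) msg else TRUE
})

#' TransfectionExperiment: log2 expression for microRNA transfections
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] for
#' probe-by-sample log2 intensity matrices from transfection experiments.
#' `colData` carries `condition` (the transfected microRNA, or the
#' non-targeting control) and `replicate`. The single assay is named
#' `"log2"`; missing values are disallowed (imputation, if any, must happen
#' before construction).
#'
#' @export
setClass("TransfectionExperiment",
  contains = "SummarizedExperiment")

setValidity("TransfectionExperiment", function(object) {
  msg <- character(0)
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  else if (anyNA(SummarizedExperiment::assay(object, "log2")))
    msg <- c(msg, "missing values are not allowed; impute before construction")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% names(cd)))
    msg <- c(msg, "colData must have 'condition' and 'replicate'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: locus-enrichment permutation test summary
#'
#' @slot locusLabel locus tested, e.g. `"14q32"`.
#' @slot observed observed locus-member count k in the differential set.
#' @slot setSize differential-set size n.
#' @slot panelLocusCount locus members on the whole panel, K.
#' @slot panelSize panel size N.
#' @slot nPerm number of permutation replicates.
#' @slot exceedCount replicates whose locus count was >= k (ties count).
#' @slot pEmpirical add-one empirical p, (exceedCount + 1) / (nPerm + 1).
#' @slot pExact exact hypergeometric upper tail P(X >= k).
#' @slot seed RNG seed used for the replicates.
#' @export
setClass("PermutationResult",
  representation(locusLabel = "character", observed = "integer",
                 setSize = "integer", panelLocusCount = "integer",
                 panelSize = "integer", nPerm = "integer",
                 exceedCount = "numeric", pEmpirical = "numeric",
                 pExact = "numeric", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (object@observed > min(object@setSize, object@panelLocusCount))
    msg <- c(msg, "observed count exceeds min(set size, panel locus count)")
  if (object@pEmpirical <= 0 || object@pEmpirical > 1)
    msg <- c(msg, "pEmpirical must lie in (0, 1]")
  if (object@exceedCount > object@nPerm)
    msg <- c(msg, "exceedCount cannot exceed nPerm")
  if (length(msg)) msg else TRUE
})

#' SamResult: per-probe SAM statistics for one contrast
#'
#' Result of [samTest()]: for each probe, the moderated relative-difference
#' statistic d, the linear-scale fold change treated/control, and a
#' permutation-based q-value (estimated false discovery rate at the probe's
#' own |d| threshold).
#'
#' @slot table data.frame with columns `probe_id`, `d`, `fold_change`,
#'   `q_value`, `called_down`.
#' @slot treated,control condition labels contrasted.
#' @slot s0 the exchangeability (fudge) constant actually used.
#' @slot nRelabelings number of balanced label permutations in the null.
#' @export
setClass("SamResult",
  representation(table = "data.frame", treated = "character",
                 control = "character", s0 = "numeric",
                 nRelabelings = "integer"))

setValidity("SamResult", function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("probe_id", "d", "fold_change", "q_value", "called_down")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table needs columns", paste(need, collapse = ", ")))
  else {
    if (any(tb$fold_change <= 0)) msg <- c(msg, "fold changes must be > 0")
    if (any(tb$q_value < 0 | tb$q_value > 1))
      msg <- c(msg, "q-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' OverlapResult: Venn pattern counts and pairwise chi-squared overlap tests
#'
#' @slot labels the set labels, in order.
#' @slot patternCounts named integer vector over the 2^k - 1 non-empty
#'   membership patterns; names join member labels with `"&"`.
#' @slot pairwise data.frame of pairwise 2x2 chi-squared results
#'   (columns `a`, `b`, `n_a`, `n_b`, `n_ab`, `chisq`, `p`).
#' @slot populationSize the population N used for the 2x2 tables (total
#'   probes detected across all arrays).
#' @export
setClass("OverlapResult",
  representation(labels = "character", patternCounts = "integer",
                 pairwise = "data.frame", populationSize = "numeric"))

#' KMCurve: Kaplan-Meier product-limit estimate
#'
#' @slot time distinct event times, strictly increasing.
#' @slot surv survival probabilities aligned to `time`, non-increasing.
#' @slot nRisk number at risk just before each event time.
#' @slot nEvent events at each time.
#' @slot censorTimes censoring times (for tick marks).
#' @slot nSubjects cohort size.
#' @export
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "integer",
                 nEvent = "integer", censorTimes = "numeric",
                 nSubjects = "integer"))

setValidity("KMCurve", function(object) {
  msg <- character(0)
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly increasing")
  if (any(diff(object@surv) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (any(object@surv < 0 | object@surv > 1))
    msg <- c(msg, "survival must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LogRankResult: two-group log-rank test
#'
#' @slot statistic chi-squared statistic (1 degree of freedom).
#' @slot df degrees of freedom (always 1 for two groups).
#' @slot p upper-tail p-value.
#' @export
setClass("LogRankResult",
  representation(statistic = "numeric", df = "integer", p = "numeric"))

setValidity("LogRankResult", function(object) {
  if (object@statistic < 0) "statistic must be >= 0" else TRUE
})
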