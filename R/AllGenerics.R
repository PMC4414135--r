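#' @include AllClasses.R
NULL

#' @export
setGeneric("mirIds", function(x) standardGeneric("mirIds"))

#' @export
setGeneric("locusLabels", function(x) standardGeneric("locusLabels"))

#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @export
setGeneric("locusCount", function(x, locus) standardGeneric("locusCount"))

#' @export
setGeneric("datasetLabel", function(x) standardGeneric("datasetLabel"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @export
setGeneric("functionalGroups", function(x) standardGeneric("functionalGroups"))

#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @export
setGeneric("samTable", function(x) standardGeneric("samTable"))

#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))

#' @export
setGeneric("pExact", function(x) standardGeneric("pExact"))

#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))

#' @export
setGeneric("pairwiseTests", function(x) standardGeneric("pairwiseTests"))

#' @export
setGeneric("quantileNormalize", function(x, ...)
  standardGeneric("quantileNormalize"))

#' @export
setGeneric("survivalAt", function(curve, t) standardGeneric("survivalAt"))
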