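#' @include AllClasses.R AllGenerics.R panel.R enrichment.R expression.R
NULL

#' Configure the synthetic-data generator
#'
#' Builds a [SynthConfig-class] describing every input the pipeline
#' consumes, with planted, recoverable structure. Defaults emulate the
#' study conditions the pipeline targets: a 377-microRNA array card with a
#' 20-member cluster locus, 39-microRNA differential sets with locus
#' enrichment odds tuned so that ~14 of 39 fall in the locus, duplicate
#' transfection arrays, per-microRNA suppressed sets with 31% of the union
#' shared by two or more microRNAs, and survival cohorts of 24 patients
#' per group with a low-vs-high hazard ratio of 3 (baseline hazard set so
#' that ~60% of high expressors are recurrence-free at 60 months).
#'
#' Every generator derives its RNG stream from `seed` plus a fixed
#' per-stage offset, so the same seed and config give bit-identical
#' fixtures, stage by stage.
#'
#' @param seed integer RNG seed.
#' @param nArrayMirs microRNAs on the array (default 377).
#' @param nLocusMirs of these, members of the labelled locus (default 20).
#' @param nDiff differential-set size (default 39).
#' @param locusEnrichmentOdds odds multiplier >= 1 for a locus member
#'   entering the differential set (default 17, giving an expected locus
#'   count of ~14 in the default geometry).
#' @param nGenes gene-universe size (default 4000).
#' @param nPathways number of pathways (default 20).
#' @param pathwaySizeRange (min, max) pathway sizes (default 100-200;
#'   sized so null pathway overlaps are large enough that the discrete
#'   hypergeometric tail is effectively continuous).
#' @param targetingConcentration fraction of a planted microRNA's
#'   above-threshold targets drawn from its designated pathways (default
#'   0.5).
#' @param backgroundTargetRate probability that a background
#'   (microRNA, gene) pair scores above the 0.6 target threshold (default
#'   0.3).
#' @param nProbes expression probes (default 2000).
#' @param nSuppressedPerMir planted suppressed probes per microRNA
#'   (default 150).
#' @param nReplicates arrays per condition (default 2, i.e. duplicates).
#' @param suppressionLog2fc planted mean down-shift on the log2 scale for
#'   suppressed probes (default 1, a 2-fold suppression).
#' @param noiseSd per-probe Gaussian noise SD on the log2 scale (default
#'   0.25).
#' @param sharedFraction fraction of the suppressed-probe union shared by
#'   two or more planted microRNAs (default 0.31).
#' @param nPatientsPerGroup survival cohort size per expression group
#'   (default 24).
#' @param hazardRatio low-vs-high group hazard ratio (default 3).
#' @param censorRate fraction subject to independent early censoring
#'   (default 0.2); administrative censoring applies at
#'   `followupHorizon` regardless.
#' @param followupHorizon follow-up horizon in months (default 72).
#' @return a validated [SynthConfig-class].
#' @export
synthConfig <- function(seed = 1L,
                        nArrayMirs = 377L, nLocusMirs = 20L,
                        nDiff = 39L, locusEnrichmentOdds = 17,
                        nGenes = 4000L, nPathways = 20L,
                        pathwaySizeRange = c(100L, 200L),
                        targetingConcentration = 0.5,
                        backgroundTargetRate = 0.3,
                        nProbes = 2000L, nSuppressedPerMir = 150L,
                        nReplicates = 2L,
                        suppressionLog2fc = 1, noiseSd = 0.25,
                        sharedFraction = 0.31,
                        nPatientsPerGroup = 24L, hazardRatio = 3,
                        censorRate = 0.2, followupHorizon = 72) {
  new("SynthConfig",
      seed = as.integer(seed),
      nArrayMirs = as.integer(nArrayMirs),
      nLocusMirs = as.integer(nLocusMirs),
      nDiff = as.integer(nDiff),
      locusEnrichmentOdds = as.numeric(locusEnrichmentOdds),
      nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      targetingConcentration = as.numeric(targetingConcentration),
      backgroundTargetRate = as.numeric(backgroundTargetRate),
      nProbes = as.integer(nProbes),
      nSuppressedPerMir = as.integer(nSuppressedPerMir),
      nReplicates = as.integer(nReplicates),
      suppressionLog2fc = as.numeric(suppressionLog2fc),
      noiseSd = as.numeric(noiseSd),
      sharedFraction = as.numeric(sharedFraction),
      nPatientsPerGroup = as.integer(nPatientsPerGroup),
      hazardRatio = as.numeric(hazardRatio),
      censorRate = as.numeric(censorRate),
      followupHorizon = as.numeric(followupHorizon))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig (seed ", object@seed, "): ", object@nArrayMirs,
      " array miRs / ", object@nLocusMirs, " in locus; ", object@nDiff,
      "-miR differential sets; ", object@nGenes, " genes, ",
      object@nPathways, " pathways; ", object@nProbes, " probes x ",
      object@nReplicates, " replicates; ", 2 * object@nPatientsPerGroup,
      " patients\n", sep = "")
})

.LOCUS_LABEL <- "14q32"

#' Simulate an array panel
#'
#' Generates `nArrayMirs` uniquely identified microRNAs of which exactly
#' `nLocusMirs` (a random subset — the identifier-to-locus assignment
#' changes with the seed) carry the locus label. Locus members are placed
#' on one contiguous window of chromosome 14; the rest are scattered over
#' the other autosomes.
#'
#' @param cfg a [SynthConfig-class].
#' @return a [MirPanel-class].
#' @export
simulatePanel <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  set.seed(cfg@seed)
  n <- cfg@nArrayMirs
  ids <- sprintf("syn-miR-%03d", seq_len(n))
  inLocus <- rep(FALSE, n)
  inLocus[sample.int(n, cfg@nLocusMirs)] <- TRUE
  chrom <- character(n); start <- integer(n)
  # contiguous locus window on 14q
  start[inLocus] <- 101e6 + 2000L * seq_len(sum(inLocus))
  chrom[inLocus] <- "chr14"
  others <- paste0("chr", setdiff(1:22, 14))
  chrom[!inLocus] <- sample(others, sum(!inLocus), replace = TRUE)
  start[!inLocus] <- sample.int(1e8, sum(!inLocus))
  mirPanel(data.frame(mir_id = ids, chrom = chrom, start = start,
                      end = start + 21L,
                      locus_label = ifelse(inLocus, .LOCUS_LABEL, "")),
           name = sprintf("synthetic_panel_seed%d", cfg@seed))
}

#' Simulate a differential microRNA set with locus enrichment
#'
#' Samples `nDiff` microRNAs from the panel without replacement, with
#' per-microRNA weights equal to `locusEnrichmentOdds` for locus members
#' and 1 otherwise. Sampling is by sequential draws with renormalized
#' weights (base R's weighted [sample()] without replacement), so odds of
#' 1 reduce exactly to simple random sampling.
#'
#' @param panel a [MirPanel-class].
#' @param cfg a [SynthConfig-class].
#' @param datasetLabel label for the resulting set.
#' @return a [DifferentialMirSet-class].
#' @export
simulateDifferential <- function(panel, cfg, datasetLabel = "synthetic") {
  if (cfg@nDiff > length(panel))
    stop("nDiff exceeds panel size")
  set.seed(cfg@seed + 1L)
  lab <- locusLabels(panel)
  w <- ifelse(lab == .LOCUS_LABEL, cfg@locusEnrichmentOdds, 1)
  picked <- sample(mirIds(panel), cfg@nDiff, prob = w)
  differentialMirSet(picked, datasetLabel = datasetLabel)
}

#' Construct a differential set with an exact locus count
#'
#' Deterministic-composition fixture: exactly `kLocus` locus members and
#' `nTotal - kLocus` others, drawn uniformly within each stratum. Used to
#' reproduce printed configurations such as 14-of-39 or 5-of-29 exactly.
#'
#' @param panel a [MirPanel-class].
#' @param locus locus label.
#' @param kLocus locus members in the set.
#' @param nTotal set size.
#' @param seed RNG seed.
#' @param datasetLabel label for the resulting set.
#' @return a [DifferentialMirSet-class].
#' @export
plantDifferentialSet <- function(panel, locus, kLocus, nTotal, seed = 1L,
                                 datasetLabel = "fixture") {
  lab <- locusLabels(panel)
  inL <- names(lab)[lab == locus]
  outL <- names(lab)[lab != locus]
  if (kLocus > length(inL) || (nTotal - kLocus) > length(outL))
    stop("requested composition exceeds panel strata")
  set.seed(seed)
  differentialMirSet(c(sample(inL, kLocus),
                       sample(outL, nTotal - kLocus)),
                     datasetLabel = datasetLabel)
}

#' Simulate a pathway collection
#'
#' Draws `nPathways` gene subsets of the universe with sizes uniform in
#' `pathwaySizeRange` (overlap between pathways allowed) and cycles the
#' functional-group labels AIM, ICS, CSS so the label counts differ by at
#' most one.
#'
#' @param cfg a [SynthConfig-class].
#' @return a [PathwayCollection-class]; the gene universe is
#'   `g0001 ... g<nGenes>`.
#' @export
simulatePathways <- function(cfg) {
  set.seed(cfg@seed + 2L)
  genes <- sprintf("g%04d", seq_len(cfg@nGenes))
  sizeChoices <- seq(cfg@pathwaySizeRange[1], cfg@pathwaySizeRange[2])
  sizes <- sizeChoices[sample.int(length(sizeChoices), cfg@nPathways,
                                  replace = TRUE)]
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PW%02d", seq_len(cfg@nPathways))
  groups <- stats::setNames(
    rep(c("AIM", "ICS", "CSS"), length.out = cfg@nPathways), names(sets))
  pathwayCollection(sets, groups = groups)
}

#' Gene universe implied by a config
#' @param cfg a [SynthConfig-class].
#' @return character vector `g0001 ... g<nGenes>`.
#' @export
synthGeneUniverse <- function(cfg) sprintf("g%04d", seq_len(cfg@nGenes))

#' Simulate microRNA target scores with planted pathway concentration
#'
#' Scores every (microRNA, gene) pair in `[0, 1)`. Background pairs score
#' above the 0.6 target threshold with probability
#' `backgroundTargetRate`, uniformly within `[0.6, 1)` when above and
#' `[0, 0.6)` when below — the simplest background making the downstream
#' hypergeometric calibration exact. For microRNAs named in `planted`,
#' a `targetingConcentration` fraction of the above-threshold targets is
#' drawn from the genes of the designated pathways (capped at the size of
#' that designated gene pool); at concentration 0 a planted microRNA is
#' indistinguishable from background.
#'
#' @param mirs character vector of microRNA identifiers to score.
#' @param pathways a [PathwayCollection-class].
#' @param cfg a [SynthConfig-class].
#' @param planted named list: microRNA id -> character vector of
#'   designated pathway ids. Unknown pathway ids are an error.
#' @return a [TargetScores-class] over the config's gene universe.
#' @export
simulateTargetScores <- function(mirs, pathways, cfg,
                                 planted = list()) {
  unknown <- setdiff(unique(unlist(planted)), pathwayIds(pathways))
  if (length(unknown))
    stop("planted designation names unknown pathway(s): ",
         paste(unknown, collapse = ", "))
  set.seed(cfg@seed + 3L)
  genes <- synthGeneUniverse(cfg)
  nG <- length(genes)
  rate <- cfg@backgroundTargetRate
  conc <- cfg@targetingConcentration
  out <- vector("list", length(mirs))
  for (i in seq_along(mirs)) {
    m <- mirs[i]
    above <- logical(nG)
    if (!is.null(planted[[m]]) && conc > 0) {
      pool <- unique(unlist(geneSets(pathways)[planted[[m]]]))
      poolIdx <- match(pool, genes)
      nAbove <- stats::rbinom(1L, nG, rate)
      nIn <- min(round(conc * nAbove), length(poolIdx))
      nOut <- min(nAbove - nIn, nG - length(poolIdx))
      above[sample(poolIdx, nIn)] <- TRUE
      above[sample(setdiff(seq_len(nG), poolIdx), nOut)] <- TRUE
    } else {
      above <- stats::runif(nG) < rate
    }
    score <- numeric(nG)
    score[above] <- 0.6 + 0.4 * stats::runif(sum(above))
    score[!above] <- 0.6 * stats::runif(sum(!above))
    out[[i]] <- data.frame(mir = m, gene = genes, score = score)
  }
  targetScores(do.call(rbind, out), universe = genes)
}

#' Simulate planted suppressed probe sets
#'
#' Draws per-microRNA suppressed probe sets whose union has approximately
#' `sharedFraction` of its members in two or more sets: each union member
#' is shared (by 2-4 microRNAs, uniformly) with probability
#' `sharedFraction` and private to one microRNA otherwise. The union size
#' is set so the expected per-microRNA set size equals
#' `nSuppressedPerMir`.
#'
#' @param cfg a [SynthConfig-class].
#' @param mirs names of the planted microRNAs (default four synthetic
#'   cluster members).
#' @return named list of probe-id sets.
#' @export
simulateSuppressedSets <- function(cfg, mirs = paste0("mir", 1:4)) {
  k <- length(mirs)
  if (k < 2L) stop("need at least 2 planted microRNAs")
  set.seed(cfg@seed + 4L)
  s <- cfg@sharedFraction
  meanMult <- (1 - s) * 1 + s * mean(2:min(4, k))
  unionSize <- round(k * cfg@nSuppressedPerMir / meanMult)
  unionSize <- min(unionSize, cfg@nProbes)
  probes <- sprintf("probe_%04d", seq_len(cfg@nProbes))
  members <- sample(probes, unionSize)
  sets <- stats::setNames(rep(list(character(0)), k), mirs)
  for (p in members) {
    if (stats::runif(1) < s) {
      multChoices <- 2:min(4, k)
      mult <- multChoices[sample.int(length(multChoices), 1L)]
      owners <- sample(mirs, mult)
    } else {
      owners <- sample(mirs, 1L)
    }
    for (o in owners) sets[[o]] <- c(sets[[o]], p)
  }
  sets
}

#' Simulate a transfection expression experiment
#'
#' Log2-scale probes-by-samples matrix with `nReplicates` columns per
#' condition (each planted microRNA plus a non-targeting control `"NT"`).
#' Probe baselines are N(8, 1.5); planted probes are shifted down by
#' `suppressionLog2fc` in their microRNA's columns; homoscedastic
#' Gaussian noise of SD `noiseSd` is added everywhere (none when
#' `noiseSd = 0`, making recovery exact).
#'
#' @param cfg a [SynthConfig-class].
#' @param planted named list microRNA -> suppressed probe ids (e.g. from
#'   [simulateSuppressedSets()]); may be empty-set lists for a null
#'   experiment.
#' @return a [TransfectionExperiment-class].
#' @export
simulateTransfection <- function(cfg, planted) {
  set.seed(cfg@seed + 5L)
  probes <- sprintf("probe_%04d", seq_len(cfg@nProbes))
  bad <- setdiff(unique(unlist(planted)), probes)
  if (length(bad))
    stop("planted probe(s) not on the array: ",
         paste(utils::head(bad, 5), collapse = ", "))
  conds <- c(names(planted), "NT")
  nc <- length(conds) * cfg@nReplicates
  baseline <- stats::rnorm(cfg@nProbes, mean = 8, sd = 1.5)
  m <- matrix(rep(baseline, nc), nrow = cfg@nProbes,
              dimnames = list(probes, NULL))
  condition <- rep(conds, each = cfg@nReplicates)
  replicate <- rep(seq_len(cfg@nReplicates), times = length(conds))
  for (j in seq_len(nc)) {
    cj <- condition[j]
    if (cj != "NT" && length(planted[[cj]]))
      m[planted[[cj]], j] <- m[planted[[cj]], j] - cfg@suppressionLog2fc
  }
  if (cfg@noiseSd > 0)
    m <- m + matrix(stats::rnorm(length(m), sd = cfg@noiseSd), nrow(m))
  transfectionExperiment(m, condition = condition, replicate = replicate)
}

#' Simulate a survival cohort
#'
#' Generates `2 * nPatientsPerGroup` patients with per-microRNA
#' expression drawn around two well-separated group means, so the
#' mean-expression median split reproduces the intended assignment; the
#' realized split defines the groups used for event generation, keeping
#' split and hazard consistent by construction. Event times are
#' exponential: the high-expression group at baseline rate
#' `-log(0.6) / 60` per month (~60% event-free at five years) and the
#' low-expression group at `hazardRatio` times that. Censoring is
#' administrative at `followupHorizon`, and a `censorRate` fraction of
#' patients drops out (censored, no event) at an independent uniform
#' time before the horizon, reproducing the tick pattern of clinical KM
#' curves; at rate 1 the whole cohort is censored.
#'
#' @param cfg a [SynthConfig-class].
#' @param mirs microRNA names for the expression columns (default four
#'   synthetic cluster members).
#' @return data.frame with columns `id`, `time_months`, `event`,
#'   `expr_<mir>` for each microRNA, plus a `true_group` column recording
#'   the planted assignment.
#' @export
simulateSurvival <- function(cfg, mirs = paste0("mir", 1:4)) {
  set.seed(cfg@seed + 6L)
  nPer <- cfg@nPatientsPerGroup
  n <- 2L * nPer
  intended <- rep(c("high", "low"), each = nPer)
  mu <- ifelse(intended == "high", 8, 6)
  expr <- sapply(seq_along(mirs), function(j)
    stats::rnorm(n, mean = mu, sd = 0.5))
  colnames(expr) <- paste0("expr_", mirs)
  score <- rowMeans(expr)
  group <- ifelse(score > stats::median(score), "high", "low")
  rateHigh <- -log(0.6) / 60
  rate <- ifelse(group == "high", rateHigh, rateHigh * cfg@hazardRatio)
  eventTime <- stats::rexp(n, rate = rate)
  # a censorRate fraction drops out at a uniform time with no event (so
  # censorRate = 1 yields an all-censored cohort); everyone else is
  # observed to the event or administratively censored at the horizon
  early <- stats::runif(n) < cfg@censorRate
  time <- pmin(eventTime, cfg@followupHorizon)
  event <- as.integer(eventTime <= cfg@followupHorizon)
  time[early] <- stats::runif(sum(early), 0, cfg@followupHorizon)
  event[early] <- 0L
  data.frame(id = sprintf("pt%02d", seq_len(n)),
             time_months = time,
             event = event,
             expr, true_group = group,
             check.names = FALSE)
}

#' Simulate the full input bundle with ground truth
#'
#' Generates every pipeline input from one config and, when `dir` is
#' given, writes them to disk together with a `ground_truth.json` sidecar
#' recording all planted structure (locus membership, planted microRNAs
#' and their designated pathways, the pathway designated to all planted
#' microRNAs, the suppressed probe sets, and the survival design), so
#' every downstream stage can be scored for recovery.
#'
#' The bundle plants: a surgical-like 39-microRNA set drawn with the
#' config's locus odds and an SBRT-like 29-microRNA set at lower odds;
#' four planted microRNAs taken from the locus members of the
#' surgical-like set, the first of which ("top" microRNA) is designated
#' every AIM pathway while the other three share a fixed trio of AIM
#' pathways (so one pathway is co-targeted by all four); matched
#' suppressed probe sets; and a survival cohort over the four planted
#' microRNAs.
#'
#' @param cfg a [SynthConfig-class].
#' @param dir optional output directory (created if needed).
#' @return invisibly, a list with all in-memory objects and the
#'   `groundTruth` list.
#' @export
simulateBundle <- function(cfg, dir = NULL) {
  panel <- simulatePanel(cfg)
  surgical <- simulateDifferential(panel, cfg, datasetLabel = "surgical")
  sbrtCfg <- cfg
  sbrtCfg@seed <- cfg@seed + 101L
  sbrtCfg@nDiff <- 29L
  sbrtCfg@locusEnrichmentOdds <- 4.1
  sbrt <- simulateDifferential(panel, sbrtCfg, datasetLabel = "SBRT")

  lab <- locusLabels(panel)
  surgLocus <- mirIds(surgical)[lab[mirIds(surgical)] == .LOCUS_LABEL]
  if (length(surgLocus) < 4L)
    stop("fewer than 4 locus members in the surgical-like set; ",
         "increase locusEnrichmentOdds")
  plantedMirs <- surgLocus[1:4]
  topMir <- plantedMirs[1]

  pathways <- simulatePathways(cfg)
  grp <- functionalGroups(pathways)
  aim <- names(grp)[grp == "AIM"]
  if (!length(aim))
    stop("the bundle needs at least one AIM pathway; increase nPathways")
  coAim <- aim[seq_len(min(3L, length(aim)))]
  designation <- c(
    stats::setNames(list(aim), topMir),
    stats::setNames(rep(list(coAim), 3L), plantedMirs[2:4]))
  sharedPathway <- aim[1]
  scores <- simulateTargetScores(surgLocus, pathways, cfg,
                                 planted = designation)

  suppressed <- simulateSuppressedSets(cfg, mirs = plantedMirs)
  expr <- simulateTransfection(cfg, planted = suppressed)
  surv <- simulateSurvival(cfg, mirs = plantedMirs)

  groundTruth <- list(
    seed = cfg@seed,
    locus = .LOCUS_LABEL,
    panel_locus_mirs = names(lab)[lab == .LOCUS_LABEL],
    planted_mirs = plantedMirs,
    top_mir = topMir,
    designation = designation,
    shared_pathway = sharedPathway,
    suppressed_sets = suppressed,
    hazard_ratio = cfg@hazardRatio,
    survival_groups = stats::setNames(surv$true_group, surv$id))

  bundle <- list(config = cfg, panel = panel, surgical = surgical,
                 sbrt = sbrt, pathways = pathways, scores = scores,
                 suppressed = suppressed, expression = expr,
                 survival = surv, groundTruth = groundTruth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writePanel(panel, file.path(dir, "panel.tsv"))
    writeMirList(surgical, file.path(dir, "differential_surgical.txt"))
    writeMirList(sbrt, file.path(dir, "differential_sbrt.txt"))
    writeGmt(pathways, file.path(dir, "pathways.gmt"))
    writeTargetScores(scores, file.path(dir, "target_scores.tsv"))
    writeExpression(expr, file.path(dir, "expression.tsv"))
    writeSurvival(surv[, setdiff(names(surv), "true_group")],
                  file.path(dir, "survival.tsv"))
    jsonlite::write_json(groundTruth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bundle)
}
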