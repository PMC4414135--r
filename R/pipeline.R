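#' @include AllClasses.R synthetic.R panel.R enrichment.R expression.R
#'   survival.R io.R
NULL

.CONFIG_DEFAULTS <- list(
  seed = 1L,
  n_perm = 1e6,        # permutation replicates for the locus test
  tau = 0.6,           # target-score threshold
  alpha = 0.05,        # enrichment significance level
  fdr = 0.05,          # SAM false discovery rate
  fc = 1.4,            # suppressed-probe fold-change gate
  fc_pathway = 2.0,    # stricter gate feeding pathway analysis
  min_mirs = 2L,       # network inclusion threshold
  locus = "14q32",
  survival_mirs = NULL,  # NULL: the bundle's planted microRNAs
  synth = list(),        # overrides passed to synthConfig()
  inputs = NULL)         # NULL: simulate; else named list of paths

.INPUT_KEYS <- c("panel", "differential", "pathways", "target_scores",
                 "expression", "survival")

#' Default pipeline configuration
#'
#' Returns the full default configuration: permutation count 1e6, target
#' threshold 0.6, enrichment alpha 0.05, SAM FDR 5% with a 1.4-fold gate,
#' a 2.0-fold gate for the pathway input, network inclusion at 2
#' microRNAs, and the `14q32` locus. With `inputs = NULL` the synthetic
#' bundle is generated in place.
#'
#' @param ... overrides of individual keys.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  over <- list(...)
  cfg <- .CONFIG_DEFAULTS
  cfg[names(over)] <- over
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every key and range and returns the complete list of
#' violations (not just the first). Unknown keys are violations, so
#' typos cannot silently fall back to defaults.
#'
#' @param config named list (see [defaultRunConfig()]).
#' @return list with `config` (defaults merged in) and `errors`
#'   (character vector, empty when valid).
#' @export
validateRunConfig <- function(config) {
  errors <- character(0)
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  cfg <- .CONFIG_DEFAULTS
  known <- intersect(names(config), names(.CONFIG_DEFAULTS))
  cfg[known] <- config[known]

  chkRange <- function(key, lo, hi, loOpen = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lo || v > hi || (loOpen && v == lo))
      paste0(key, " must be a number in ", if (loOpen) "(" else "[",
             lo, ", ", hi, "]; got ", deparse(v))
    else NULL
  }
  errors <- c(errors,
              chkRange("tau", 0, 1),
              chkRange("alpha", 0, 1, loOpen = TRUE),
              chkRange("fdr", 0, 1),
              chkRange("fc", 1, Inf),
              chkRange("fc_pathway", 1, Inf),
              chkRange("min_mirs", 1, Inf),
              chkRange("n_perm", 1, Inf),
              chkRange("seed", -2^31, 2^31))
  if (!is.character(cfg$locus) || length(cfg$locus) != 1L ||
      !nzchar(cfg$locus))
    errors <- c(errors, "locus must be a non-empty string")
  if (!is.null(cfg$survival_mirs) && !is.character(cfg$survival_mirs))
    errors <- c(errors, "survival_mirs must be a character vector or NULL")
  if (!is.list(cfg$synth))
    errors <- c(errors, "synth must be a list of synthConfig overrides")
  if (!is.null(cfg$inputs)) {
    if (!is.list(cfg$inputs)) {
      errors <- c(errors, "inputs must be a named list of paths")
    } else {
      miss <- setdiff(.INPUT_KEYS, names(cfg$inputs))
      if (length(miss))
        errors <- c(errors, paste0("inputs missing key(s): ",
                                   paste(miss, collapse = ", ")))
      for (k in intersect(names(cfg$inputs), .INPUT_KEYS)) {
        for (p in unlist(cfg$inputs[[k]]))
          if (!file.exists(p))
            errors <- c(errors,
                        paste0("inputs$", k, ": no such file: ", p))
      }
    }
  }
  list(config = cfg, errors = errors)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the keys of [defaultRunConfig()].
#' @return validated config list; all violations are reported together
#'   on failure.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  v <- validateRunConfig(raw)
  if (length(v$errors))
    stop("invalid configuration:\n  ",
         paste(v$errors, collapse = "\n  "))
  v$config
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> locus enrichment -> pathway
#' co-targeting -> differential suppression -> co-repression overlap ->
#' survival as one configured, seeded run. Identical config and seed give
#' identical outputs. A stage failure stops its dependents but completed
#' outputs are kept and the failure is recorded in the report.
#'
#' @param config validated configuration list ([defaultRunConfig()] /
#'   [readRunConfig()]).
#' @param outDir output directory (created if needed).
#' @return the run report (invisibly); also written as `report.json` and
#'   `report.txt` under `outDir`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  v <- validateRunConfig(config)
  if (length(v$errors))
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  cfgHash <- unname(tools::md5sum(cfgPath))

  report <- list(
    provenance = list(
      package = "oligomiR",
      version = as.character(utils::packageVersion("oligomiR")),
      seed = cfg$seed, config_hash = cfgHash,
      config_file = cfgPath,
      timestamp = format(Sys.time(), tz = "UTC"),
      thresholds = cfg[c("n_perm", "tau", "alpha", "fdr", "fc",
                         "fc_pathway", "min_mirs")]),
    stages = list(), warnings = character(0))
  fail <- function(stage, e) {
    report$stages[[stage]] <<- list(status = "failed",
                                    error = conditionMessage(e))
  }
  skip <- function(stage, why) {
    report$stages[[stage]] <<- list(status = "skipped", reason = why)
  }
  done <- function(stage, outputs, summary = list()) {
    report$stages[[stage]] <<- list(status = "ok", outputs = outputs,
                                    summary = summary)
  }

  ## stage 1: inputs -----------------------------------------------------
  bundle <- tryCatch({
    if (is.null(cfg$inputs)) {
      scfg <- do.call(synthConfig, c(list(seed = cfg$seed), cfg$synth))
      b <- simulateBundle(scfg, dir = file.path(outDir, "inputs"))
      done("inputs",
           list.files(file.path(outDir, "inputs"), full.names = TRUE),
           list(source = "simulated"))
      b
    } else {
      inp <- cfg$inputs
      panel <- readPanel(inp$panel)
      diffs <- lapply(inp$differential, readMirList)
      pathways <- readGmt(inp$pathways)
      scores <- readTargetScores(inp$target_scores)
      expr <- readExpression(inp$expression)
      surv <- readSurvival(inp$survival)
      done("inputs", unlist(inp, use.names = FALSE),
           list(source = "loaded"))
      list(panel = panel, surgical = diffs[[1]],
           sbrt = if (length(diffs) > 1) diffs[[2]] else NULL,
           pathways = pathways, scores = scores, expression = expr,
           survival = surv, groundTruth = NULL)
    }
  }, error = function(e) { fail("inputs", e); NULL })
  if (is.null(bundle)) {
    for (s in c("locus", "enrichment", "differential_expression",
                "overlap", "survival"))
      skip(s, "inputs stage failed")
    return(.finishReport(report, outDir))
  }

  ## stage 2: locus enrichment ------------------------------------------
  locusRes <- tryCatch({
    sets <- Filter(Negate(is.null),
                   list(bundle$surgical, bundle$sbrt))
    rows <- lapply(sets, function(s) {
      pr <- permutationLocusTest(s, bundle$panel, cfg$locus,
                                 nPerm = cfg$n_perm, seed = cfg$seed)
      fr <- locusFraction(s, bundle$panel, cfg$locus)
      data.frame(dataset = datasetLabel(s), k = pr@observed,
                 n = pr@setSize, percent = fr$percent,
                 K = pr@panelLocusCount, N = pr@panelSize,
                 n_perm = pr@nPerm, exceed = pr@exceedCount,
                 p_empirical = pr@pEmpirical, p_exact = pr@pExact)
    })
    tab <- do.call(rbind, rows)
    f <- .writeTsv(tab, file.path(outDir, "locus_tests.tsv"))
    done("locus", f, list(datasets = tab$dataset,
                          p_empirical = tab$p_empirical))
    tab
  }, error = function(e) { fail("locus", e); NULL })

  ## stage 3: pathway co-targeting --------------------------------------
  enrich <- tryCatch({
    mirsScored <- unique(scoreTable(bundle$scores)$mir)
    targets <- thresholdTargets(bundle$scores, tau = cfg$tau)
    cells <- enrichmentTable(targets, bundle$pathways,
                             geneUniverse(bundle$scores))
    combined <- combinePathways(cells)
    hm <- heatmapMatrix(cells, combined, alpha = cfg$alpha)
    ranking <- rankByAim(cells, bundle$pathways, alpha = cfg$alpha)
    net <- pathwayNetwork(cells, alpha = cfg$alpha,
                          minMirs = cfg$min_mirs)
    fs <- c(.writeTsv(cells, file.path(outDir, "enrichment_cells.tsv")),
            .writeTsv(combined,
                      file.path(outDir, "enrichment_combined.tsv")),
            .writeTsv(data.frame(mir = rownames(hm$matrix),
                                 hm$matrix, check.names = FALSE),
                      file.path(outDir, "heatmap_matrix.tsv")),
            .writeTsv(ranking, file.path(outDir, "aim_ranking.tsv")),
            .writeTsv(net, file.path(outDir, "pathway_network.tsv")))
    done("enrichment", fs,
         list(n_mirs = length(mirsScored),
              n_significant_pathways = length(hm$pathways),
              top_mir = if (nrow(ranking)) ranking$mir[1] else NA))
    list(cells = cells, combined = combined, ranking = ranking,
         network = net)
  }, error = function(e) { fail("enrichment", e); NULL })

  ## stage 4: differential suppression ----------------------------------
  de <- tryCatch({
    norm <- quantileNormalize(bundle$expression)
    conds <- setdiff(unique(conditions(norm)), "NT")
    supp <- list(); pathIn <- list(); rows <- list()
    for (cond in conds) {
      res <- samTest(norm, treated = cond, control = "NT",
                     fdr = cfg$fdr)
      supp[[cond]] <- selectSuppressed(res, fcMin = cfg$fc,
                                       fdrMax = cfg$fdr)
      pathIn[[cond]] <- selectPathwayInput(res, fcMin = cfg$fc_pathway,
                                           fdrMax = cfg$fdr)
      rows[[cond]] <- data.frame(mir_id = cond,
                                 probe_id = supp[[cond]])
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    f <- .writeTsv(tab, file.path(outDir, "suppressed_sets.tsv"))
    done("differential_expression", f,
         list(n_suppressed = vapply(supp, length, 0L)))
    list(suppressed = supp, pathwayInput = pathIn)
  }, error = function(e) { fail("differential_expression", e); NULL })

  ## stage 5: co-repression overlap -------------------------------------
  overlap <- if (is.null(de)) {
    skip("overlap", "differential_expression stage failed"); NULL
  } else tryCatch({
    N <- nrow(bundle$expression)
    ov <- overlapAnalysis(de$suppressed, N = N)
    cnt <- patternCounts(ov)
    fs <- c(.writeTsv(data.frame(pattern = names(cnt),
                                 count = as.integer(cnt)),
                      file.path(outDir, "venn_counts.tsv")),
            .writeTsv(pairwiseTests(ov),
                      file.path(outDir, "overlap_tests.tsv")))
    done("overlap", fs,
         list(population = N,
              shared_fraction = sharedFraction(ov)))
    ov
  }, error = function(e) { fail("overlap", e); NULL })

  ## stage 6: survival ---------------------------------------------------
  survRes <- tryCatch({
    mirs <- cfg$survival_mirs
    if (is.null(mirs)) {
      ex <- grep("^expr_", names(bundle$survival), value = TRUE)
      mirs <- sub("^expr_", "", ex)
    }
    st <- survivalStratified(bundle$survival, mirs)
    curveTab <- do.call(rbind, lapply(names(st$curves), function(g) {
      cv <- st$curves[[g]]
      if (!length(cv@time))
        return(data.frame(group = g, time = 0, survival = 1,
                          at_risk = cv@nSubjects))
      data.frame(group = g, time = cv@time, survival = cv@surv,
                 at_risk = cv@nRisk)
    }))
    f1 <- .writeTsv(curveTab, file.path(outDir, "km_curves.tsv"))
    f2 <- file.path(outDir, "logrank.json")
    jsonlite::write_json(
      list(statistic = st$logrank@statistic, df = st$logrank@df,
           p = st$logrank@p,
           survival_at_60m = lapply(st$curves, survivalAt, t = 60)),
      f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    done("survival", c(f1, f2),
         list(logrank_p = st$logrank@p,
              survival_at_60m_high = survivalAt(st$curves$high, 60),
              survival_at_60m_low = survivalAt(st$curves$low, 60)))
    st
  }, error = function(e) { fail("survival", e); NULL })

  report$results <- list(locus = locusRes,
                         enrichment = enrich,
                         de = de, overlap = overlap,
                         survival = survRes)
  .finishReport(report, outDir)
}

.finishReport <- function(report, outDir) {
  json <- report
  json$results <- NULL  # in-memory objects are not serialized
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  txt <- c("oligomiR pipeline report",
           paste0("  version ", json$provenance$version, ", seed ",
                  json$provenance$seed, ", config ",
                  json$provenance$config_hash),
           paste0("  thresholds: ",
                  paste(names(json$provenance$thresholds),
                        unlist(json$provenance$thresholds),
                        sep = "=", collapse = ", ")),
           vapply(names(json$stages), function(s)
             paste0("  [", json$stages[[s]]$status, "] ", s), ""))
  writeLines(txt, file.path(outDir, "report.txt"))
  invisible(report)
}
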