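## schema: known keys per config section; unknown keys are rejected up front
pipelineSchema <- list(
  top = c("seed", "output_dir", "simulation", "expression", "annotation",
          "train", "query", "reads"),
  simulation = c("classes", "nGenes", "nMarkersPerClass", "markerEffect",
                 "nSamplesPerClass", "nStudies", "batchSigma", "librarySize",
                 "dispersion", "nCellsPerClass", "cellLibrarySize", "dropout"),
  train = c("trainFraction", "prevalenceThreshold", "rankGenesTrees",
            "nTopAltogetherGenes", "nTopPerClassGenes", "rankRulesTrees",
            "nAltogetherRules", "nPerClassRules", "geneRepetitionCap",
            "boruta", "borutaIterations", "borutaTrees", "nTrees",
            "classWeights"),
  query = c("mixture", "expression"),
  mixture = c("classes", "weights", "nSamples"),
  reads = c("run", "readLength", "errorRate", "k", "rrnaK", "nReadsA",
            "nReadsB", "nReadsShared", "minHits", "margin"))

trainDefaults <- list(trainFraction = 0.6, prevalenceThreshold = 0.8,
                      rankGenesTrees = 2000, nTopAltogetherGenes = 60,
                      nTopPerClassGenes = 40, rankRulesTrees = 500,
                      nAltogetherRules = 100, nPerClassRules = 100,
                      geneRepetitionCap = 1, boruta = TRUE,
                      borutaIterations = 15, borutaTrees = 300,
                      nTrees = 1000, classWeights = "inverse_frequency")

readsDefaults <- list(run = FALSE, readLength = 100, errorRate = 0.01,
                      k = 25, rrnaK = 15, nReadsA = 700, nReadsB = 700,
                      nReadsShared = 600, minHits = 4, margin = 2)

#' Validate a pipeline configuration
#'
#' Checks the configuration (an R list or a YAML file path) against the
#' pipeline schema — unknown keys anywhere are rejected before any compute —
#' and fills defaults. Either a `simulation` block or `expression` +
#' `annotation` paths must provide the training data.
#'
#' @param config list or YAML file path.
#' @return validated config list with defaults filled.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  checkKeys <- function(x, where) {
    bad <- setdiff(names(x), pipelineSchema[[where]])
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  checkKeys(config, "top")
  if (is.null(config$seed)) stop("config requires a seed", call. = FALSE)
  hasSim <- !is.null(config$simulation)
  hasFiles <- !is.null(config$expression) && !is.null(config$annotation)
  if (!hasSim && !hasFiles)
    stop("config needs a 'simulation' block or 'expression' + 'annotation' paths",
         call. = FALSE)
  if (hasSim) checkKeys(config$simulation, "simulation")
  if (hasFiles) {
    for (p in c(config$expression, config$annotation))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  config$train <- utils::modifyList(trainDefaults, config$train %||% list())
  checkKeys(config$train, "train")
  if (!is.null(config$query)) {
    checkKeys(config$query, "query")
    if (!is.null(config$query$mixture)) {
      checkKeys(config$query$mixture, "mixture")
      mx <- config$query$mixture
      if (length(mx$classes) != length(mx$weights))
        stop("mixture classes and weights must have equal length", call. = FALSE)
    }
  }
  config$reads <- utils::modifyList(readsDefaults, config$reads %||% list())
  checkKeys(config$reads, "reads")
  config
}

## internal: structured JSON-lines logging with a console mirror
stageLogger <- function(path) {
  con <- file(path, open = "wt")
  list(log = function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    message("[", stage, "] ", paste(names(rec[-(1:2)]), unlist(rec[-(1:2)]),
                                    sep = "=", collapse = " "))
  }, close = function() close(con))
}

#' Run the end-to-end gene-pair-rule pipeline
#'
#' Executes, in order: data acquisition (simulate or load), prevalence
#' filtering, stratified split, gene ranking and selection, rule generation
#' and evaluation, rule ranking and capped selection, optional shadow-feature
#' pruning, forest training, held-out evaluation, optional query scoring and
#' optional read-origin QC. Artifacts (model.json, rules.tsv,
#' scores_test.tsv, report.json, and optionally query_scores.tsv,
#' read_origin.json) are written to the output directory together with a
#' structured JSON-lines log and a run manifest carrying the config hash,
#' package version, seed and per-artifact MD5 checksums. Re-running with an
#' identical config and seed reproduces identical artifact checksums.
#'
#' @param config list or YAML path, see [pipelineConfig()].
#' @param outDir output directory (default `config$output_dir`, or a
#'   temporary directory).
#' @return Invisibly, the manifest list (also written as manifest.json).
#' @export
runPipeline <- function(config, outDir = NULL) {
  config <- pipelineConfig(config)
  outDir <- outDir %||% config$output_dir %||% tempfile("pairForest_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logger <- stageLogger(file.path(outDir, "log.jsonl"))
  on.exit(logger$close(), add = TRUE)
  seed <- config$seed
  tr <- config$train
  timer <- function(expr, stage, ...) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logger$log(stage, elapsed = round(proc.time()[["elapsed"]] - t0, 2), ...)
    res
  }

  sim <- NULL
  if (!is.null(config$simulation)) {
    data <- timer({
      sim <- simulateBulk(do.call(simulationConfig,
                                  c(config$simulation, list(seed = seed))))
      sim[c("expr", "annotation")]
    }, "simulate")   # promise evaluates in this frame, so `sim` lands here
  } else {
    data <- timer(list(expr = readExpression(config$expression),
                       annotation = readSampleAnnotation(config$annotation)),
                  "load")
  }
  expr <- timer(filterGenesByPrevalence(data$expr, tr$prevalenceThreshold),
                "filter", genes = NA)
  ann <- data$annotation

  split <- timer(stratifiedSplit(ann, tr$trainFraction, seed), "split")
  exprTrain <- expr[, split$train, drop = FALSE]
  annTrain <- ann[ann$sample_id %in% split$train, , drop = FALSE]

  ranking <- timer(rankGenes(exprTrain, annTrain, nTrees = tr$rankGenesTrees,
                             seed = seed), "rank_genes")
  genes <- timer(selectTopGenes(ranking, tr$nTopAltogetherGenes,
                                tr$nTopPerClassGenes), "select_genes",
                 n = NA)
  ruleTab <- generateRules(genes)
  rmTrain <- timer(evaluateRules(exprTrain, ruleTab), "evaluate_rules",
                   rules = nrow(ruleTab))
  ranked <- timer(rankRules(rmTrain, annTrain, classWeights = tr$classWeights,
                            nTrees = tr$rankRulesTrees, seed = seed),
                  "rank_rules")
  sel <- timer(suppressWarnings(
    selectRules(ranked, tr$nAltogetherRules, tr$nPerClassRules,
                tr$geneRepetitionCap)), "select_rules")
  rmSel <- new("RuleMatrix",
               values = rmTrain@values[, ruleId(sel), drop = FALSE],
               rules = sel)
  verdicts <- NULL
  if (isTRUE(tr$boruta)) {
    pr <- timer(borutaPrune(rmSel, annTrain, maxIterations = tr$borutaIterations,
                            nTrees = tr$borutaTrees, seed = seed), "boruta")
    rmSel <- pr$kept
    verdicts <- pr$verdicts
  }
  model <- timer(trainRuleForest(rmSel, annTrain, nTrees = tr$nTrees,
                                 classWeights = tr$classWeights, seed = seed,
                                 metadata = list(borutaVerdicts = verdicts)),
                 "train", rules = nrow(rmSel@rules))

  exprTest <- expr[, split$test, drop = FALSE]
  annTest <- ann[ann$sample_id %in% split$test, , drop = FALSE]
  ps <- timer(predictScores(model, exprTest), "predict_test")
  report <- confusionReport(hardLabels(ps),
                            annTest$class_label[match(rownames(scores(ps)),
                                                      annTest$sample_id)])

  writeRuleForest(model, file.path(outDir, "model.json"))
  writeRules(model@rules, file.path(outDir, "rules.tsv"))
  data.table::fwrite(scoreTable(ps, annTest),
                     file.path(outDir, "scores_test.tsv"), sep = "\t")
  writeLines(jsonlite::toJSON(list(
    overall = report$overall, perClass = report$perClass,
    confusion = as.data.frame(report$table)), digits = I(10),
    auto_unbox = TRUE, dataframe = "columns"),
    file.path(outDir, "report.json"))

  if (!is.null(config$query)) {
    qExpr <- if (!is.null(config$query$mixture)) {
      if (is.null(sim))
        stop("mixture queries require simulated training data", call. = FALSE)
      mx <- config$query$mixture
      timer(simulateMixture(sim, setNames(as.numeric(mx$weights),
                                          as.character(mx$classes)),
                            mx$nSamples, seed), "simulate_query")
    } else readExpression(config$query$expression)
    qps <- timer(predictScores(model, qExpr), "predict_query")
    data.table::fwrite(scoreTable(qps), file.path(outDir, "query_scores.tsv"),
                       sep = "\t")
  }

  if (isTRUE(config$reads$run)) {
    rd <- config$reads
    ro <- timer({
      refs <- makeToyReferences(seed)
      simR <- simulateReads(list(refA = refs$uniqueA, refB = refs$uniqueB,
                                 shared = refs$shared),
                            nReads = c(refA = rd$nReadsA, refB = rd$nReadsB,
                                       shared = rd$nReadsShared),
                            readLength = rd$readLength,
                            errorRate = rd$errorRate, seed = seed)
      idx <- buildKmerIndex(refs$refA, refs$refB, k = rd$k)
      cls <- classifyReads(simR$reads, idx, minHits = rd$minHits,
                           margin = rd$margin)
      rrna <- estimateRrnaFraction(simR$reads, refs$shared, k = rd$rrnaK)
      list(counts = as.list(readCounts(cls$summary)),
           percentages = as.list(readPercentages(cls$summary)),
           rrnaFraction = rrna)
    }, "read_origin")
    writeLines(jsonlite::toJSON(ro, digits = I(10), auto_unbox = TRUE),
               file.path(outDir, "read_origin.json"))
  }

  configHash <- unname(tools::md5sum(writeConfigCanonical(config, outDir)))
  arts <- setdiff(list.files(outDir),
                  c("manifest.json", "log.jsonl", "config_used.yaml"))
  manifest <- list(
    package = "pairForest",
    version = as.character(utils::packageVersion("pairForest")),
    seed = seed,
    configHash = configHash,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    checksums = as.list(tools::md5sum(file.path(outDir, arts))),
    nFinalRules = nrow(model@rules),
    testAccuracy = report$overall$accuracy)
  names(manifest$checksums) <- arts
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(10)),
             file.path(outDir, "manifest.json"))
  invisible(manifest)
}

## internal: canonical config serialization for hashing; the output location
## is not part of the run's identity
writeConfigCanonical <- function(config, outDir) {
  p <- file.path(outDir, "config_used.yaml")
  config$output_dir <- NULL
  yaml::write_yaml(config[order(names(config))], p)
  p
}

#' Write a ready-to-run demo workspace
#'
#' Generates a complete synthetic five-class, five-study, imbalanced training
#' cohort, a 50/50 astrocyte + microglia mixture query set emulating a
#' heterogeneous cell line, toy two-reference FASTA files plus a FASTQ of
#' simulated reads (with an rRNA-like shared segment), and a ready
#' `config.yaml`, all deterministic for a fixed seed.
#'
#' @param dir target directory.
#' @param seed integer seed (default 1).
#' @return Invisibly, the path of the written config.
#' @export
makeDemo <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateBulk(simulationConfig(seed = seed))
  writeExpression(sim$expr, file.path(dir, "train_expression.tsv"))
  writeSampleAnnotation(sim$annotation, file.path(dir, "train_annotation.tsv"))
  mix <- simulateMixture(sim, c(astrocyte = 0.5, microglia = 0.5), 12,
                         seed = seed)
  writeExpression(mix, file.path(dir, "query_mixture.tsv"))

  refs <- makeToyReferences(seed)
  Biostrings::writeXStringSet(refs$refA, file.path(dir, "refA.fa"))
  Biostrings::writeXStringSet(refs$refB, file.path(dir, "refB.fa"))
  Biostrings::writeXStringSet(refs$shared, file.path(dir, "rrna.fa"))
  rd <- simulateReads(list(refA = refs$uniqueA, refB = refs$uniqueB,
                           shared = refs$shared),
                      nReads = c(refA = 700, refB = 700, shared = 600),
                      readLength = 100, errorRate = 0.01, seed = seed)
  writeFastq(rd$reads, file.path(dir, "reads.fq"))

  config <- list(
    seed = as.integer(seed),
    output_dir = "results",   # relative to the directory the run starts in
    simulation = list(),
    query = list(mixture = list(classes = c("astrocyte", "microglia"),
                                weights = c(0.5, 0.5), nSamples = 12)),
    reads = list(run = TRUE))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
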