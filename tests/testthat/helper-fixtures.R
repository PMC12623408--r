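## tiny deterministic expression matrix with named genes/samples
toyMatrix <- function(nGenes = 5, nSamples = 4, seed = 1, genes = NULL,
                      samples = NULL) {
  set.seed(seed)
  m <- matrix(round(runif(nGenes * nSamples, 0, 100)), nGenes, nSamples)
  rownames(m) <- genes %||% paste0("G", seq_len(nGenes))
  colnames(m) <- samples %||% paste0("S", seq_len(nSamples))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toyAnnotation <- function(m, classes) {
  data.frame(sample_id = colnames(m),
             class_label = rep_len(classes, ncol(m)),
             study_id = "study1", stringsAsFactors = FALSE)
}

## hand-built RuleMatrix from an explicit binary matrix
toyRuleMatrix <- function(values, genePrefix = "R") {
  nr <- ncol(values)
  rules <- data.frame(gene_a = paste0(genePrefix, seq_len(nr), "a"),
                      gene_b = paste0(genePrefix, seq_len(nr), "b"),
                      stringsAsFactors = FALSE)
  colnames(values) <- pairForest::ruleId(rules)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  methods::new("RuleMatrix", values = values, rules = rules)
}

## a full desk-scale fit shared by the heavier tests: built once per run
acceptanceFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    seed <- 1L
    sim <- simulateBulk(simulationConfig(seed = seed))
    expr <- filterGenesByPrevalence(sim$expr, 0.8)
    sp <- stratifiedSplit(sim$annotation, 0.6, seed)
    ann <- sim$annotation
    exprTrain <- expr[, sp$train, drop = FALSE]
    annTrain <- ann[ann$sample_id %in% sp$train, , drop = FALSE]
    ranking <- rankGenes(exprTrain, annTrain, nTrees = 2000, seed = seed)
    genes <- selectTopGenes(ranking, 60, 40)
    rm <- evaluateRules(exprTrain, generateRules(genes))
    ranked <- rankRules(rm, annTrain, nTrees = 500, seed = seed)
    sel <- suppressWarnings(selectRules(ranked, 100, 100, 1))
    rmSel <- methods::new("RuleMatrix",
                          values = ruleValues(rm)[, ruleId(sel), drop = FALSE],
                          rules = sel)
    pruned <- borutaPrune(rmSel, annTrain, maxIterations = 15, seed = seed)
    model <- trainRuleForest(pruned$kept, annTrain, nTrees = 1000, seed = seed)
    exprTest <- expr[, sp$test, drop = FALSE]
    annTest <- ann[ann$sample_id %in% sp$test, , drop = FALSE]
    ps <- predictScores(model, exprTest)
    truthTest <- annTest$class_label[match(rownames(scores(ps)),
                                           annTest$sample_id)]
    cache <<- list(seed = seed, sim = sim, expr = expr, split = sp,
                   annTrain = annTrain, model = model,
                   exprTest = exprTest, annTest = annTest,
                   ps = ps, truthTest = truthTest)
    cache
  }
})
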