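#' Boruta-style shadow-feature pruning of rule matrices
#'
#' Iteratively compares each candidate rule's Random-Forest importance against
#' the maximum importance of "shadow" features (column-shuffled copies of the
#' candidates). At each iteration a rule scores a hit when it beats the best
#' shadow; hits accumulate and a two-sided binomial test (Bonferroni-corrected
#' across the rules still undecided) confirms rules significantly above chance
#' and rejects rules significantly below. Rules still tentative after
#' `maxIterations` are kept (conservative toward signal retention).
#'
#' @param rm a \linkS4class{RuleMatrix} of candidate rules.
#' @param ann annotation data.frame.
#' @param maxIterations maximum shadow iterations (default 25).
#' @param alpha significance level of the binomial test (default 0.01).
#' @param nTrees trees per iteration forest (default 300).
#' @param classWeights `"inverse_frequency"` or `"none"`.
#' @param seed integer seed.
#' @return list: `kept` (\linkS4class{RuleMatrix} restricted to confirmed + tentative
#'   rules), `verdicts` (factor `confirmed`/`tentative`/`rejected` named by
#'   rule), `hits`, `iterations`.
#' @export
borutaPrune <- function(rm, ann, maxIterations = 25, alpha = 0.01,
                        nTrees = 300, classWeights = c("inverse_frequency", "none"),
                        seed) {
  classWeights <- match.arg(classWeights)
  stopifnot(is(rm, "RuleMatrix"), nrow(rm@values) > 1, ncol(rm@values) >= 1)
  ann <- ann[match(rownames(rm@values), ann$sample_id), , drop = FALSE]
  labels <- factor(ann$class_label)
  w <- caseWeights(labels, classWeights)

  ids <- ruleId(rm@rules)
  status <- setNames(rep("tentative", length(ids)), ids)
  hits <- setNames(integer(length(ids)), ids)
  tested <- setNames(integer(length(ids)), ids)
  iter <- 0L
  while (iter < maxIterations && any(status == "tentative")) {
    iter <- iter + 1L
    undecided <- names(status)[status == "tentative"]
    x <- rm@values[, undecided, drop = FALSE]
    set.seed(stageSeed(seed, paste0("boruta_shuffle_", iter)))
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0(".shadow_", seq_len(ncol(shadow)))
    imp <- importanceFit(cbind(x, shadow), labels, nTrees,
                         stageSeed(seed, paste0("boruta_fit_", iter)), w)
    impVec <- setNames(imp$importance, imp$feature)
    shadowMax <- max(impVec[startsWith(names(impVec), ".shadow_")])
    hit <- impVec[undecided] > shadowMax
    hits[undecided] <- hits[undecided] + as.integer(hit)
    tested[undecided] <- tested[undecided] + 1L
    pHi <- stats::pbinom(hits[undecided] - 1L, tested[undecided], 0.5,
                         lower.tail = FALSE)
    pLo <- stats::pbinom(hits[undecided], tested[undecided], 0.5)
    confirm <- p.adjust(pHi, "bonferroni") < alpha
    reject <- p.adjust(pLo, "bonferroni") < alpha & !confirm
    status[undecided[confirm]] <- "confirmed"
    status[undecided[reject]] <- "rejected"
  }
  verdicts <- factor(status, levels = c("confirmed", "tentative", "rejected"))
  names(verdicts) <- ids
  keep <- status != "rejected"
  if (!any(keep))
    stop("all rules rejected by shadow-feature pruning; ",
         "check that the rule matrix carries class signal", call. = FALSE)
  kept <- new("RuleMatrix", values = rm@values[, keep, drop = FALSE],
              rules = rm@rules[keep, , drop = FALSE])
  list(kept = kept, verdicts = verdicts, hits = hits, iterations = iter)
}

#' Train the gene-pair-rule probability forest
#'
#' Fits a bagged ensemble of `nTrees` decision trees on the binary rule
#' features, with probability estimation (class scores are averaged leaf
#' class fractions; trees are grown to `minNodeSize = 1`, so with separable
#' leaves the scores are tree-vote fractions). Out-of-bag predictions and
#' in-bag assignments are retained for self-assessment and proximity.
#' Deterministic for a fixed seed.
#'
#' @param rm the selected (and pruned) training \linkS4class{RuleMatrix}.
#' @param ann annotation data.frame.
#' @param nTrees number of trees (default 1000).
#' @param classWeights `"inverse_frequency"` (default) or `"none"`.
#' @param probability grow a probability forest (default TRUE).
#' @param minNodeSize minimum node size (default 1).
#' @param seed integer seed.
#' @param metadata extra metadata entries stored in the model.
#' @return A \linkS4class{RuleForest}.
#' @export
trainRuleForest <- function(rm, ann, nTrees = 1000,
                            classWeights = c("inverse_frequency", "none"),
                            probability = TRUE, minNodeSize = 1, seed,
                            metadata = list()) {
  classWeights <- match.arg(classWeights)
  stopifnot(is(rm, "RuleMatrix"))
  ann <- ann[match(rownames(rm@values), ann$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("rule matrix rows do not match annotation", call. = FALSE)
  labels <- as.factor(ann$class_label)   # declared factor levels are honored
  empty <- levels(labels)[table(labels) == 0]
  if (length(empty))
    stop("class absent from training: ", paste(empty, collapse = ", "), call. = FALSE)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)

  fit <- ranger::ranger(x = rm@values, y = labels, num.trees = nTrees,
                        probability = probability, keep.inbag = TRUE,
                        min.node.size = minNodeSize,
                        case.weights = caseWeights(labels, classWeights),
                        seed = stageSeed(seed, "train_forest"),
                        num.threads = 1, importance = "impurity")
  majority <- as.integer(colMeans(rm@values) > 0.5)   # tie -> 0, as for rule ties
  meta <- c(list(seed = seed, nTrees = nTrees, classWeights = classWeights,
                 probability = probability, minNodeSize = minNodeSize,
                 version = as.character(utils::packageVersion("pairForest"))),
            metadata)
  new("RuleForest", rules = rm@rules, forest = fit,
      classes = levels(labels), ruleMajority = majority,
      trainRuleMatrix = rm@values, trainLabels = labels, metadata = meta)
}

## internal: build the samples x rules feature matrix for prediction,
## imputing rules whose genes are absent in the query matrix
predictionFeatures <- function(model, m, missingPolicy, maxMissingFraction,
                               kImpute) {
  rules <- model@rules
  present <- rules$gene_a %in% rownames(m) & rules$gene_b %in% rownames(m)
  missingFrac <- mean(!present)
  if (any(!present) && missingPolicy == "error")
    stop(sum(!present), " rules not evaluable (missing genes) and missingPolicy='error'",
         call. = FALSE)
  if (missingFrac > maxMissingFraction)
    stop(sprintf("%.1f%% of rules not evaluable, above the %.1f%% cap",
                 100 * missingFrac, 100 * maxMissingFraction), call. = FALSE)
  x <- matrix(rep(model@ruleMajority, each = ncol(m)), ncol(m),
              nrow(rules), dimnames = list(colnames(m), ruleId(rules)))
  if (any(present)) {
    sub <- rules[present, , drop = FALSE]
    x[, present] <- t(m[sub$gene_a, , drop = FALSE] <
                      m[sub$gene_b, , drop = FALSE]) * 1L
  }
  if (missingPolicy == "impute_knn" && any(!present) && any(present)) {
    trm <- model@trainRuleMatrix
    k <- min(kImpute, nrow(trm))
    # Hamming distances on the evaluable rules, all queries at once
    xp <- x[, present, drop = FALSE]
    tp <- trm[, present, drop = FALSE]
    d <- xp %*% t(1 - tp) + (1 - xp) %*% t(tp)
    for (i in seq_len(nrow(x))) {
      nn <- order(d[i, ])[seq_len(k)]           # stable order: deterministic
      x[i, !present] <- as.integer(colMeans(trm[nn, !present, drop = FALSE]) > 0.5)
    }
  }
  list(x = x, nImputed = sum(!present))
}

#' Score samples with a trained rule forest
#'
#' Rules whose genes are both present in the query matrix are evaluated
#' normally; a rule with any absent gene is imputed, up to
#' `maxMissingFraction` of the rules. The default `"impute_knn"` policy fills
#' each query sample's missing rules from its `kImpute` Hamming-nearest
#' training samples over the evaluable rules (majority vote among the
#' neighbors), so the fill is class-consistent even when most rules are
#' missing; `"impute_majority"` fills every missing rule with its global
#' training-majority activation (simpler, but biased toward the largest
#' class when the missing fraction is high); `"error"` refuses missing
#' genes. The training rule matrix backing either policy is stored in the
#' model, so imputations are auditable. Scores are per-class probability
#' estimates (tree-vote fractions); each row sums to 1.
#'
#' @param model a \linkS4class{RuleForest}.
#' @param m genes x samples query matrix (any monotone per-sample scale).
#' @param missingPolicy `"impute_knn"` (default), `"impute_majority"`, or
#'   `"error"`.
#' @param maxMissingFraction maximum tolerated fraction of non-evaluable rules
#'   (default 0.75).
#' @param kImpute neighbors used by `"impute_knn"` (default 5; odd values
#'   avoid neighbor-vote ties).
#' @return A \linkS4class{PredictionScores}.
#' @export
predictScores <- function(model, m,
                          missingPolicy = c("impute_knn", "impute_majority",
                                            "error"),
                          maxMissingFraction = 0.75, kImpute = 5L) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(model, "RuleForest"))
  assertExpressionMatrix(m, allow_negative = TRUE)
  pf <- predictionFeatures(model, m, missingPolicy, maxMissingFraction, kImpute)
  pred <- predict(model@forest, data = pf$x, num.threads = 1)$predictions
  if (is.null(dim(pred)))
    stop("model must be a probability forest to emit scores", call. = FALSE)
  rownames(pred) <- colnames(m)
  pred <- pred[, model@classes, drop = FALSE]
  new("PredictionScores", scores = pred,
      nImputed = rep(as.integer(pf$nImputed), ncol(m)))
}

#' Random-Forest proximity matrix
#'
#' `proximity(i, j)` is the fraction of trees in which samples i and j land in
#' the same terminal leaf. For training samples the default restricts each
#' pair to the trees where both samples are out-of-bag (the unbiased
#' estimate); `useOOB = FALSE` uses all trees, which is also the mode applied
#' to new samples.
#'
#' @param model a \linkS4class{RuleForest}.
#' @param rm optional \linkS4class{RuleMatrix} of new samples; default uses the training
#'   samples.
#' @param useOOB restrict to jointly out-of-bag trees (training samples only).
#' @return symmetric samples x samples matrix of proximities between 0 and 1 with unit diagonal.
#' @export
proximityMatrix <- function(model, rm = NULL, useOOB = is.null(rm)) {
  stopifnot(is(model, "RuleForest"))
  values <- if (is.null(rm)) model@trainRuleMatrix else {
    stopifnot(is(rm, "RuleMatrix"))
    if (useOOB) stop("useOOB applies only to the training samples", call. = FALSE)
    rm@values[, ruleId(model@rules), drop = FALSE]
  }
  leaves <- predict(model@forest, data = values, type = "terminalNodes",
                    num.threads = 1)$predictions
  n <- nrow(values); nt <- ncol(leaves)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  oob <- if (useOOB) {
    ib <- do.call(cbind, model@forest$inbag.counts)
    ib == 0
  } else NULL
  for (t in seq_len(nt)) {
    eq <- outer(leaves[, t], leaves[, t], "==")
    if (useOOB) {
      w <- outer(oob[, t], oob[, t], "&")
      num <- num + (eq & w)
      den <- den + w
    } else {
      num <- num + eq
    }
  }
  prox <- if (useOOB) ifelse(den > 0, num / den, 0) else num / nt
  diag(prox) <- 1
  dimnames(prox) <- list(rownames(values), rownames(values))
  prox
}

#' Grid search over rule-selection and forest parameters
#'
#' Exhaustively evaluates every combination of the supplied parameter values
#' by re-running rule selection (and optionally shadow-feature pruning) and
#' training a forest, scoring each setting by out-of-bag macro-averaged
#' balanced accuracy. Ties break toward fewer rules, then fewer trees.
#'
#' @param rm the candidate \linkS4class{RuleMatrix} (all generated rules).
#' @param ann annotation data.frame.
#' @param ranked output of [rankRules()] over `rm`.
#' @param grid named list of vectors over any of `geneRepetitionCap`,
#'   `nAltogether`, `nPerClass`, `boruta` (logical), `nTrees`.
#' @param seed integer seed.
#' @param borutaIterations,borutaTrees scaled-down pruning settings used
#'   inside the grid search.
#' @return list: `best` (row of the score table) and `scores` (full table,
#'   one row per grid point).
#' @export
optimizeParameters <- function(rm, ann, ranked,
                               grid = list(geneRepetitionCap = 1,
                                           nAltogether = 100, nPerClass = 100,
                                           boruta = TRUE, nTrees = 1000),
                               seed, borutaIterations = 10, borutaTrees = 200) {
  defaults <- list(geneRepetitionCap = 1, nAltogether = 100, nPerClass = 100,
                   boruta = TRUE, nTrees = 1000)
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown)) stop("unknown grid parameters: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  grid <- utils::modifyList(defaults, grid)
  tab <- expand.grid(grid, stringsAsFactors = FALSE)
  ann2 <- ann[match(rownames(rm@values), ann$sample_id), , drop = FALSE]
  truth <- factor(ann2$class_label)

  res <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab[i, ]
    sel <- suppressWarnings(selectRules(ranked, p$nAltogether, p$nPerClass,
                                        p$geneRepetitionCap))
    sub <- new("RuleMatrix", values = rm@values[, ruleId(sel), drop = FALSE],
               rules = sel)
    if (isTRUE(p$boruta))
      sub <- borutaPrune(sub, ann2, maxIterations = borutaIterations,
                         nTrees = borutaTrees, seed = seed)$kept
    model <- trainRuleForest(sub, ann2, nTrees = p$nTrees, seed = seed)
    oob <- model@forest$predictions
    hard <- colnames(oob)[max.col(oob, ties.method = "first")]
    data.frame(p, nRules = nrow(sub@rules),
               oobBalancedAccuracy = macroBalancedAccuracy(hard, truth))
  })
  scoresTab <- do.call(rbind, res)
  ord <- order(-scoresTab$oobBalancedAccuracy, scoresTab$nRules, scoresTab$nTrees)
  list(best = scoresTab[ord[1], , drop = FALSE], scores = scoresTab)
}

## ---- JSON serialization -----------------------------------------------

#' Serialize / restore a trained rule forest as JSON
#'
#' The model — rules, per-rule training majorities, every tree's node records,
#' out-of-bag predictions and in-bag assignments — is written as a single
#' JSON document with 17 significant digits, which round-trips IEEE doubles
#' exactly; [readRuleForest()] reconstructs a model whose predictions are
#' bit-identical to the original's.
#'
#' @param model a \linkS4class{RuleForest}.
#' @param path output path.
#' @export
writeRuleForest <- function(model, path) {
  stopifnot(is(model, "RuleForest"))
  fit <- model@forest
  doc <- list(
    format = "pairForest/rule-forest",
    version = model@metadata$version %||% "0",
    classes = model@classes,
    rules = as.list(model@rules),
    ruleMajority = model@ruleMajority,
    trainLabels = as.character(model@trainLabels),
    trainRuleMatrix = list(dim = dim(model@trainRuleMatrix),
                           rownames = rownames(model@trainRuleMatrix),
                           colnames = colnames(model@trainRuleMatrix),
                           values = as.integer(model@trainRuleMatrix)),
    metadata = rapply(model@metadata, function(x)
      if (is.factor(x)) as.character(x) else x, how = "replace"),
    ranger = list(
      num.trees = fit$num.trees, mtry = fit$mtry,
      min.node.size = fit$min.node.size, splitrule = fit$splitrule,
      num.samples = fit$num.samples, replace = fit$replace,
      treetype = fit$treetype,
      num.independent.variables = fit$num.independent.variables,
      predictions = list(dim = dim(fit$predictions),
                         colnames = colnames(fit$predictions),
                         values = as.numeric(fit$predictions)),
      inbag.counts = fit$inbag.counts,
      forest = unclass(fit$forest)))
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = FALSE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeRuleForest
#' @return `readRuleForest()` returns the restored \linkS4class{RuleForest}.
#' @export
readRuleForest <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(as.character(doc$format), "pairForest/rule-forest"))
    stop("not a pairForest rule-forest JSON document", call. = FALSE)
  rules <- as.data.frame(lapply(doc$rules, unlist), stringsAsFactors = FALSE)
  trm <- matrix(as.integer(doc$trainRuleMatrix$values),
                doc$trainRuleMatrix$dim[1], doc$trainRuleMatrix$dim[2],
                dimnames = list(as.character(doc$trainRuleMatrix$rownames),
                                as.character(doc$trainRuleMatrix$colnames)))
  rg <- doc$ranger
  f <- rg$forest
  f$num.trees <- as.numeric(f$num.trees)
  f$child.nodeIDs <- lapply(f$child.nodeIDs, function(t) lapply(t, as.numeric))
  f$split.varIDs <- lapply(f$split.varIDs, as.numeric)
  f$split.values <- lapply(f$split.values, as.numeric)
  if (!is.null(f$terminal.class.counts))
    f$terminal.class.counts <- lapply(f$terminal.class.counts,
                                      function(t) lapply(t, as.numeric))
  f$is.ordered <- as.logical(f$is.ordered)
  f$class.values <- as.numeric(f$class.values)
  f$levels <- as.character(f$levels)
  f$independent.variable.names <- as.character(f$independent.variable.names)
  f$treetype <- as.character(f$treetype[[1]])
  class(f) <- "ranger.forest"
  pred <- matrix(as.numeric(rg$predictions$values),
                 rg$predictions$dim[1], rg$predictions$dim[2])
  colnames(pred) <- as.character(rg$predictions$colnames)
  fit <- list(forest = f, treetype = as.character(rg$treetype[[1]]),
              num.trees = as.numeric(rg$num.trees),
              num.independent.variables = as.numeric(rg$num.independent.variables),
              mtry = as.numeric(rg$mtry), min.node.size = as.numeric(rg$min.node.size),
              splitrule = as.character(rg$splitrule[[1]]),
              num.samples = as.numeric(rg$num.samples),
              replace = as.logical(rg$replace),
              predictions = pred,
              inbag.counts = lapply(rg$inbag.counts, as.integer),
              importance.mode = "none")
  class(fit) <- "ranger"
  labels <- factor(as.character(doc$trainLabels), levels = as.character(doc$classes))
  new("RuleForest", rules = rules, forest = fit,
      classes = as.character(doc$classes),
      ruleMajority = as.integer(doc$ruleMajority),
      trainRuleMatrix = trm, trainLabels = labels,
      metadata = doc$metadata)
}
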