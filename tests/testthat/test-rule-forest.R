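## binary rule matrix with one class-indicator column and pure-noise columns
borutaToy <- function(nNoise = 50, n = 60, seed = 2) {
  set.seed(seed)
  labels <- rep(c("pos", "neg"), each = n / 2)
  values <- cbind(as.integer(labels == "pos"),
                  matrix(rbinom(n * nNoise, 1, 0.5), n, nNoise))
  rm <- toyRuleMatrix(values)
  ann <- data.frame(sample_id = rownames(ruleValues(rm)), class_label = labels)
  list(rm = rm, ann = ann, indicator = ruleId(rules(rm))[1])
}

test_that("shadow pruning confirms the indicator and rejects most noise rules", {
  toy <- borutaToy()
  out <- borutaPrune(toy$rm, toy$ann, nTrees = 200, seed = 4)
  expect_identical(as.character(out$verdicts[toy$indicator]), "confirmed")
  noise <- out$verdicts[names(out$verdicts) != toy$indicator]
  expect_gte(mean(noise == "rejected"), 0.9)
  expect_true(toy$indicator %in% ruleId(rules(out$kept)))
})

test_that("shadow pruning confirms nothing under label permutation", {
  toy <- borutaToy(nNoise = 25, n = 40)
  confirmed <- vapply(1:20, function(r) {
    set.seed(300 + r)
    annP <- toy$ann
    annP$class_label <- sample(annP$class_label)
    out <- tryCatch(
      borutaPrune(toy$rm, annP, maxIterations = 6, nTrees = 100, seed = r),
      error = function(e) NULL)   # all-rejected is also a no-confirmation run
    if (is.null(out)) 0L else sum(out$verdicts == "confirmed")
  }, integer(1))
  expect_gte(mean(confirmed == 0), 0.95)
})

test_that("a single perfectly separating rule survives its own shadow", {
  toy <- borutaToy(nNoise = 0)
  out <- borutaPrune(toy$rm, toy$ann, maxIterations = 10, nTrees = 100, seed = 1)
  expect_identical(as.character(out$verdicts[toy$indicator]), "confirmed")
})

test_that("training on separable rules reaches perfect out-of-bag accuracy", {
  toy <- borutaToy(nNoise = 5)
  model <- trainRuleForest(toy$rm, toy$ann, nTrees = 200, seed = 3)
  oob <- model@forest$predictions
  hard <- colnames(oob)[max.col(oob, ties.method = "first")]
  expect_identical(mean(hard == toy$ann$class_label), 1)
  expect_setequal(classLabels(model), c("pos", "neg"))
})

test_that("a single-tree forest emits 0/1 scores", {
  toy <- borutaToy(nNoise = 5)
  model <- trainRuleForest(toy$rm, toy$ann, nTrees = 1, seed = 3)
  rg <- unique(c(rules(model)$gene_a, rules(model)$gene_b))
  m <- toyMatrix(length(rg), 10, seed = 5)
  rownames(m) <- rg
  ps <- predictScores(model, m)
  expect_true(all(scores(ps) %in% c(0, 1)))
})

test_that("training is deterministic and the JSON round trip is bit-exact", {
  toy <- borutaToy(nNoise = 8)
  m1 <- trainRuleForest(toy$rm, toy$ann, nTrees = 100, seed = 7)
  m2 <- trainRuleForest(toy$rm, toy$ann, nTrees = 100, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeRuleForest(m1, f1); writeRuleForest(m2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  rg <- unique(c(rules(m1)$gene_a, rules(m1)$gene_b))
  query <- toyMatrix(length(rg), 12, seed = 8)
  rownames(query) <- rg
  restored <- readRuleForest(f1)
  expect_identical(scores(predictScores(m1, query)),
                   scores(predictScores(restored, query)))
  expect_identical(rules(restored), rules(m1))
  expect_identical(restored@ruleMajority, m1@ruleMajority)
})

test_that("prediction with no missing genes equals the direct evaluation path", {
  fx <- acceptanceFixture()
  direct <- predict(fx$model@forest,
                    data = ruleValues(evaluateRules(fx$exprTest,
                                                    rules(fx$model))),
                    num.threads = 1)$predictions
  got <- scores(fx$ps)
  expect_equal(unname(got), unname(direct[, colnames(got)]), tolerance = 0)
  expect_true(all(nImputed(fx$ps) == 0))
})

test_that("missing-gene handling obeys the policy and the missing-fraction cap", {
  fx <- acceptanceFixture()
  model <- fx$model
  rl <- rules(model)
  # drop one rule gene: that rule is imputed, the rest evaluated
  drop1 <- fx$exprTest[setdiff(rownames(fx$exprTest), rl$gene_a[1]), ]
  ps <- predictScores(model, drop1)
  expect_true(all(nImputed(ps) >= 1))
  expect_error(predictScores(model, drop1, missingPolicy = "error"),
               "missingPolicy")

  # deleting every rule gene exceeds any cap below 1
  none <- fx$exprTest[setdiff(rownames(fx$exprTest),
                              unique(c(rl$gene_a, rl$gene_b))), ]
  expect_error(predictScores(model, none), "cap")

  # with the cap lifted, majority fill gives every sample identical scores
  psAll <- predictScores(model, none, missingPolicy = "impute_majority",
                         maxMissingFraction = 1)
  expect_identical(nrow(unique(scores(psAll))), 1L)
})

test_that("proximity is symmetric, unit-diagonal, and tracks class structure", {
  fx <- acceptanceFixture()
  prox <- proximityMatrix(fx$model)
  expect_identical(unname(diag(prox)), rep(1, nrow(prox)))
  expect_lt(max(abs(prox - t(prox))), 1e-12)
  expect_true(all(prox >= 0 & prox <= 1))

  lab <- fx$annTrain$class_label[match(rownames(prox),
                                       fx$annTrain$sample_id)]
  same <- outer(lab, lab, "==") & upper.tri(prox)
  diff <- (!outer(lab, lab, "==")) & upper.tri(prox)
  expect_gt(mean(prox[same]), mean(prox[diff]))

  # duplicated feature rows land in the same leaf of every tree
  rmDup <- methods::new("RuleMatrix",
                        values = fx$model@trainRuleMatrix[c(1, 1, 2), ],
                        rules = rules(fx$model))
  proxDup <- proximityMatrix(fx$model, rmDup, useOOB = FALSE)
  expect_identical(proxDup[1, 2], 1)
})

test_that("parameter optimization is exhaustive with declared tie-breaks", {
  toy <- borutaToy(nNoise = 10)
  rr <- rankRules(toy$rm, toy$ann, nTrees = 100, seed = 5)
  one <- optimizeParameters(toy$rm, toy$ann, rr,
                            grid = list(nTrees = 50, boruta = FALSE), seed = 5)
  expect_identical(nrow(one$scores), 1L)
  expect_identical(one$best$nTrees, 50)

  grid <- list(nTrees = c(50, 100), geneRepetitionCap = c(1, 2), boruta = FALSE)
  out <- optimizeParameters(toy$rm, toy$ann, rr, grid = grid, seed = 5)
  expect_identical(nrow(out$scores), 4L)
  best <- out$best
  topScore <- max(out$scores$oobBalancedAccuracy)
  contenders <- out$scores[out$scores$oobBalancedAccuracy == topScore, ]
  expect_identical(best$nRules, min(contenders$nRules))
})

test_that("a class absent from training is rejected", {
  toy <- borutaToy(nNoise = 3)
  ann <- toy$ann
  ann$class_label <- factor(ann$class_label, levels = c("pos", "neg", "ghost"))
  expect_error(trainRuleForest(toy$rm, ann, nTrees = 50, seed = 1), "ghost")
})
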