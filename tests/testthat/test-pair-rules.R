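## toy where exactly one gene separates two classes perfectly
separableToy <- function(nNoise = 20, nPer = 15, seed = 3) {
  set.seed(seed)
  n <- 2 * nPer
  m <- matrix(runif(nNoise * n, 10, 20), nNoise, n,
              dimnames = list(paste0("N", seq_len(nNoise)), paste0("S", seq_len(n))))
  sep <- c(runif(nPer, 50, 60), runif(nPer, 1, 5))
  m <- rbind(SEP = sep, m)
  ann <- data.frame(sample_id = colnames(m),
                    class_label = rep(c("hi", "lo"), each = nPer))
  list(m = m, ann = ann)
}

test_that("a perfectly separating gene ranks first under both schemes", {
  toy <- separableToy()
  rk <- rankGenes(toy$m, toy$ann, nTrees = 500, seed = 7)
  expect_identical(rk$altogether$feature[1], "SEP")
  expect_identical(rk$perClass$hi$feature[1], "SEP")
  expect_identical(rk$perClass$lo$feature[1], "SEP")
})

test_that("permuted labels destroy the separating gene's dominance", {
  toy <- separableToy()
  trueTop <- rankGenes(toy$m, toy$ann, scheme = "altogether",
                       nTrees = 300, seed = 7)$altogether$importance[1]
  permTops <- vapply(1:20, function(r) {
    set.seed(100 + r)
    annP <- toy$ann
    annP$class_label <- sample(annP$class_label)
    rankGenes(toy$m, annP, scheme = "altogether", nTrees = 300,
              seed = 7)$altogether$importance[1]
  }, numeric(1))
  expect_true(all(permTops < trueTop))
})

test_that("rankings on within-sample ranks are invariant to monotone transforms", {
  toy <- separableToy()
  rk1 <- rankGenes(toy$m, toy$ann, nTrees = 300, seed = 11)
  rk2 <- rankGenes(exp(toy$m / 10), toy$ann, nTrees = 300, seed = 11)
  expect_identical(rk1$altogether, rk2$altogether)
  expect_identical(rk1$perClass, rk2$perClass)
})

test_that("classes with fewer than two samples are rejected by name", {
  m <- toyMatrix(4, 3)
  ann <- data.frame(sample_id = colnames(m),
                    class_label = c("a", "a", "lonely"))
  expect_error(rankGenes(m, ann, nTrees = 50, seed = 1), "lonely")
})

test_that("top-gene selection unions the per-scheme lists", {
  fake <- list(scheme = "both",
               altogether = data.frame(feature = c("A", "B", "C", "D"),
                                       importance = 4:1),
               perClass = list(
                 x = data.frame(feature = c("B", "E", "A"), importance = 3:1),
                 y = data.frame(feature = c("F", "A", "B"), importance = 3:1)))
  expect_equal(selectTopGenes(fake, 2, 0), c("A", "B"), ignore_attr = TRUE)

  got <- selectTopGenes(fake, 2, 2)
  expect_setequal(got, c("A", "B", "E", "F"))
  expect_lt(length(got), 2 + 2 * 2)   # dedup across overlapping lists

  expect_error(selectTopGenes(fake, 10, 0), "depth")
})

test_that("top-gene union matches a brute-force set union on random rankings", {
  set.seed(5)
  for (rep in 1:20) {
    genes <- paste0("g", 1:12)
    fake <- list(
      altogether = data.frame(feature = sample(genes), importance = 12:1),
      perClass = lapply(setNames(nm = c("c1", "c2", "c3")), function(cl)
        data.frame(feature = sample(genes), importance = 12:1)))
    got <- selectTopGenes(fake, 5, 5)
    oracle <- unique(c(fake$altogether$feature[1:5],
                       unlist(lapply(fake$perClass, function(d) d$feature[1:5]))))
    expect_setequal(got, oracle)
  }
})

test_that("rule generation emits every unordered pair once, canonically", {
  expect_identical(nrow(generateRules(c("a", "b", "c"))), 3L)
  expect_identical(nrow(generateRules(paste0("g", 1:10))), 45L)
  expect_error(generateRules("solo"), ">= 2")

  for (n in c(2, 5, 9)) {
    genes <- paste0("G", sample(100, n))
    rules <- generateRules(genes)
    # enumeration oracle: nested loops over sorted symbols
    oracle <- character(0)
    gs <- sort(genes)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      oracle <- c(oracle, paste0(gs[i], "<", gs[j]))
    expect_setequal(ruleId(rules), oracle)
    expect_true(all(rules$gene_a < rules$gene_b))
  }
})

test_that("rule evaluation is the strict within-sample comparison, ties give 0", {
  m <- matrix(c(1, 2, 5, 5), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  rm <- evaluateRules(m, data.frame(gene_a = "A", gene_b = "B"))
  expect_identical(unname(ruleValues(rm)[, 1]), c(1L, 0L))
  expect_error(evaluateRules(m, data.frame(gene_a = "A", gene_b = "Z")), "Z")
})

test_that("rule evaluation matches the elementwise brute-force oracle", {
  set.seed(9)
  m <- toyMatrix(20, 10, seed = 9)
  rules <- generateRules(sample(rownames(m), 6))[1:15, ]
  rm <- evaluateRules(m, rules)
  for (r in seq_len(nrow(rules)))
    for (s in seq_len(ncol(m)))
      expect_identical(ruleValues(rm)[s, r],
                       as.integer(m[rules$gene_a[r], s] < m[rules$gene_b[r], s]))
})

test_that("rule activations are invariant to strictly increasing per-sample transforms", {
  m <- toyMatrix(15, 8, seed = 4)
  rules <- generateRules(rownames(m)[1:8])
  base <- ruleValues(evaluateRules(m, rules))
  expect_identical(ruleValues(evaluateRules(exp(m / 20), rules)), base)
  expect_identical(ruleValues(evaluateRules(2.5 * m + 3, rules)), base)
  ranked <- apply(m, 2, rank)
  expect_identical(ruleValues(evaluateRules(ranked, rules)), base)
})

test_that("rule ranking finds class-indicator rules and zeroes constant ones", {
  set.seed(6)
  n <- 40
  labels <- rep(c("pos", "neg"), each = n / 2)
  values <- cbind(ind = as.integer(labels == "pos"),
                  matrix(rbinom(n * 10, 1, 0.5), n, 10),
                  allone = 1L, allzero = 0L)
  rm <- toyRuleMatrix(values)
  ann <- data.frame(sample_id = rownames(ruleValues(rm)), class_label = labels)
  rr <- rankRules(rm, ann, nTrees = 300, seed = 2)
  indicator <- ruleId(rules(rm))[1]
  expect_identical(rr$perClass$pos$feature[1], indicator)
  expect_identical(rr$altogether$feature[1], indicator)
  constIds <- ruleId(rules(rm))[c(12, 13)]
  expect_equal(rr$altogether$importance[rr$altogether$feature %in% constIds],
               c(0, 0))
})

test_that("inverse-frequency weighting keeps rankings stable when the majority doubles", {
  set.seed(16)
  n <- 30
  labels <- rep(c("pos", "neg"), each = n / 2)
  values <- cbind(ind = as.integer(labels == "pos"),
                  matrix(rbinom(n * 8, 1, 0.5), n, 8))
  rm1 <- toyRuleMatrix(values)
  ann1 <- data.frame(sample_id = rownames(ruleValues(rm1)), class_label = labels)
  # double every majority-class sample
  dup <- ruleValues(rm1)[labels == "neg", ]
  rownames(dup) <- paste0(rownames(dup), "_dup")
  rm2 <- methods::new("RuleMatrix", values = rbind(ruleValues(rm1), dup),
                      rules = rules(rm1))
  ann2 <- rbind(ann1, data.frame(sample_id = rownames(dup), class_label = "neg"))
  r1 <- rankRules(rm1, ann1, classWeights = "inverse_frequency",
                  nTrees = 300, seed = 2)
  r2 <- rankRules(rm2, ann2, classWeights = "inverse_frequency",
                  nTrees = 300, seed = 2)
  expect_identical(r1$perClass$pos$feature[1], r2$perClass$pos$feature[1])
})

test_that("capped rule selection skips rules that would exceed the gene cap", {
  ranked <- list(altogether = data.frame(
    feature = c("A<B", "A<C", "D<E"), importance = c(3, 2, 1),
    gene_a = c("A", "A", "D"), gene_b = c("B", "C", "E")))
  sel <- selectRules(ranked, nAltogether = 10, nPerClass = 0,
                     geneRepetitionCap = 1)
  expect_identical(ruleId(sel), c("A<B", "D<E"))

  # inactive cap returns the top-n list unchanged
  sel2 <- selectRules(ranked, nAltogether = 3, nPerClass = 0,
                      geneRepetitionCap = Inf)
  expect_identical(ruleId(sel2), c("A<B", "A<C", "D<E"))
})

test_that("greedy capped selection matches a reimplemented greedy oracle", {
  set.seed(31)
  for (rep in 1:30) {
    genes <- paste0("g", sprintf("%02d", 1:8))
    pool <- generateRules(genes)
    pool <- pool[sample(nrow(pool), 12), ]
    pool$importance <- sort(runif(12), decreasing = TRUE)
    ranked <- list(altogether = cbind(feature = ruleId(pool), pool))
    cap <- 2
    sel <- selectRules(ranked, nAltogether = 8, nPerClass = 0,
                       geneRepetitionCap = cap)
    # oracle: literal greedy walk with a usage table
    use <- setNames(integer(8), genes); picked <- character(0)
    for (i in seq_len(nrow(pool))) {
      if (length(picked) >= 8) break
      ga <- pool$gene_a[i]; gb <- pool$gene_b[i]
      if (use[ga] >= cap || use[gb] >= cap) next
      use[ga] <- use[ga] + 1L; use[gb] <- use[gb] + 1L
      picked <- c(picked, paste0(ga, "<", gb))
    }
    expect_identical(ruleId(sel), picked)
    tab <- table(c(sel$gene_a, sel$gene_b))
    expect_true(all(tab <= cap))
  }
})

test_that("rule tables round-trip through TSV", {
  ranked <- list(altogether = data.frame(
    feature = c("A<B", "C<D"), importance = c(2, 1),
    gene_a = c("A", "C"), gene_b = c("B", "D")))
  sel <- selectRules(ranked, 2, 0, Inf)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRules(sel, path)
  back <- readRules(path)
  expect_equal(back$gene_a, sel$gene_a)
  expect_equal(back$importance, sel$importance)
  expect_true(all(is.na(back$class)))
})
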