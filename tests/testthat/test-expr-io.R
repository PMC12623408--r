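test_that("TSV/CSV expression round-trips preserve names, order and values", {
  m <- toyMatrix(3, 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(m, tsv)
  expect_identical(readExpression(tsv), m)

  csv <- withr::local_tempfile(fileext = ".csv")
  dt <- data.frame(gene = rownames(m), m, check.names = FALSE)
  data.table::fwrite(dt, csv)
  expect_identical(readExpression(csv), m)
})

test_that("duplicate gene rows are a hard error naming the gene", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "TP53\t1\t2", "GFAP\t3\t4", "TP53\t5\t6"), tsv)
  expect_error(readExpression(tsv), "TP53")
})

test_that("MTX triplet densifies to the brute-force dense matrix", {
  # 5 nonzeros over 4x3: densify by walking the triplet list directly
  i <- c(1, 2, 4, 3, 1); j <- c(1, 2, 3, 1, 3); x <- c(5, 7, 2, 1, 9)
  dense <- matrix(0, 4, 3)
  for (t in seq_along(i)) dense[i[t], j[t]] <- x[t]
  dimnames(dense) <- list(paste0("G", 1:4), paste0("C", 1:3))

  mtx <- withr::local_tempfile(fileext = ".mtx")
  gf <- withr::local_tempfile(); sf <- withr::local_tempfile()
  Matrix::writeMM(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(4, 3)), mtx)
  writeLines(rownames(dense), gf)
  writeLines(colnames(dense), sf)
  got <- readExpression(mtx, format = "mtx", genesFile = gf, samplesFile = sf)
  expect_equal(got, dense)
  expect_identical(sum(got == 0), 7L)
})

test_that("gene-id harmonization maps, drops unmapped, and applies collision policies", {
  m <- toyMatrix(2, 2, genes = c("ENSG1", "ENSG2"))
  map <- data.frame(source_id = "ENSG1", target_symbol = "TP53")
  out <- harmonizeGeneIds(m, map)
  expect_identical(rownames(out), "TP53")
  expect_identical(attr(out, "n_unmapped"), 1L)
  expect_equal(unname(out[1, ]), unname(m["ENSG1", ]))

  # two sources -> one symbol, policy sum: hand-summed 2x2 toy
  m2 <- matrix(c(1, 2, 3, 4), 2, 2,
               dimnames = list(c("E1", "E2"), c("S1", "S2")))
  map2 <- data.frame(source_id = c("E1", "E2"), target_symbol = "GFAP")
  expect_equal(unname(harmonizeGeneIds(m2, map2, "sum")[1, ]), c(3, 7))
  expect_error(harmonizeGeneIds(m2, map2, "error"), "GFAP")
  expect_identical(nrow(harmonizeGeneIds(m2, map2, "drop")), 0L)  # all collide

  # identity map leaves the matrix unchanged
  idMap <- data.frame(source_id = rownames(m), target_symbol = rownames(m))
  out3 <- harmonizeGeneIds(m, idMap)
  expect_equal(out3, m, ignore_attr = TRUE)
})

test_that("prevalence filter keeps exactly the genes at/above the threshold", {
  m <- matrix(1, 2, 5, dimnames = list(c("keep", "drop"), paste0("S", 1:5)))
  m["keep", 5] <- 0    # 4/5 nonzero, at the 0.8 boundary: kept (inclusive)
  m["drop", 3:5] <- 0  # 2/5
  out <- filterGenesByPrevalence(m, 0.8)
  expect_identical(rownames(out), "keep")

  allPos <- toyMatrix(6, 4) + 1
  expect_identical(filterGenesByPrevalence(allPos, 0.8), allPos)
})

test_that("prevalence filter matches the brute-force count oracle and is monotone in t", {
  set.seed(7)
  m <- toyMatrix(50, 20, seed = 7) * matrix(rbinom(1000, 1, 0.7), 50, 20)
  m <- m[rowSums(m) > 0, ]
  kept <- rownames(filterGenesByPrevalence(m, 0.8))
  oracle <- rownames(m)[vapply(seq_len(nrow(m)),
                               function(i) sum(m[i, ] > 0) >= ceiling(0.8 * 20),
                               logical(1))]
  expect_setequal(kept, oracle)

  prev <- NULL
  for (t in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
    cur <- tryCatch(rownames(filterGenesByPrevalence(m, t)),
                    error = function(e) character(0))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("merging studies intersects genes and copies values verbatim", {
  m1 <- toyMatrix(3, 2, genes = c("A", "B", "C"), samples = c("s1", "s2"))
  m2 <- toyMatrix(3, 2, seed = 2, genes = c("B", "C", "D"), samples = c("s3", "s4"))
  a1 <- toyAnnotation(m1, "x"); a2 <- toyAnnotation(m2, "y")
  out <- mergeStudies(list(m1, m2), list(a1, a2))
  expect_setequal(rownames(out$expr), c("B", "C"))
  for (g in c("B", "C")) {
    expect_identical(out$expr[g, c("s1", "s2")], m1[g, ])
    expect_identical(out$expr[g, c("s3", "s4")], m2[g, ])
  }
  expect_identical(out$annotation$sample_id, c("s1", "s2", "s3", "s4"))

  # self-merge under renamed samples: both blocks identical (no normalization)
  m1b <- m1; colnames(m1b) <- c("r1", "r2")
  a1b <- toyAnnotation(m1b, "x")
  both <- mergeStudies(list(m1, m1b), list(a1, a1b))
  expect_identical(both$expr[, c("s1", "s2")], both$expr[, c("r1", "r2")],
                   ignore_attr = TRUE)

  expect_error(mergeStudies(list(m1, m1), list(a1, a1)), "duplicate sample_id")
  m3 <- toyMatrix(2, 2, genes = c("X", "Y"), samples = c("q1", "q2"))
  expect_error(mergeStudies(list(m1, m3), list(a1, toyAnnotation(m3, "z"))),
               "empty gene intersection")
})

test_that("merged entries equal their source entries on random toys", {
  mats <- lapply(1:3, function(k)
    toyMatrix(6, 3, seed = k, samples = paste0("st", k, "_", 1:3)))
  anns <- lapply(mats, toyAnnotation, classes = "c")
  out <- mergeStudies(mats, anns)
  for (k in 1:3)
    for (s in colnames(mats[[k]]))
      expect_identical(out$expr[, s], mats[[k]][rownames(out$expr), s])
})

test_that("counts-to-TPM follows the length-normalized formula and conserves 1e6", {
  one <- matrix(c(17, 1), 1, 2, dimnames = list("G1", c("S1", "S2")))
  expect_equal(unname(countsToTPM(one, 1.5)[1, ]), c(1e6, 1e6))

  two <- matrix(c(10, 10), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
  tpm <- countsToTPM(two, c(G1 = 1, G2 = 2))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3))  # ratio 2:1, sums 1e6

  m <- toyMatrix(8, 5) + 1
  tpm2 <- countsToTPM(m, runif(8, 0.5, 5))
  expect_equal(unname(colSums(tpm2)), rep(1e6, 5), tolerance = 1e-6)

  mz <- m; mz[, 2] <- 0
  expect_error(countsToTPM(mz, rep(1, 8)), "S2")
})

test_that("matrices with missing values are rejected everywhere", {
  m <- toyMatrix(3, 3)
  m[2, 2] <- NA
  expect_error(filterGenesByPrevalence(m, 0.5), "missing")
  expect_error(evaluateRules(m, data.frame(gene_a = "G1", gene_b = "G2")),
               "missing")
})
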