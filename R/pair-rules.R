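## internal: one ranger importance fit, impurity scores
importanceFit <- function(x, y, nTrees, seed, caseWeights = NULL) {
  fit <- ranger::ranger(x = x, y = y, num.trees = nTrees,
                        importance = "impurity", seed = seed,
                        num.threads = 1, case.weights = caseWeights,
                        write.forest = FALSE)
  imp <- fit$variable.importance
  data.frame(feature = names(imp), importance = unname(imp),
             stringsAsFactors = FALSE)[order(-imp), , drop = FALSE]
}

## internal: shared two-scheme ranking over an arbitrary feature matrix
rankFeatures <- function(features, labels, scheme, nTrees, seed, stage,
                         caseWeights = NULL) {
  labels <- factor(labels)
  small <- names(which(table(labels) < 2))
  if (length(small))
    stop("class with fewer than 2 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)
  out <- list(scheme = scheme)
  if (scheme %in% c("altogether", "both")) {
    df <- importanceFit(features, labels, nTrees,
                        stageSeed(seed, paste0(stage, "_altogether")), caseWeights)
    rownames(df) <- NULL
    out$altogether <- df
  }
  if (scheme %in% c("one_vs_rest", "both")) {
    out$perClass <- lapply(setNames(nm = levels(labels)), function(cl) {
      y <- factor(ifelse(labels == cl, cl, "rest"), levels = c(cl, "rest"))
      df <- importanceFit(features, y, nTrees,
                          stageSeed(seed, paste0(stage, "_ovr_", cl)), caseWeights)
      rownames(df) <- NULL
      df
    })
  }
  out
}

#' Rank genes by Random-Forest importance
#'
#' Ranks genes by their impurity-based importance in a Random Forest trained
#' on each sample's within-column gene ranks (average ranks for ties), so the
#' ranking — like the downstream rules — sees only within-sample order, never
#' absolute expression. Two schemes: `"altogether"` ranks genes by their
#' ability to separate all classes jointly; `"one_vs_rest"` trains one binary
#' forest per class. `"both"` (default) computes both.
#'
#' @param m genes x samples matrix.
#' @param ann annotation data.frame (`sample_id`, `class_label`).
#' @param scheme `"both"`, `"altogether"` or `"one_vs_rest"`.
#' @param nTrees trees per importance forest (default 2000).
#' @param useWithinSampleRanks replace values by within-sample ranks first
#'   (default TRUE).
#' @param seed integer seed.
#' @return list with elements `scheme`, `altogether` (data.frame
#'   `feature`, `importance`, sorted descending) and/or `perClass` (named list
#'   of such data.frames).
#' @export
rankGenes <- function(m, ann, scheme = c("both", "altogether", "one_vs_rest"),
                      nTrees = 2000, useWithinSampleRanks = TRUE, seed) {
  scheme <- match.arg(scheme)
  assertExpressionMatrix(m, allow_negative = !useWithinSampleRanks)
  ann <- assertAnnotation(ann, m)
  features <- if (useWithinSampleRanks) t(apply(m, 2, rank)) else t(m)
  rankFeatures(features, ann$class_label, scheme, nTrees, seed, "rank_genes")
}

#' Select the top-ranked genes from both schemes
#'
#' Union (deduplicated) of the top `nAltogether` genes of the altogether
#' ranking and the top `nPerClass` genes of every one-vs-rest ranking.
#'
#' @param ranking output of [rankGenes()] (scheme `"both"` for both depths).
#' @param nAltogether genes from the altogether list (default 85).
#' @param nPerClass genes per class from the one-vs-rest lists (default 100).
#' @return character vector of genes; attribute `"provenance"` records source
#'   list and rank of each pick.
#' @export
selectTopGenes <- function(ranking, nAltogether = 85, nPerClass = 100) {
  prov <- list()
  if (nAltogether > 0) {
    if (is.null(ranking$altogether) || nrow(ranking$altogether) < nAltogether)
      stop("requested depth nAltogether=", nAltogether,
           " exceeds available genes", call. = FALSE)
    top <- head(ranking$altogether, nAltogether)
    prov[["altogether"]] <- data.frame(gene = top$feature, source = "altogether",
                                       rank = seq_len(nrow(top)))
  }
  if (nPerClass > 0) {
    if (is.null(ranking$perClass))
      stop("one-vs-rest rankings required for nPerClass > 0", call. = FALSE)
    for (cl in names(ranking$perClass)) {
      df <- ranking$perClass[[cl]]
      if (nrow(df) < nPerClass)
        stop("requested depth nPerClass=", nPerClass,
             " exceeds available genes for class ", cl, call. = FALSE)
      top <- head(df, nPerClass)
      prov[[cl]] <- data.frame(gene = top$feature, source = cl,
                               rank = seq_len(nrow(top)))
    }
  }
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  structure(unique(prov$gene), provenance = prov)
}

#' Generate all gene-pair rules
#'
#' All unordered pairs of the given genes, each emitted once in canonical
#' orientation (lexicographically smaller symbol as `gene_a`); the count is
#' `choose(n, 2)`.
#'
#' @param genes character vector of >= 2 gene symbols.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
generateRules <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 2) stop("need >= 2 genes to form pairs", call. = FALSE)
  cmb <- combn(genes, 2)
  data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Evaluate gene-pair rules within each sample
#'
#' Entry is 1 iff `value(gene_a) < value(gene_b)` strictly within that sample;
#' ties give 0. Comparisons are entirely within-sample, so the result is
#' invariant to any strictly increasing per-sample transform of the input.
#'
#' @param m genes x samples matrix.
#' @param rules data.frame with columns `gene_a`, `gene_b`.
#' @return A \linkS4class{RuleMatrix} (samples x rules).
#' @export
evaluateRules <- function(m, rules) {
  assertExpressionMatrix(m, allow_negative = TRUE)
  need <- unique(c(rules$gene_a, rules$gene_b))
  absent <- setdiff(need, rownames(m))
  if (length(absent))
    stop("rule genes absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  v <- t(m[rules$gene_a, , drop = FALSE] < m[rules$gene_b, , drop = FALSE]) * 1L
  dimnames(v) <- list(colnames(m), ruleId(rules))
  new("RuleMatrix", values = v, rules = as.data.frame(rules))
}

#' Rank rules by Random-Forest importance
#'
#' Same two ranking schemes as [rankGenes()], applied to the binary rule
#' features, with optional inverse-class-frequency sample weights to reduce
#' bias from class imbalance. Constant (all-0 or all-1) rule columns are
#' retained and receive zero importance.
#'
#' @param rm a \linkS4class{RuleMatrix}.
#' @param ann annotation data.frame.
#' @param scheme `"both"`, `"altogether"` or `"one_vs_rest"`.
#' @param classWeights `"inverse_frequency"` (default) or `"none"`.
#' @param nTrees trees per importance forest (default 500).
#' @param seed integer seed.
#' @return list as in [rankGenes()], features being rule ids; each data.frame
#'   additionally carries `gene_a`, `gene_b`.
#' @export
rankRules <- function(rm, ann, scheme = c("both", "altogether", "one_vs_rest"),
                      classWeights = c("inverse_frequency", "none"),
                      nTrees = 500, seed) {
  scheme <- match.arg(scheme)
  classWeights <- match.arg(classWeights)
  stopifnot(is(rm, "RuleMatrix"))
  ann <- ann[match(rownames(rm@values), ann$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("rule matrix rows do not match annotation", call. = FALSE)
  w <- caseWeights(ann$class_label, classWeights)
  out <- rankFeatures(rm@values, ann$class_label, scheme, nTrees, seed,
                      "rank_rules", caseWeights = w)
  decorate <- function(df) {
    i <- match(df$feature, ruleId(rm@rules))
    cbind(df, rm@rules[i, c("gene_a", "gene_b"), drop = FALSE],
          row.names = NULL)
  }
  if (!is.null(out$altogether)) out$altogether <- decorate(out$altogether)
  if (!is.null(out$perClass)) out$perClass <- lapply(out$perClass, decorate)
  out
}

#' Select top rules under a gene-repetition cap
#'
#' Greedy descent through each ranked list (altogether first, then each
#' one-vs-rest class list): a rule is skipped when it was already selected or
#' when selecting it would push either of its genes past
#' `geneRepetitionCap`; the walk continues deeper until the list has
#' contributed its quota or is exhausted.
#'
#' @param ranked output of [rankRules()].
#' @param nAltogether rules from the altogether list (default 100).
#' @param nPerClass rules per class (default 100).
#' @param geneRepetitionCap maximum selections any one gene may appear in
#'   (default 1; `Inf` disables the cap).
#' @return data.frame of selected rules with provenance columns `scheme`,
#'   `class`, `rank`, `importance`; a warning is issued for any list that
#'   contributes zero rules.
#' @export
selectRules <- function(ranked, nAltogether = 100, nPerClass = 100,
                        geneRepetitionCap = 1) {
  stopifnot(geneRepetitionCap >= 1)
  geneUse <- new.env(parent = emptyenv())
  useOf <- function(g) if (is.null(geneUse[[g]])) 0L else geneUse[[g]]
  chosen <- list()
  chosenIds <- character(0)

  takeFrom <- function(df, quota, schemeName, className) {
    got <- 0L
    for (i in seq_len(nrow(df))) {
      if (got >= quota) break
      ga <- df$gene_a[i]; gb <- df$gene_b[i]
      id <- paste0(ga, "<", gb)
      if (id %in% chosenIds) next
      if (useOf(ga) >= geneRepetitionCap || useOf(gb) >= geneRepetitionCap) next
      geneUse[[ga]] <- useOf(ga) + 1L
      geneUse[[gb]] <- useOf(gb) + 1L
      chosenIds <<- c(chosenIds, id)
      chosen[[length(chosen) + 1L]] <<- data.frame(
        gene_a = ga, gene_b = gb, scheme = schemeName, class = className,
        rank = i, importance = df$importance[i], stringsAsFactors = FALSE)
      got <- got + 1L
    }
    if (got == 0L && quota > 0 && nrow(df) > 0)
      warning("list ", schemeName, if (!is.na(className)) paste0("/", className),
              " contributed zero rules under geneRepetitionCap=",
              geneRepetitionCap, call. = FALSE)
    invisible(got)
  }

  if (!is.null(ranked$altogether) && nAltogether > 0)
    takeFrom(ranked$altogether, nAltogether, "altogether", NA_character_)
  if (!is.null(ranked$perClass) && nPerClass > 0)
    for (cl in sort(names(ranked$perClass)))
      takeFrom(ranked$perClass[[cl]], nPerClass, "one_vs_rest", cl)

  sel <- do.call(rbind, chosen)
  if (is.null(sel)) stop("no rule selected", call. = FALSE)
  counts <- table(c(sel$gene_a, sel$gene_b))
  stopifnot(all(counts <= geneRepetitionCap))   # cap invariant
  rownames(sel) <- NULL
  sel
}

#' Serialize a rule table to TSV (lossless round trip)
#'
#' @param rules data.frame of rules (selection output or plain pairs).
#' @param path output path.
#' @export
writeRules <- function(rules, path) {
  data.table::fwrite(rules, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writeRules
#' @export
readRules <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = "NA")
}
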