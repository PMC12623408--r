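#' RuleMatrix: binary gene-pair rule activations
#'
#' Samples x rules binary matrix obtained by evaluating gene-pair rules
#' ("expression of `gene_a` < expression of `gene_b`") within each sample.
#' Entries are 1 when the strict inequality holds and 0 otherwise (ties give
#' 0). Columns correspond one-to-one with the rows of the rule table.
#'
#' @slot values integer matrix, samples x rules, entries in \{0, 1\}.
#' @slot rules data.frame with at least columns `gene_a` and `gene_b`
#'   (distinct symbols, canonical orientation), plus optional provenance
#'   columns (`scheme`, `class`, `rank`, `importance`).
#' @seealso [evaluateRules()], [generateRules()]
#' @export
setClass("RuleMatrix",
  representation(values = "matrix", rules = "data.frame"))

setValidity("RuleMatrix", function(object) {
  v <- object@values
  r <- object@rules
  msg <- character()
  if (!all(c("gene_a", "gene_b") %in% names(r)))
    msg <- c(msg, "rules must have columns gene_a, gene_b")
  else {
    if (any(r$gene_a == r$gene_b)) msg <- c(msg, "gene_a must differ from gene_b")
    if (anyDuplicated(ruleId(r))) msg <- c(msg, "duplicate rules")
  }
  if (ncol(v) != nrow(r)) msg <- c(msg, "ncol(values) must equal nrow(rules)")
  if (length(v) && !all(v %in% c(0L, 1L))) msg <- c(msg, "values must be 0/1")
  if (is.null(rownames(v))) msg <- c(msg, "values must have sample rownames")
  if (length(msg)) msg else TRUE
})

#' Canonical rule identifier
#'
#' @param rules data.frame with columns `gene_a`, `gene_b`.
#' @return Character vector `"gene_a<gene_b"`.
#' @export
ruleId <- function(rules) paste0(rules$gene_a, "<", rules$gene_b)

#' Number of rules
#' @param x a `RuleMatrix`
#' @export
setGeneric("ruleCount", function(x) standardGeneric("ruleCount"))

#' @rdname ruleCount
#' @export
setMethod("ruleCount", "RuleMatrix", function(x) nrow(x@rules))

#' Rule table accessor
#' @param x a `RuleMatrix` or `RuleForest`
#' @return data.frame of gene-pair rules with provenance columns.
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname rules
#' @export
setMethod("rules", "RuleMatrix", function(x) x@rules)

#' Binary rule activation values
#' @param x a `RuleMatrix`
#' @return integer samples x rules matrix.
#' @export
setGeneric("ruleValues", function(x) standardGeneric("ruleValues"))

#' @rdname ruleValues
#' @export
setMethod("ruleValues", "RuleMatrix", function(x) x@values)

setMethod("show", "RuleMatrix", function(object) {
  cat("RuleMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "rules\n")
  cat("  mean activation:",
      if (length(object@values)) signif(mean(object@values), 3) else NA, "\n")
})

#' RuleForest: a trained gene-pair-rule probability forest
#'
#' Bundles the final rule list, the fitted probability forest over binary rule
#' features, the class set, per-rule training-majority values used to impute
#' rules whose genes are absent at prediction time, the training rule matrix
#' (for auditing, proximity and imputation), and training metadata.
#'
#' @slot rules data.frame of final rules (after selection and pruning).
#' @slot forest the fitted `ranger` probability forest.
#' @slot classes character vector of class labels.
#' @slot ruleMajority integer vector, per-rule majority activation over the
#'   training samples (ties resolve to 0, matching the rule tie policy).
#' @slot trainRuleMatrix the training `RuleMatrix` values.
#' @slot trainLabels factor of training class labels.
#' @slot metadata list: seed, parameters, Boruta verdicts, package version.
#' @seealso [trainRuleForest()], [predictScores()], [writeRuleForest()]
#' @export
setClass("RuleForest",
  representation(rules = "data.frame", forest = "ANY", classes = "character",
                 ruleMajority = "integer", trainRuleMatrix = "matrix",
                 trainLabels = "factor", metadata = "list"))

setValidity("RuleForest", function(object) {
  msg <- character()
  if (!length(object@classes)) msg <- c(msg, "class list must be non-empty")
  if (length(object@ruleMajority) != nrow(object@rules))
    msg <- c(msg, "one majority value per rule required")
  if (ncol(object@trainRuleMatrix) != nrow(object@rules))
    msg <- c(msg, "training rule matrix must have one column per rule")
  if (length(msg)) msg else TRUE
})

#' @rdname rules
#' @export
setMethod("rules", "RuleForest", function(x) x@rules)

#' Class labels of a trained model or score object
#' @param x a `RuleForest` or `PredictionScores`
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "RuleForest", function(x) x@classes)

setMethod("show", "RuleForest", function(object) {
  cat("RuleForest:", nrow(object@rules), "gene-pair rules,",
      object@forest$num.trees, "trees,",
      length(object@classes), "classes\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  trained on", nrow(object@trainRuleMatrix), "samples; seed",
      object@metadata$seed %||% NA, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PredictionScores: per-class probability scores
#'
#' Samples x classes matrix of tree-vote fractions from a \linkS4class{RuleForest},
#' together with the number of imputed rules per sample. Rows sum to one.
#'
#' @slot scores numeric matrix, samples x classes, rows summing to 1.
#' @slot nImputed integer vector, per-sample count of imputed rules.
#' @seealso [predictScores()], [scoreTable()]
#' @export
setClass("PredictionScores",
  representation(scores = "matrix", nImputed = "integer"))

setValidity("PredictionScores", function(object) {
  s <- object@scores
  msg <- character()
  if (length(s)) {
    if (any(s < -1e-12) || any(s > 1 + 1e-12)) msg <- c(msg, "scores outside [0,1]")
    if (any(abs(rowSums(s) - 1) > 1e-9)) msg <- c(msg, "score rows must sum to 1")
  }
  if (length(object@nImputed) != nrow(s))
    msg <- c(msg, "one imputed-rule count per sample required")
  if (length(msg)) msg else TRUE
})

#' Score matrix accessor
#' @param x a `PredictionScores`
#' @return numeric samples x classes matrix.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "PredictionScores", function(x) x@scores)

#' @rdname classLabels
#' @export
setMethod("classLabels", "PredictionScores", function(x) colnames(x@scores))

#' Per-sample imputed-rule counts
#' @param x a `PredictionScores`
#' @export
setGeneric("nImputed", function(x) standardGeneric("nImputed"))

#' @rdname nImputed
#' @export
setMethod("nImputed", "PredictionScores", function(x) x@nImputed)

setMethod("show", "PredictionScores", function(object) {
  cat("PredictionScores:", nrow(object@scores), "samples x",
      ncol(object@scores), "classes\n")
  if (any(object@nImputed > 0))
    cat("  imputed rules per sample:", paste(range(object@nImputed), collapse = "-"), "\n")
})

#' KmerIndex: canonical k-mer membership over two references
#'
#' Maps every canonical k-mer (lexicographic minimum of a k-mer and its
#' reverse complement) occurring in either of two reference sequence sets to a
#' membership flag: specific to reference A, specific to reference B, or
#' shared.
#'
#' @slot k odd integer k-mer length.
#' @slot flags integer vector named by canonical k-mer; 1 = A only,
#'   2 = B only, 3 = both.
#' @slot refA,refB character, names of the two references.
#' @seealso [buildKmerIndex()], [classifyReads()]
#' @export
setClass("KmerIndex",
  representation(k = "integer", flags = "integer",
                 refA = "character", refB = "character"))

setValidity("KmerIndex", function(object) {
  msg <- character()
  if (object@k %% 2L == 0L || object@k < 11L)
    msg <- c(msg, "k must be odd and >= 11")
  if (length(object@flags) && !all(object@flags %in% 1:3))
    msg <- c(msg, "flags must be 1 (A only), 2 (B only) or 3 (both)")
  if (length(msg)) msg else TRUE
})

#' The k-mer length of an index
#' @param x a `KmerIndex`
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname kmerSize
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)

setMethod("show", "KmerIndex", function(object) {
  tab <- tabulate(object@flags, 3L)
  cat("KmerIndex: k =", object@k, "\n")
  cat(sprintf("  %s-specific: %d | %s-specific: %d | shared: %d\n",
              object@refA, tab[1], object@refB, tab[2], tab[3]))
})

#' ReadOriginSummary: per-category read counts for two-reference classification
#'
#' Counts over the categories `a_only`, `b_only`, `both`, `neither`,
#' `ambiguous`; categories partition the read set.
#'
#' @slot counts named integer vector over the five categories.
#' @slot refA,refB character reference names.
#' @seealso [classifyReads()]
#' @export
setClass("ReadOriginSummary",
  representation(counts = "integer", refA = "character", refB = "character"))

readCategories <- c("a_only", "b_only", "both", "neither", "ambiguous")

setValidity("ReadOriginSummary", function(object) {
  if (!identical(names(object@counts), readCategories))
    "counts must be named a_only, b_only, both, neither, ambiguous" else TRUE
})

#' Per-category read counts / percentages
#' @param x a `ReadOriginSummary`
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname readCounts
#' @export
setMethod("readCounts", "ReadOriginSummary", function(x) x@counts)

#' @rdname readCounts
#' @export
setGeneric("readPercentages", function(x) standardGeneric("readPercentages"))

#' @rdname readCounts
#' @export
setMethod("readPercentages", "ReadOriginSummary",
          function(x) 100 * x@counts / sum(x@counts))

setMethod("show", "ReadOriginSummary", function(object) {
  pct <- readPercentages(object)
  cat("ReadOriginSummary (", sum(object@counts), " reads; A = ", object@refA,
      ", B = ", object@refB, ")\n", sep = "")
  for (cat_ in readCategories)
    cat(sprintf("  %-9s %7d  %6.2f%%\n", cat_, object@counts[[cat_]], pct[[cat_]]))
})
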