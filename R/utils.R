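#' @importFrom methods new validObject is slot setValidity show
#' @importFrom ranger ranger
#' @importFrom stats rnbinom rbinom runif rnorm binom.test p.adjust setNames predict
#' @importFrom utils head packageVersion combn
NULL

#' Derive a per-stage random seed from a pipeline-level seed
#'
#' Every stochastic stage draws its seed from one pipeline seed plus a stage
#' name, so adding or reordering stages never perturbs another stage's random
#' stream. The expansion is a small modular string hash, kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed integer pipeline-level seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stageSeed(1L, "rank_genes")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647           # 2^31 - 1, prime; products stay exact in doubles
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 7919) %% m)
}

## internal: validate a genes x samples expression matrix
assertExpressionMatrix <- function(m, allow_negative = FALSE, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(what, ": duplicate gene ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(what, ": duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop(what, " contains missing or non-finite values; complete matrices are required",
         call. = FALSE)
  if (!allow_negative && any(m < 0))
    stop(what, " contains negative values", call. = FALSE)
  invisible(m)
}

## internal: validate a sample annotation data.frame against a matrix
assertAnnotation <- function(ann, m = NULL) {
  need <- c("sample_id", "class_label")
  if (!is.data.frame(ann) || !all(need %in% names(ann)))
    stop("annotation must be a data.frame with columns sample_id, class_label",
         " (and optionally study_id)", call. = FALSE)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(m)) {
    if (!setequal(colnames(m), ann$sample_id))
      stop("annotation sample_ids do not match matrix columns", call. = FALSE)
    ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  }
  ann
}

## internal: per-sample case weights
caseWeights <- function(labels, classWeights = c("inverse_frequency", "none")) {
  classWeights <- match.arg(classWeights)
  if (classWeights == "none") return(rep(1, length(labels)))
  tab <- table(labels)
  unname(1 / as.numeric(tab[as.character(labels)]))
}

## internal: macro-averaged balanced accuracy from hard labels
macroBalancedAccuracy <- function(predicted, truth) {
  lev <- sort(unique(as.character(truth)))
  ba <- vapply(lev, function(cl) {
    pos <- truth == cl
    sens <- if (any(pos)) mean(predicted[pos] == cl) else NA_real_
    spec <- if (any(!pos)) mean(predicted[!pos] != cl) else NA_real_
    (sens + spec) / 2
  }, numeric(1))
  mean(ba, na.rm = TRUE)
}
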