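#' Stratified train/test split
#'
#' Splits samples per class, taking `floor(trainFraction * n)` of each class
#' (at least one sample on each side), so the partitions are disjoint, cover
#' all samples, and preserve class composition as closely as integer rounding
#' allows.
#'
#' @param ann annotation data.frame (`sample_id`, `class_label`).
#' @param trainFraction fraction in (0, 1); default 0.6.
#' @param seed integer seed.
#' @return `list(train, test)` of sample ids.
#' @export
stratifiedSplit <- function(ann, trainFraction = 0.6, seed) {
  ann <- assertAnnotation(ann)
  stopifnot(trainFraction > 0, trainFraction < 1)
  sizes <- table(ann$class_label)
  if (any(sizes < 2))
    stop("class of size 1 cannot be split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  set.seed(stageSeed(seed, "split"))
  train <- character(0)
  for (cl in names(sizes)) {
    ids <- ann$sample_id[ann$class_label == cl]
    nTrain <- min(max(floor(trainFraction * length(ids)), 1L), length(ids) - 1L)
    train <- c(train, sample(ids, nTrain))
  }
  list(train = train, test = setdiff(ann$sample_id, train))
}

#' Confusion-matrix performance report
#'
#' One-vs-rest sensitivity, specificity, balanced accuracy and F1 per class;
#' overall accuracy with an exact (Clopper-Pearson) 95% binomial confidence
#' interval; the no-information rate (largest class frequency) and its
#' one-sided binomial p-value `P(Binomial(n, NIR) >= correct)`.
#'
#' @param predicted character/factor of predicted labels.
#' @param truth character/factor of true labels, aligned with `predicted`.
#' @return list of class `"confusion_report"`: `table` (raw counts,
#'   predictions x truth), `perClass` (data.frame of per-class metrics;
#'   classes present only in predictions are flagged in
#'   `prediction_only_labels`), `overall` (accuracy, ciLower, ciUpper, nir,
#'   nirPValue, n, correct).
#' @export
confusionReport <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  lev <- sort(unique(c(predicted, truth)))
  predictionOnly <- setdiff(unique(predicted), unique(truth))
  tab <- table(factor(predicted, lev), factor(truth, lev),
               dnn = c("predicted", "truth"))
  n <- length(truth)
  correct <- sum(diag(tab))
  acc <- correct / n
  ci <- stats::binom.test(correct, n)$conf.int
  nir <- max(table(factor(truth, lev))) / n
  pval <- stats::binom.test(correct, n, p = nir, alternative = "greater")$p.value

  trueLev <- sort(unique(truth))
  perClass <- do.call(rbind, lapply(trueLev, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fn <- sum(predicted != cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    tn <- sum(predicted != cl & truth != cl)
    sens <- tp / (tp + fn)
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens) else NA_real_
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               balancedAccuracy = (sens + spec) / 2, f1 = f1,
               n = tp + fn, stringsAsFactors = FALSE)
  }))
  rownames(perClass) <- NULL
  structure(list(table = tab, perClass = perClass,
                 overall = list(accuracy = acc, ciLower = ci[1], ciUpper = ci[2],
                                nir = nir, nirPValue = pval, n = n,
                                correct = correct),
                 prediction_only_labels = predictionOnly),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Accuracy %.4f (95%% CI %.4f-%.4f), NIR %.4f, p(acc > NIR) %.3g\n",
              o$accuracy, o$ciLower, o$ciUpper, o$nir, o$nirPValue))
  print(x$perClass, digits = 4)
  if (length(x$prediction_only_labels))
    cat("labels predicted but absent from truth:",
        paste(x$prediction_only_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-sample score table
#'
#' Long-format table backing per-class score barplots: one row per
#' (sample, class) with the score, a `top_class` flag (row maximum; ties
#' broken lexicographically and flagged in `is_tie`), and the per-sample
#' imputed-rule count. Rows are ordered by sample then class.
#'
#' @param ps a \linkS4class{PredictionScores}.
#' @param ann optional annotation; adds a `true_class` column.
#' @return data.frame (`sample`, `class`, `score`, `top_class`, `is_tie`,
#'   `imputed_rule_count` and optionally `true_class`).
#' @export
scoreTable <- function(ps, ann = NULL) {
  stopifnot(is(ps, "PredictionScores"))
  s <- ps@scores
  cls <- sort(colnames(s))
  s <- s[, cls, drop = FALSE]
  rowMax <- apply(s, 1, max)
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    top <- cls[s[i, ] == rowMax[i]]
    data.frame(sample = rownames(s)[i], class = cls, score = as.numeric(s[i, ]),
               top_class = cls == top[1],            # lexicographic tie-break
               is_tie = length(top) > 1,
               imputed_rule_count = ps@nImputed[i], stringsAsFactors = FALSE)
  }))
  if (!is.null(ann))
    out$true_class <- ann$class_label[match(out$sample, ann$sample_id)]
  rownames(out) <- NULL
  out[order(out$sample, out$class), , drop = FALSE]
}

#' Hard labels from prediction scores
#'
#' Argmax per sample with lexicographic tie-break.
#'
#' @param ps a \linkS4class{PredictionScores}.
#' @return named character vector of predicted classes.
#' @export
hardLabels <- function(ps) {
  s <- ps@scores[, sort(colnames(ps@scores)), drop = FALSE]
  setNames(colnames(s)[max.col(s, ties.method = "first")], rownames(s))
}
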