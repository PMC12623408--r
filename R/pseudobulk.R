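#' Aggregate single-cell counts into pseudo-bulk profiles
#'
#' Sums (or averages) counts over all cells sharing a
#' (`donor_or_sample_id`, `cell_type_label`) annotation, producing one
#' bulk-like column per group with at least `minCells` cells. With
#' `statistic = "sum"` total counts are conserved exactly. Per-group cell
#' counts are always reported, because small groups yield unstable downstream
#' predictions and must be visible to the analyst.
#'
#' @param counts genes x cells matrix (dense or sparse `dgCMatrix`).
#' @param ann data.frame with columns `cell_id`, `donor_or_sample_id`,
#'   `cell_type_label`; every cell must be annotated.
#' @param minCells minimum cells per retained group (default 1).
#' @param statistic `"sum"` (default, count-conserving) or `"mean"`.
#' @return list: `expr` (dense genes x groups matrix, columns named
#'   `donor.celltype`), `groups` (data.frame `group`,
#'   `donor_or_sample_id`, `cell_type_label`, `n_cells` for retained groups),
#'   `dropped` (same columns for groups below `minCells`).
#' @export
aggregatePseudobulk <- function(counts, ann, minCells = 1,
                                statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  need <- c("cell_id", "donor_or_sample_id", "cell_type_label")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation column absent: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$cell_id)) stop("duplicate cell_id", call. = FALSE)
  if (is.null(colnames(counts))) stop("counts must have cell colnames", call. = FALSE)
  unann <- setdiff(colnames(counts), ann$cell_id)
  if (length(unann))
    stop("cells without annotation: ", paste(head(unann, 5), collapse = ", "),
         call. = FALSE)
  ann <- ann[match(colnames(counts), ann$cell_id), , drop = FALSE]

  group <- paste(ann$donor_or_sample_id, ann$cell_type_label, sep = ".")
  groups <- unique(data.frame(group = group,
                              donor_or_sample_id = ann$donor_or_sample_id,
                              cell_type_label = ann$cell_type_label,
                              stringsAsFactors = FALSE))
  groups$n_cells <- as.integer(table(group)[groups$group])
  groups <- groups[order(groups$group), , drop = FALSE]
  rownames(groups) <- NULL

  gf <- factor(group, levels = groups$group)
  ind <- Matrix::sparseMatrix(i = seq_along(gf), j = as.integer(gf), x = 1,
                              dims = c(length(gf), nlevels(gf)))
  expr <- as.matrix(counts %*% ind)
  colnames(expr) <- groups$group
  if (statistic == "mean")
    expr <- sweep(expr, 2, groups$n_cells, "/")

  keep <- groups$n_cells >= minCells
  list(expr = expr[, keep, drop = FALSE],
       groups = groups[keep, , drop = FALSE],
       dropped = groups[!keep, , drop = FALSE])
}
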