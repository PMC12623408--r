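#' Read an expression matrix
#'
#' Reads a genes x samples expression matrix from TSV/CSV (first column gene
#' symbol, header row of sample ids) or from a MatrixMarket coordinate triplet
#' with sidecar gene/sample name files (one name per line). Row and column
#' order are preserved from the file; duplicate gene symbols are a hard error.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @param genesFile,samplesFile sidecar name files, required for `"mtx"`.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
readExpression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                           genesFile = NULL, samplesFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    if (is.null(genesFile) || is.null(samplesFile))
      stop("MTX input requires genesFile and samplesFile sidecars", call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesFile)
    samples <- readLines(samplesFile)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("MTX dimensions do not match sidecar name files", call. = FALSE)
    dimnames(m) <- list(genes, samples)
  } else {
    dt <- tryCatch(
      data.table::fread(path, sep = if (format == "csv") "," else "\t",
                        header = TRUE, data.table = FALSE),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (ncol(dt) < 2) stop("parse error in ", path,
                           ": need gene column plus >= 1 sample", call. = FALSE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  }
  assertExpressionMatrix(m, what = path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m genes x samples matrix.
#' @param path output path.
#' @param geneColumn name of the first (gene symbol) column.
#' @export
writeExpression <- function(m, path, geneColumn = "gene") {
  assertExpressionMatrix(m)
  dt <- data.table::data.table(gene = rownames(m))
  data.table::setnames(dt, "gene", geneColumn)
  out <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' TSV with columns `sample_id`, `class_label` and (optionally) `study_id`.
#'
#' @param path file path.
#' @return data.frame annotation.
#' @export
readSampleAnnotation <- function(path) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = "character")
  assertAnnotation(ann)
}

#' @rdname readSampleAnnotation
#' @param ann annotation data.frame.
#' @export
writeSampleAnnotation <- function(ann, path) {
  assertAnnotation(ann)
  data.table::fwrite(ann, path, sep = "\t")
  invisible(path)
}

#' Map gene identifiers to HUGO-style symbols
#'
#' Applies a user-supplied two-column identifier map (e.g. Ensembl id to HUGO
#' symbol) to the rows of an expression matrix. Genes without a mapping are
#' dropped (their number is recorded in the `"n_unmapped"` attribute). When
#' several source ids map to the same target symbol the `collisionPolicy`
#' decides: `"sum"` (element-wise sum; counts are additive), `"drop"` (remove
#' all colliding symbols), or `"error"`.
#'
#' @param m genes x samples matrix.
#' @param map data.frame with columns `source_id`, `target_symbol` (extra
#'   columns ignored; duplicated `source_id` rows are de-duplicated keeping
#'   the first).
#' @param collisionPolicy `"sum"`, `"drop"` or `"error"`.
#' @return Re-keyed matrix; attributes `n_unmapped` and `collisions`.
#' @export
harmonizeGeneIds <- function(m, map, collisionPolicy = c("sum", "drop", "error")) {
  collisionPolicy <- match.arg(collisionPolicy)
  assertExpressionMatrix(m)
  if (is.matrix(map)) map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (ncol(map) < 2) stop("map needs two columns: source_id, target_symbol", call. = FALSE)
  names(map)[1:2] <- c("source_id", "target_symbol")
  map <- map[!duplicated(map$source_id), , drop = FALSE]

  target <- map$target_symbol[match(rownames(m), map$source_id)]
  mapped <- !is.na(target)
  if (!any(mapped)) stop("map covers no gene of the matrix", call. = FALSE)
  nUnmapped <- sum(!mapped)
  m2 <- m[mapped, , drop = FALSE]
  sym <- target[mapped]

  collided <- unique(sym[duplicated(sym)])
  if (length(collided)) {
    if (collisionPolicy == "error")
      stop("gene symbol collisions after mapping: ",
           paste(collided, collapse = ", "), call. = FALSE)
    if (collisionPolicy == "drop") {
      keep <- !(sym %in% collided)
      m2 <- m2[keep, , drop = FALSE]
      sym <- sym[keep]
    } else {
      m2 <- rowsum(m2, group = sym, reorder = FALSE)
      sym <- rownames(m2)
    }
  }
  rownames(m2) <- sym
  structure(m2, n_unmapped = nUnmapped, collisions = collided)
}

#' Filter genes by non-zero prevalence
#'
#' Keeps exactly the genes whose fraction of strictly positive entries is at
#' least `minNonzeroFraction` (inclusive threshold). The sample set is
#' unchanged.
#'
#' @param m genes x samples matrix.
#' @param minNonzeroFraction threshold in (0, 1]; default 0.8.
#' @return Filtered matrix.
#' @export
filterGenesByPrevalence <- function(m, minNonzeroFraction = 0.8) {
  assertExpressionMatrix(m)
  stopifnot(minNonzeroFraction > 0, minNonzeroFraction <= 1)
  frac <- rowMeans(m > 0)
  keep <- frac >= minNonzeroFraction
  if (!any(keep))
    stop("no gene passes the prevalence filter; lower minNonzeroFraction",
         call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Merge expression matrices from several studies
#'
#' Restricts all matrices to the intersection of their gene sets and binds the
#' sample columns. Values are copied verbatim: no scaling, normalization or
#' batch correction is applied, because downstream gene-pair rules compare
#' expression only within samples, never across them.
#'
#' @param matrices list of genes x samples matrices.
#' @param annotations list of matching annotation data.frames.
#' @return `list(expr = matrix, annotation = data.frame)`.
#' @export
mergeStudies <- function(matrices, annotations) {
  stopifnot(is.list(matrices), length(matrices) >= 2,
            is.list(annotations), length(annotations) == length(matrices))
  for (i in seq_along(matrices)) {
    assertExpressionMatrix(matrices[[i]], what = paste0("matrix ", i))
    annotations[[i]] <- assertAnnotation(annotations[[i]], matrices[[i]])
  }
  allSamples <- unlist(lapply(matrices, colnames), use.names = FALSE)
  if (anyDuplicated(allSamples))
    stop("duplicate sample_id across studies: ",
         paste(unique(allSamples[duplicated(allSamples)]), collapse = ", "),
         call. = FALSE)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(genes)) stop("empty gene intersection across studies", call. = FALSE)
  expr <- do.call(cbind, lapply(matrices, function(x) x[genes, , drop = FALSE]))
  ann <- do.call(rbind, lapply(annotations, function(a)
    a[, intersect(c("sample_id", "class_label", "study_id"), names(a)), drop = FALSE]))
  rownames(ann) <- NULL
  list(expr = expr, annotation = ann)
}

#' Convert raw counts to transcripts per million
#'
#' `TPM_g = 1e6 * (count_g / len_g) / sum_h(count_h / len_h)` per sample;
#' every output column sums to one million.
#'
#' @param m genes x samples count matrix.
#' @param geneLengthsKb positive gene lengths in kilobases, named by gene or
#'   in row order.
#' @return TPM matrix.
#' @export
countsToTPM <- function(m, geneLengthsKb) {
  assertExpressionMatrix(m)
  if (!is.null(names(geneLengthsKb))) {
    if (!all(rownames(m) %in% names(geneLengthsKb)))
      stop("gene lengths missing for: ",
           paste(head(setdiff(rownames(m), names(geneLengthsKb)), 5), collapse = ", "),
           call. = FALSE)
    geneLengthsKb <- geneLengthsKb[rownames(m)]
  }
  stopifnot(length(geneLengthsKb) == nrow(m), all(geneLengthsKb > 0))
  rate <- m / geneLengthsKb
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("zero column total for sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(rate, 2, tot, "/") * 1e6
}
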