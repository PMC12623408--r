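#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' generator emulates the statistical structure the classifier is built for:
#' several cell classes with disjoint marker-gene sets, several studies with
#' gene-wise multiplicative batch distortions (a strictly monotone
#' within-sample transform family, under which gene-pair rules are invariant),
#' negative-binomial count noise, class imbalance, and optionally single-cell
#' dropout.
#'
#' Defaults mirror a multi-study brain cell-type design: five classes with the
#' imbalanced per-class sample counts 32/27/140/13/46 (astrocyte, endothelial,
#' microglia, monocyte, neuron; 258 samples over five studies), a marker
#' log-effect of 2 natural-log units and a between-study batch sigma of 0.5.
#'
#' @param classes character vector of class labels.
#' @param nGenes total number of genes.
#' @param nMarkersPerClass markers per class (disjoint blocks).
#' @param markerEffect marker elevation, natural-log units (default 2).
#' @param nSamplesPerClass integer vector (recycled or named by class).
#' @param nStudies number of studies (samples cycle through studies).
#' @param batchSigma sd of gene-wise log-normal per-study scale factors.
#' @param librarySize length-2 range of per-sample library sizes.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param nCellsPerClass cells per class for single-cell simulation.
#' @param cellLibrarySize length-2 range of per-cell library sizes.
#' @param dropout single-cell Bernoulli dropout rate in [0, 1).
#' @param seed mandatory integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A validated list of class `"simulation_config"`.
#' @export
simulationConfig <- function(classes = c("astrocyte", "endothelial", "microglia",
                                         "monocyte", "neuron"),
                             nGenes = 400L, nMarkersPerClass = 20L,
                             markerEffect = 2,
                             nSamplesPerClass = c(astrocyte = 32L, endothelial = 27L,
                                                  microglia = 140L, monocyte = 13L,
                                                  neuron = 46L),
                             nStudies = 5L, batchSigma = 0.5,
                             librarySize = c(2e5, 5e5), dispersion = 0.1,
                             nCellsPerClass = 200L,
                             cellLibrarySize = c(1000, 5000),
                             dropout = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  classes <- as.character(classes)
  if (length(classes) < 1 || anyDuplicated(classes))
    stop("classes must be unique and non-empty", call. = FALSE)
  if (nGenes < 1 || nMarkersPerClass < 0 ||
      nMarkersPerClass * length(classes) > nGenes)
    stop("degenerate config: need nGenes >= nMarkersPerClass * n classes >= 0",
         call. = FALSE)
  if (!is.null(names(nSamplesPerClass)) &&
      !setequal(names(nSamplesPerClass), classes))
    nSamplesPerClass <- rep_len(unname(nSamplesPerClass), length(classes))
  n <- rep_len(as.integer(nSamplesPerClass), length(classes))
  if (!is.null(names(nSamplesPerClass)) && setequal(names(nSamplesPerClass), classes))
    n <- as.integer(nSamplesPerClass[classes])
  names(n) <- classes
  stopifnot(all(n >= 1), nStudies >= 1, batchSigma >= 0,
            length(librarySize) == 2, all(librarySize > 0),
            dispersion > 0, dropout >= 0, dropout < 1,
            nCellsPerClass >= 0, length(cellLibrarySize) == 2,
            all(cellLibrarySize > 0), markerEffect >= 0)
  structure(list(classes = classes, nGenes = as.integer(nGenes),
                 nMarkersPerClass = as.integer(nMarkersPerClass),
                 markerEffect = markerEffect, nSamplesPerClass = n,
                 nStudies = as.integer(nStudies), batchSigma = batchSigma,
                 librarySize = sort(as.numeric(librarySize)),
                 dispersion = dispersion,
                 nCellsPerClass = as.integer(nCellsPerClass),
                 cellLibrarySize = sort(as.numeric(cellLibrarySize)),
                 dropout = dropout, seed = as.integer(seed)),
            class = "simulation_config")
}

## internal: class profiles (log-scale) + marker assignment + study factors
simulateProfiles <- function(config) {
  set.seed(stageSeed(config$seed, "profiles"))
  genes <- sprintf("G%04d", seq_len(config$nGenes))
  baseline <- stats::runif(config$nGenes, 1, 4)
  profiles <- matrix(baseline, config$nGenes, length(config$classes),
                     dimnames = list(genes, config$classes))
  markers <- list()
  idx <- 0L
  for (cl in config$classes) {
    mk <- if (config$nMarkersPerClass > 0) idx + seq_len(config$nMarkersPerClass)
          else integer()
    idx <- idx + config$nMarkersPerClass
    profiles[mk, cl] <- profiles[mk, cl] + config$markerEffect
    markers[[cl]] <- genes[mk]
  }
  studyFactors <- matrix(stats::rnorm(config$nGenes * config$nStudies,
                                      0, config$batchSigma),
                         config$nGenes, config$nStudies,
                         dimnames = list(genes, paste0("study", seq_len(config$nStudies))))
  list(genes = genes, profiles = profiles, markers = markers,
       studyFactors = studyFactors)
}

## internal: one NB count column from a linear-scale relative profile
nbCountColumn <- function(muRel, librarySize, dispersion) {
  p <- muRel / sum(muRel)
  L <- stats::runif(1, librarySize[1], librarySize[2])
  stats::rnbinom(length(p), mu = p * L, size = 1 / dispersion)
}

#' Simulate a multi-study bulk RNA-seq cohort
#'
#' Counts are negative binomial with mean
#' `exp(class profile + study batch factor)` rescaled to a per-sample library
#' size. Samples of each class cycle through the studies so every study mixes
#' classes. Deterministic for a fixed config (which carries the seed).
#'
#' @param config a [simulationConfig()].
#' @return `list(expr, annotation, profiles, markers, studyFactors, config)`;
#'   `expr` is a genes x samples count matrix, `annotation` has columns
#'   `sample_id`, `class_label`, `study_id`.
#' @export
simulateBulk <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- simulateProfiles(config)
  set.seed(stageSeed(config$seed, "bulk_counts"))
  cols <- list(); ann <- list()
  for (cl in config$classes) {
    for (i in seq_len(config$nSamplesPerClass[[cl]])) {
      study <- ((i - 1L) %% config$nStudies) + 1L
      muRel <- exp(truth$profiles[, cl] + truth$studyFactors[, study])
      id <- sprintf("%s_st%d_%02d", cl, study, i)
      cols[[id]] <- nbCountColumn(muRel, config$librarySize, config$dispersion)
      ann[[id]] <- data.frame(sample_id = id, class_label = cl,
                              study_id = colnames(truth$studyFactors)[study])
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- truth$genes
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  c(list(expr = expr, annotation = annotation), truth["profiles"],
    truth["markers"], truth["studyFactors"], list(config = config))
}

#' Simulate mixture samples (heterogeneous-profile queries)
#'
#' Each sample is drawn from the weight-averaged mean profile on the linear
#' scale, with the same negative-binomial noise model as [simulateBulk()] and
#' no study distortion. Emulates samples of ambiguous or mixed identity, e.g.
#' a cell line whose transcriptome blends two lineage signatures.
#'
#' @param truth output of [simulateBulk()] (or any list with `profiles` and
#'   `config`).
#' @param weights named non-negative weights over a subset of the classes,
#'   summing to 1.
#' @param nSamples number of mixture samples.
#' @param seed integer seed.
#' @return genes x samples count matrix.
#' @export
simulateMixture <- function(truth, weights, nSamples, seed) {
  profiles <- truth$profiles; config <- truth$config
  if (is.null(names(weights)) || !all(names(weights) %in% colnames(profiles)))
    stop("unknown class label in mixture weights: ",
         paste(setdiff(names(weights), colnames(profiles)), collapse = ", "),
         call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  muRel <- as.numeric(exp(profiles[, names(weights), drop = FALSE]) %*% weights)
  set.seed(stageSeed(seed, "mixture"))
  expr <- vapply(seq_len(nSamples), function(i)
    nbCountColumn(muRel, config$librarySize, config$dispersion),
    numeric(nrow(profiles)))
  dimnames(expr) <- list(rownames(profiles), sprintf("mix_%03d", seq_len(nSamples)))
  expr
}

#' Simulate single-cell counts with dropout
#'
#' Per-cell counts follow the bulk noise model at single-cell library sizes;
#' Bernoulli dropout is applied after sampling. Cells cycle through
#' `nStudies` donors. No per-donor expression distortion is applied.
#'
#' @param config a [simulationConfig()] (fields `nCellsPerClass`,
#'   `cellLibrarySize`, `dropout`).
#' @return `list(counts, annotation, config)`; `counts` is a sparse
#'   genes x cells `dgCMatrix`, `annotation` has columns `cell_id`,
#'   `donor_or_sample_id`, `cell_type_label`.
#' @export
simulateSingleCell <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- simulateProfiles(config)
  set.seed(stageSeed(config$seed, "single_cell"))
  cols <- list(); ann <- list()
  for (cl in config$classes) {
    muRel <- exp(truth$profiles[, cl])
    for (i in seq_len(config$nCellsPerClass)) {
      donor <- sprintf("donor%d", ((i - 1L) %% config$nStudies) + 1L)
      id <- sprintf("%s_%s_c%03d", cl, donor, i)
      cnt <- nbCountColumn(muRel, config$cellLibrarySize, config$dispersion)
      if (config$dropout > 0)
        cnt <- cnt * (stats::rbinom(length(cnt), 1, 1 - config$dropout))
      cols[[id]] <- cnt
      ann[[id]] <- data.frame(cell_id = id, donor_or_sample_id = donor,
                              cell_type_label = cl)
    }
  }
  counts <- if (length(cols))
    Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  else Matrix::Matrix(0, nrow = config$nGenes, ncol = 0, sparse = TRUE)
  rownames(counts) <- truth$genes
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(cell_id = character(0), donor_or_sample_id = character(0),
               cell_type_label = character(0))
  rownames(annotation) <- NULL
  list(counts = counts, annotation = annotation, config = config)
}

#' Random toy reference sequences with a shared rRNA-like segment
#'
#' Builds two multi-record references that are random (hence essentially
#' k-mer-disjoint) except for one identical segment present in both, emulating
#' the highly conserved rRNA content that inflates cross-species "both"
#' read fractions.
#'
#' @param seed integer seed.
#' @param uniqueLength length of each reference-specific sequence.
#' @param sharedLength length of the shared (rRNA-like) segment.
#' @return list with `DNAStringSet`s `refA`, `refB` (unique + shared record
#'   each), `shared`, `uniqueA`, `uniqueB`.
#' @export
makeToyReferences <- function(seed, uniqueLength = 3000L, sharedLength = 1500L) {
  set.seed(stageSeed(seed, "toy_refs"))
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  uniqueA <- rand(uniqueLength); uniqueB <- rand(uniqueLength)
  shared <- rand(sharedLength)
  list(refA = Biostrings::DNAStringSet(c(refA_unique = uniqueA, shared_rRNA = shared)),
       refB = Biostrings::DNAStringSet(c(refB_unique = uniqueB, shared_rRNA = shared)),
       shared = Biostrings::DNAStringSet(c(shared_rRNA = shared)),
       uniqueA = Biostrings::DNAStringSet(c(refA_unique = uniqueA)),
       uniqueB = Biostrings::DNAStringSet(c(refB_unique = uniqueB)))
}

#' Simulate sequencing reads from named sources
#'
#' Reads are uniform substrings of their declared source sequence with
#' independent per-base substitution errors; the source is recorded in the
#' read name (`<source>_<i>`), giving truth labels for free.
#'
#' @param references named list of `DNAStringSet` (or plain character)
#'   sources, e.g. `list(refA = ..., refB = ..., shared = ...)`.
#' @param nReads named integer vector of read counts per source (names must
#'   match `references`; 0 allowed).
#' @param readLength read length; must not exceed the shortest source record.
#' @param errorRate per-base substitution probability.
#' @param seed integer seed.
#' @return `list(reads, truth, positions)`: `reads` a named `DNAStringSet`,
#'   `truth` a factor of source names, `positions` a data.frame
#'   (`source`, `record`, `start`) locating each read in its source.
#' @export
simulateReads <- function(references, nReads, readLength = 100L,
                          errorRate = 0, seed) {
  stopifnot(is.list(references), !is.null(names(references)),
            !is.null(names(nReads)), all(names(nReads) %in% names(references)),
            all(nReads >= 0), errorRate >= 0, errorRate < 1)
  refs <- lapply(references, function(r) {
    if (is.character(r)) r <- Biostrings::DNAStringSet(r)
    as.character(r)
  })
  minLen <- min(unlist(lapply(refs[names(nReads)[nReads > 0]], nchar)), Inf)
  if (readLength > minLen)
    stop("readLength ", readLength, " exceeds shortest source record (", minLen, ")",
         call. = FALSE)
  set.seed(stageSeed(seed, "reads"))
  bases <- c("A", "C", "G", "T")
  out <- character(0); src <- character(0)
  recIdx <- integer(0); startPos <- integer(0)
  for (s in names(nReads)) {
    n <- nReads[[s]]
    if (n == 0) next
    recs <- refs[[s]]
    lens <- nchar(recs)
    for (i in seq_len(n)) {
      j <- sample.int(length(recs), 1, prob = lens - readLength + 1)
      rec <- recs[[j]]
      start <- sample.int(nchar(rec) - readLength + 1L, 1)
      read <- substr(rec, start, start + readLength - 1L)
      if (errorRate > 0) {
        hit <- which(stats::runif(readLength) < errorRate)
        if (length(hit)) {
          ch <- strsplit(read, "", fixed = TRUE)[[1]]
          for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1)
          read <- paste(ch, collapse = "")
        }
      }
      out <- c(out, read)
      src <- c(src, s)
      recIdx <- c(recIdx, j)
      startPos <- c(startPos, start)
    }
  }
  reads <- Biostrings::DNAStringSet(out)
  names(reads) <- sprintf("%s_%05d", src, seq_along(src))
  list(reads = reads, truth = factor(src, levels = names(references)),
       positions = data.frame(source = src, record = recIdx,
                              start = startPos, stringsAsFactors = FALSE))
}

#' Write reads as a plain 4-line FASTQ
#'
#' @param reads named `DNAStringSet`.
#' @param path output path (`.gz` supported).
#' @export
writeFastq <- function(reads, path) {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                     function(w) strrep("I", w), character(1)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
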