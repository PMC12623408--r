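## internal: load reads from FASTQ path, DNAStringSet, or character vector
loadReads <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    out <- tryCatch(Biostrings::readDNAStringSet(reads, format = "fastq"),
                    error = function(e)
                      stop("malformed FASTQ '", reads, "': ",
                           conditionMessage(e), call. = FALSE))
    return(out)
  }
  if (is.character(reads)) return(Biostrings::DNAStringSet(reads))
  if (is(reads, "DNAStringSet")) return(reads)
  stop("reads must be a FASTQ path, DNAStringSet, or character vector",
       call. = FALSE)
}

## internal: per-sequence list of canonical k-mers (strand-collapsed,
## k-mers containing non-ACGT symbols dropped)
canonicalKmerList <- function(seqs, k) {
  seqs <- as.character(seqs)
  raw <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  })
  all <- unlist(raw, use.names = FALSE)
  if (!length(all)) return(raw)
  ok <- grepl("^[ACGT]+$", all)
  canon <- rep(NA_character_, length(all))
  if (any(ok)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all[ok])))
    canon[ok] <- pmin(all[ok], rc)
  }
  idx <- rep(seq_along(raw), lengths(raw))
  out <- rep(list(character(0)), length(seqs))
  keep <- !is.na(canon)
  hits <- split(canon[keep], idx[keep])
  out[as.integer(names(hits))] <- hits
  out
}

#' Build a two-reference canonical k-mer index
#'
#' Enumerates every canonical k-mer (lexicographic minimum of the k-mer and
#' its reverse complement) of two reference sequence sets and flags each as
#' specific to reference A, specific to reference B, or shared. K-mers
#' containing non-ACGT symbols are skipped.
#'
#' @param refA,refB references: FASTA path, `DNAStringSet`, or character.
#' @param k odd k-mer length >= 11 (default 25); values that are even or
#'   short are rejected (palindrome/specificity guard).
#' @return A \linkS4class{KmerIndex}.
#' @export
buildKmerIndex <- function(refA, refB, k = 25L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L)
    stop("k must be odd and >= 11", call. = FALSE)
  loadRef <- function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r))
      r <- Biostrings::readDNAStringSet(r)
    if (is.character(r)) r <- Biostrings::DNAStringSet(r)
    if (!length(r)) stop("empty reference", call. = FALSE)
    r
  }
  a <- loadRef(refA); b <- loadRef(refB)
  if (k > max(Biostrings::width(a)) || k > max(Biostrings::width(b)))
    stop("k exceeds every sequence of a reference", call. = FALSE)
  ka <- unique(unlist(canonicalKmerList(a, k), use.names = FALSE))
  kb <- unique(unlist(canonicalKmerList(b, k), use.names = FALSE))
  all <- union(ka, kb)
  flags <- 1L * (all %in% ka) + 2L * (all %in% kb)
  names(flags) <- all
  new("KmerIndex", k = k, flags = flags,
      refA = if (is.character(refA) && length(refA) == 1) basename(refA) else "refA",
      refB = if (is.character(refB) && length(refB) == 1) basename(refB) else "refB")
}

#' Classify reads by k-mer membership in two references
#'
#' Counts, per read, the k-mers hitting A-specific (`a`), B-specific (`b`) and
#' shared (`c`) index entries, then assigns: `a_only` if
#' `a >= minHits` and `a - b >= margin` (symmetric for `b_only`); `both` if
#' `c >= minHits` while neither specific count reaches `minHits`; `neither` if
#' `a + b + c < minHits`; otherwise `ambiguous`. Reads shorter than k are
#' classified `neither` and counted in the `short_reads` attribute.
#'
#' @param reads FASTQ path (plain or gzip), `DNAStringSet`, or character.
#' @param index a \linkS4class{KmerIndex}.
#' @param minHits minimum supporting k-mers (default 4).
#' @param margin required lead of the winning specific count (default 2).
#' @return list: `category` (factor per read), `summary`
#'   (\linkS4class{ReadOriginSummary}).
#' @export
classifyReads <- function(reads, index, minHits = 4L, margin = 2L) {
  stopifnot(is(index, "KmerIndex"))
  reads <- loadReads(reads)
  if (!length(reads)) stop("empty read set", call. = FALSE)
  k <- index@k
  kl <- canonicalKmerList(reads, k)
  lens <- lengths(kl)
  all <- unlist(kl, use.names = FALSE)
  flag <- index@flags[match(all, names(index@flags))]
  idx <- rep(seq_along(kl), lens)
  n <- length(reads)
  cnt <- function(f) {
    hit <- which(!is.na(flag) & flag == f)
    tabulate(idx[hit], nbins = n)
  }
  a <- cnt(1L); b <- cnt(2L); cc <- cnt(3L)

  category <- rep("ambiguous", n)
  category[a >= minHits & (a - b) >= margin] <- "a_only"
  category[b >= minHits & (b - a) >= margin] <- "b_only"
  category[cc >= minHits & a < minHits & b < minHits] <- "both"
  category[(a + b + cc) < minHits] <- "neither"
  short <- Biostrings::width(reads) < k
  category[short] <- "neither"
  category <- factor(category, levels = readCategories)
  names(category) <- names(reads)
  counts <- setNames(as.integer(table(category)), readCategories)
  list(category = category,
       summary = structure(new("ReadOriginSummary", counts = counts,
                               refA = index@refA, refB = index@refB),
                           short_reads = sum(short)))
}

#' Estimate the rRNA read fraction
#'
#' A read counts as rRNA when at least `minHitFraction` of its canonical
#' k-mers are present in the rRNA reference k-mer set; the estimate is the
#' fraction of such reads. Used to diagnose insufficient rRNA depletion, the
#' usual cause of inflated cross-species "both" fractions (rRNA is highly
#' conserved and can dominate a library's RNA content).
#'
#' The default k of 15 is deliberately smaller than the read-origin index's
#' 25: a single substitution destroys up to k consecutive k-mers, so at
#' typical per-base error rates a shorter k keeps the surviving-k-mer
#' fraction of a true rRNA read safely above the 0.5 decision threshold
#' while random matches remain negligible at 4^15 possible words.
#'
#' @param reads FASTQ path, `DNAStringSet`, or character; must be non-empty.
#' @param rrnaRef rRNA reference: FASTA path, `DNAStringSet`, or character.
#' @param k odd k-mer length >= 11 (default 15).
#' @param minHitFraction per-read hit-fraction threshold (default 0.5).
#' @return fraction between 0 and 1.
#' @export
estimateRrnaFraction <- function(reads, rrnaRef, k = 15L, minHitFraction = 0.5) {
  reads <- loadReads(reads)
  if (!length(reads)) stop("empty read set", call. = FALSE)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L) stop("k must be odd and >= 11", call. = FALSE)
  if (is.character(rrnaRef) && length(rrnaRef) == 1 && file.exists(rrnaRef))
    rrnaRef <- Biostrings::readDNAStringSet(rrnaRef)
  if (is.character(rrnaRef)) rrnaRef <- Biostrings::DNAStringSet(rrnaRef)
  if (!length(rrnaRef)) stop("empty rRNA reference", call. = FALSE)
  set <- unique(unlist(canonicalKmerList(rrnaRef, k), use.names = FALSE))
  kl <- canonicalKmerList(reads, k)
  frac <- vapply(kl, function(km)
    if (!length(km)) 0 else mean(km %in% set), numeric(1))
  mean(frac >= minHitFraction & lengths(kl) > 0)
}
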