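# Canonical k-mer counting, alphabet sampling, IDF weighting and sparse
# feature construction for both orientations of every read.

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement, which makes counting strand-symmetric. Vectorized; idempotent.
#'
#' @param kmer character vector of DNA k-mers over ACGT.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmer) {
  if (any(grepl("[^ACGT]", kmer)))
    stop("k-mers must contain only A, C, G, T")
  rc <- revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

#' Count canonical k-mers across a read set
#'
#' Slides a window of width `k` over every read; each window's canonical form
#' is counted, so the count of a k-mer is its collection frequency (CF): the
#' combined number of occurrences of the k-mer and its reverse complement
#' across all reads. Windows containing a non-ACGT base are skipped.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @param k k-mer size, 3-31 (odd values avoid palindromic ambiguity).
#' @return An object of class `kmer_count_table`: list with `k`, `kmer`
#'   (sorted canonical k-mers), `count` (CF per k-mer) and `n_reads`.
#' @export
count_kmers <- function(reads, k) {
  if (k < 3 || k > 31) stop("`k` must be between 3 and 31")
  seqs <- as.character(reads)
  if (length(seqs) == 0L) {
    return(structure(list(k = as.integer(k), kmer = character(0),
                          count = integer(0), n_reads = 0L),
                     class = "kmer_count_table"))
  }
  tab <- cpp_count_kmers(seqs, as.integer(k))
  structure(list(k = as.integer(k), kmer = tab$kmer, count = tab$count,
                 n_reads = length(seqs)),
            class = "kmer_count_table")
}

#' @exportS3Method base::print
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("kmer_count_table: k=%d, %d canonical k-mers over %d reads\n",
              x$k, length(x$kmer), x$n_reads))
  invisible(x)
}

#' Import an external k-mer counter dump
#'
#' Reads the plain-text two-column `kmer count` dump format written by
#' column-oriented k-mer counters, as an alternative to [count_kmers()].
#' K-mers are canonicalized if they are not already.
#'
#' @param path dump file path (whitespace-separated `kmer count` rows).
#' @param n_reads number of reads in the dataset the dump was computed from
#'   (needed for IDF weighting; counters do not record it).
#' @return A `kmer_count_table`.
#' @export
read_kmer_dump <- function(path, n_reads) {
  d <- read.table(path, header = FALSE, col.names = c("kmer", "count"),
                  colClasses = c("character", "integer"))
  if (nrow(d) == 0L) stop("empty k-mer dump: ", path)
  k <- unique(nchar(d$kmer))
  if (length(k) != 1L) stop("k-mer dump mixes k-mer sizes")
  d$kmer <- canonical_kmer(d$kmer)
  agg <- tapply(d$count, d$kmer, sum)
  kmers <- sort(names(agg))
  structure(list(k = as.integer(k), kmer = kmers,
                 count = as.integer(agg[kmers]),
                 n_reads = as.integer(n_reads)),
            class = "kmer_count_table")
}

#' Filter low-frequency k-mers and sample the feature alphabet
#'
#' Keeps k-mers with CF at least `min_count` (removing the singleton k-mers
#' that sequencing errors generate), then samples a fraction of the survivors
#' uniformly without replacement. Survivors are sorted lexicographically
#' before the seeded draw, so the alphabet is reproducible across platforms;
#' the sampled alphabet is kept in sorted order. The alphabet size is
#' `max(1, round(fraction * n_survivors))`.
#'
#' @param table a `kmer_count_table`.
#' @param min_count minimum CF to retain; default 2.
#' @param fraction sampling fraction in `(0, 1]`; default 0.15.
#' @param seed integer seed for the draw.
#' @return An object of class `kmer_alphabet`: list with `k`, `kmers`
#'   (ordered canonical k-mers) and `index` (named integer map k-mer ->
#'   1-based column).
#' @export
filter_and_sample <- function(table, min_count = 2L, fraction = 0.15,
                              seed = 1L) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (length(table$kmer) == 0L) stop("k-mer table is empty")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  keep <- table$count >= min_count
  survivors <- table$kmer[keep]
  if (length(survivors) == 0L)
    stop("no k-mers survive the min_count filter (min_count = ", min_count, ")")
  if (is.unsorted(survivors)) survivors <- sort(survivors)
  m <- max(1L, round(fraction * length(survivors)))
  kmers <- withr::with_seed(seed, sort(sample(survivors, m)))
  structure(list(k = table$k, kmers = kmers,
                 index = setNames(seq_along(kmers), kmers)),
            class = "kmer_alphabet")
}

#' @exportS3Method base::print
print.kmer_alphabet <- function(x, ...) {
  cat(sprintf("kmer_alphabet: k=%d, m=%d sampled canonical k-mers\n",
              x$k, length(x$kmers)))
  invisible(x)
}

#' Inverse document frequency weights for an alphabet
#'
#' Computes `w_j = ln(N / c_j)` per alphabet k-mer, where `N` is the number
#' of reads and `c_j` the k-mer's collection frequency (CF). CF is used as a
#' surrogate for the document frequency, which tracks it almost exactly on
#' log scale for long-read data (see the package vignette); this lets the
#' weights come straight from the count table. Natural log; a k-mer occurring
#' exactly `N` times has weight 0, and weights decrease as `c_j` grows, so
#' repetitive k-mers are down-weighted.
#'
#' @param table a `kmer_count_table` (provides `c_j` and `N`).
#' @param alphabet a `kmer_alphabet`; every alphabet k-mer must be present in
#'   the table.
#' @return An object of class `idf_weights`: numeric vector of length `m`
#'   with the alphabet stored as an attribute.
#' @export
idf_weights <- function(table, alphabet) {
  stopifnot(inherits(table, "kmer_count_table"),
            inherits(alphabet, "kmer_alphabet"))
  pos <- match(alphabet$kmers, table$kmer)
  if (anyNA(pos))
    stop("alphabet k-mers missing from the count table: ",
         paste(head(alphabet$kmers[is.na(pos)], 3L), collapse = ", "))
  w <- log(table$n_reads / table$count[pos])
  structure(w, names = alphabet$kmers, class = "idf_weights")
}

#' Document frequency of k-mers across a read set
#'
#' Counts, for each query k-mer, the number of reads containing it (in
#' canonical form) at least once. This is the conventional DF that IDF
#' weighting calls for; the pipeline substitutes the cheaper collection
#' frequency, and this function is what quantifies how faithful that
#' surrogate is on a given dataset.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @param k k-mer size matching the query k-mers.
#' @param kmers canonical k-mer strings to look up.
#' @return Integer vector of document frequencies, one per query k-mer.
#' @export
kmer_doc_freq <- function(reads, k, kmers) {
  if (any(nchar(kmers) != k)) stop("`kmers` must all have length `k`")
  cpp_doc_freq(as.character(reads), as.integer(k), kmers)
}

FEATURE_SCHEMES <- c("binary", "tf", "raw_tf", "idf", "tf_idf")

#' Build the sparse feature batch for both orientations of each read
#'
#' For every read, two rows are produced: the `+` row counts literal
#' occurrences of alphabet k-mer strings in the read as given, the `-` row
#' counts occurrences in its reverse complement. The alphabet holds canonical
#' k-mer strings, so orientation is carried by which strand the literal match
#' falls on; the `-` row of a read equals the `+` row of its reverse
#' complement. Weighting schemes: `binary` (presence), `raw_tf` (occurrence
#' count), `tf` (count divided by the total alphabet-k-mer occurrences in
#' that oriented read), `idf` (binary times IDF weight), `tf_idf` (tf times
#' IDF weight). The `idf`/`tf_idf` schemes here are the exact-mode path; the
#' streamed pipeline keeps features binary/tf and applies IDF inside the
#' fused projection instead.
#'
#' @param reads character vector or [Biostrings::DNAStringSet], named or not.
#' @param alphabet a `kmer_alphabet`.
#' @param scheme one of `"binary"`, `"tf"`, `"raw_tf"`, `"idf"`, `"tf_idf"`.
#' @param idf an `idf_weights` vector, required for `idf` and `tf_idf`.
#' @return An object of class `feature_batch`: list with `rows` (sparse
#'   `dgCMatrix`, `2 * n_reads` x `m`), `row_ids` (oriented-read data frame,
#'   see [oriented_ids()]), `scheme`, and `flagged` (logical per row, `TRUE`
#'   for all-zero rows, e.g. reads shorter than `k`).
#' @export
featurize_batch <- function(reads, alphabet, scheme = "binary", idf = NULL) {
  stopifnot(inherits(alphabet, "kmer_alphabet"))
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  seqs <- as.character(reads)
  nms <- names(seqs) %||% sprintf("read%05d", seq_along(seqs))
  m <- length(alphabet$kmers)
  n2 <- 2L * length(seqs)
  if (scheme %in% c("idf", "tf_idf")) {
    if (is.null(idf)) stop("`idf` weights are required for scheme ", scheme)
    if (length(idf) != m) stop("`idf` length must equal the alphabet size")
  }
  trip <- if (length(seqs) > 0)
    cpp_featurize(seqs, alphabet$k, alphabet$kmers)
    else list(i = integer(0), j = integer(0), x = integer(0))
  x <- as.numeric(trip$x)
  i1 <- trip$i + 1L
  if (scheme %in% c("tf", "tf_idf")) {
    tot <- numeric(n2)
    agg <- rowsum(x, i1)
    tot[as.integer(rownames(agg))] <- agg[, 1L]
    x <- x / tot[i1]
  } else if (scheme == "binary" || scheme == "idf") {
    x <- rep(1, length(x))
  }
  if (scheme %in% c("idf", "tf_idf")) x <- x * as.numeric(idf)[trip$j + 1L]
  rows <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = x, index1 = FALSE,
                               dims = c(n2, m))
  present <- logical(n2)
  present[unique(i1)] <- TRUE
  structure(
    list(rows = rows, row_ids = oriented_ids(nms), scheme = scheme,
         flagged = !present),
    class = "feature_batch"
  )
}

#' @exportS3Method base::print
print.feature_batch <- function(x, ...) {
  cat(sprintf(
    "feature_batch: %d oriented rows x %d k-mers (%s scheme), %d flagged all-zero rows\n",
    nrow(x$rows), ncol(x$rows), x$scheme, sum(x$flagged)))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ, plain or gzipped
#'
#' Format is detected from the first record character (`>` FASTA, `@`
#' FASTQ).
#'
#' @param path input file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("empty input file: ", path)
  fmt <- if (startsWith(first, ">")) "fasta"
    else if (startsWith(first, "@")) "fastq"
    else stop("cannot detect FASTA/FASTQ format of ", path)
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  # FASTQ descriptions keep everything after '@'; trim to the first word
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
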