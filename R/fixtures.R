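# Synthetic genomes and error-bearing long reads with ground-truth placement.
#
# All genomic intervals are 0-based half-open, as in BED/PAF: a read covering
# bases ref_start .. ref_end - 1 has width ref_end - ref_start, and two
# intervals that merely touch do not overlap.

BASES <- c("A", "C", "G", "T")

# integer codes 0..3 <-> DNA characters
dna_to_int <- function(s) {
  codes <- integer(256)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("T")] <- 3L
  codes[utf8ToInt(s) ]
}

int_to_dna <- function(x) {
  intToUtf8(utf8ToInt("ACGT")[x + 1L])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a synthetic genome with controllable repeat content
#'
#' Builds an i.i.d.-uniform background sequence in blocks of
#' `repeat_unit_len` bases, then designates `round(repeat_fraction *
#' n_blocks)` of the non-initial blocks as repeats: each repeat block is a
#' verbatim copy of a segment starting at a random earlier position. Repeats
#' therefore emulate dispersed duplications (transposon-like elements) rather
#' than tandem arrays.
#'
#' @param length genome length in bp.
#' @param repeat_fraction fraction of positions covered by repeat copies, in
#'   `[0, 1]`.
#' @param repeat_unit_len length of each repeat unit in bp; default 5000,
#'   the scale of LINE-class transposable elements, long enough to confound
#'   reads of 10-20 kb.
#' @param seed integer seed; identical seeds give identical genomes.
#' @return An object of class `synthetic_genome`: a list with `sequence`
#'   (a single DNA string over ACGT) and `repeat_annotations` (a data frame
#'   with 0-based half-open `start`, `end` and the `source_start` each copy
#'   was taken from).
#' @export
generate_genome <- function(length, repeat_fraction = 0, repeat_unit_len = 5000L,
                            seed = 1L) {
  stopifnot_scalar_number(length, "length")
  stopifnot_scalar_number(repeat_fraction, "repeat_fraction")
  if (length <= 0) stop("`length` must be positive")
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop("`repeat_fraction` must be in [0, 1]")
  if (repeat_unit_len >= length)
    stop("`repeat_unit_len` must be smaller than `length`")
  length <- as.integer(length)
  repeat_unit_len <- as.integer(repeat_unit_len)

  withr::with_seed(seed, {
    n_blocks <- ceiling(length / repeat_unit_len)
    n_repeat <- min(round(repeat_fraction * n_blocks), n_blocks - 1L)
    repeat_blocks <- if (n_repeat > 0)
      sort(sample(2:n_blocks, n_repeat)) else integer(0)

    seq_int <- integer(length)
    ann <- vector("list", n_repeat)
    a <- 0L
    pos <- 0L  # 0-based position of next block
    for (b in seq_len(n_blocks)) {
      blen <- min(repeat_unit_len, length - pos)
      if (b %in% repeat_blocks && pos > blen) {
        src <- sample.int(pos - blen + 1L, 1L) - 1L
        seq_int[(pos + 1L):(pos + blen)] <- seq_int[(src + 1L):(src + blen)]
        a <- a + 1L
        ann[[a]] <- c(start = pos, end = pos + blen, source_start = src)
      } else {
        seq_int[(pos + 1L):(pos + blen)] <- sample(0:3, blen, replace = TRUE)
      }
      pos <- pos + blen
    }
    ann <- if (a > 0) as.data.frame(do.call(rbind, ann[seq_len(a)]))
      else data.frame(start = integer(0), end = integer(0),
                      source_start = integer(0))
    structure(
      list(sequence = int_to_dna(seq_int), repeat_annotations = ann,
           length = length),
      class = "synthetic_genome"
    )
  })
}

#' @exportS3Method base::print
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d bp, %d repeat annotations (%.1f%% of positions)\n",
              x$length, nrow(x$repeat_annotations),
              100 * sum(x$repeat_annotations$end - x$repeat_annotations$start) /
                x$length))
  invisible(x)
}

# per-read error process: independent per-base deletion, substitution and
# (post-base) insertion, in that order
apply_read_errors <- function(x, sub_rate, ins_rate, del_rate) {
  n <- length(x)
  if (del_rate > 0) {
    x <- x[runif(n) >= del_rate]
    n <- length(x)
  }
  if (n == 0L) return(x)
  if (sub_rate > 0) {
    hit <- runif(n) < sub_rate
    nh <- sum(hit)
    if (nh > 0)
      x[hit] <- (x[hit] + sample.int(3L, nh, replace = TRUE)) %% 4L
  }
  if (ins_rate > 0) {
    ins <- runif(n) < ins_rate
    ni <- sum(ins)
    if (ni > 0) {
      out <- integer(n + ni)
      pos <- seq_len(n) + cumsum(c(0L, ins[-n]))
      out[pos] <- x
      out[setdiff(seq_len(n + ni), pos)] <- sample(0:3, ni, replace = TRUE)
      x <- out
    }
  }
  x
}

#' Simulate long reads with ground-truth intervals
#'
#' Samples reads uniformly from a genome at a target coverage depth, with
#' truncated-normal lengths, uniform strand choice, and independent per-base
#' substitution/insertion/deletion errors applied after extraction. The
#' ground-truth table records the error-free source interval and strand of
#' every read, which is what reference overlap graphs are built from.
#'
#' @param genome a `synthetic_genome`, or a single DNA string.
#' @param depth target coverage depth (x); read count is
#'   `round(depth * genome_length / mean_len)`.
#' @param mean_len,len_sd mean and standard deviation of read length (bp);
#'   lengths are clamped to `[min(500, mean_len), genome_length]`.
#' @param sub_rate,ins_rate,del_rate per-base error rates in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical reads and truth.
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and `truth`
#'   (data frame: `read_id`, `ref_start`, `ref_end` 0-based half-open,
#'   `strand`, `length` = emitted read length).
#' @export
simulate_reads <- function(genome, depth, mean_len, len_sd = 0.1 * mean_len,
                           sub_rate = 0, ins_rate = 0, del_rate = 0,
                           seed = 1L) {
  seq_chr <- if (inherits(genome, "synthetic_genome")) genome$sequence
    else as.character(genome)
  L <- nchar(seq_chr)
  if (depth <= 0) stop("`depth` must be positive")
  if (mean_len > L) stop("`mean_len` must not exceed the genome length")
  for (r in c(sub_rate, ins_rate, del_rate))
    if (r < 0 || r > 1) stop("error rates must be in [0, 1]")
  g <- dna_to_int(seq_chr)

  withr::with_seed(seed, {
    n <- max(1L, round(depth * L / mean_len))
    lens <- round(rnorm(n, mean_len, len_sd))
    lower <- max(50, min(500, mean_len - 3 * len_sd))
    lens <- pmin(pmax(lens, lower), L)
    starts <- floor(runif(n, 0, L - lens + 1))  # 0-based
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("read%05d", seq_len(n))

    seqs <- character(n)
    out_len <- integer(n)
    for (i in seq_len(n)) {
      x <- g[(starts[i] + 1L):(starts[i] + lens[i])]
      if (strands[i] == "-") x <- rev(3L - x)
      x <- apply_read_errors(x, sub_rate, ins_rate, del_rate)
      seqs[i] <- int_to_dna(x)
      out_len[i] <- length(x)
    }
    reads <- Biostrings::DNAStringSet(setNames(seqs, ids))
    truth <- data.frame(
      read_id = ids,
      ref_start = as.integer(starts),
      ref_end = as.integer(starts + lens),
      strand = strands,
      length = out_len,
      stringsAsFactors = FALSE
    )
    list(reads = reads, truth = truth)
  })
}

#' Build the ground-truth reference overlap graph from simulated intervals
#'
#' Two reads whose source intervals intersect by at least `min_overlap` bp
#' overlap. Each such pair contributes two oriented edges: `(A+, B+)` and
#' `(A-, B-)` when the reads were sampled from the same strand, `(A+, B-)`
#' and `(A-, B+)` otherwise. Edge overlap size is the interval-intersection
#' length.
#'
#' @param truth data frame as returned by [simulate_reads()] (columns
#'   `read_id`, `ref_start`, `ref_end`, `strand`).
#' @param min_overlap minimum intersection (bp) for an edge; default 1, the
#'   most permissive ground truth.
#' @return An object of class `reference_graph`; see [reference_from_paf()]
#'   for the shared structure.
#' @export
truth_reference_graph <- function(truth, min_overlap = 1L) {
  if (nrow(truth) == 0L) stop("`truth` must be non-empty")
  if (min_overlap < 1L) stop("`min_overlap` must be >= 1")
  ir <- IRanges::IRanges(start = truth$ref_start + 1L, end = truth$ref_end)
  hits <- IRanges::findOverlaps(ir, minoverlap = as.integer(min_overlap),
                                drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  sizes <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
  oriented_reference(n_reads = nrow(truth), read_names = truth$read_id,
                     i = qi, j = si, same_strand = truth$strand[qi] == truth$strand[si],
                     size = sizes, retained = seq_len(nrow(truth)),
                     min_overlap = as.integer(min_overlap))
}

# Assemble a reference_graph from read-pair intersections. For each pair,
# emit the two strand-consistent oriented edges.
oriented_reference <- function(n_reads, read_names, i, j, same_strand, size,
                               retained, min_overlap) {
  u1 <- ifelse(same_strand, vertex_id(i, "+"), vertex_id(i, "+"))
  v1 <- ifelse(same_strand, vertex_id(j, "+"), vertex_id(j, "-"))
  u2 <- ifelse(same_strand, vertex_id(i, "-"), vertex_id(i, "-"))
  v2 <- ifelse(same_strand, vertex_id(j, "-"), vertex_id(j, "+"))
  edges <- data.frame(
    u = pmin(c(u1, u2), c(v1, v2)),
    v = pmax(c(u1, u2), c(v1, v2)),
    size = rep(size, 2L)
  )
  structure(
    list(n_reads = n_reads, read_names = read_names, edges = edges,
         retained = retained, min_overlap = min_overlap),
    class = "reference_graph"
  )
}

#' @exportS3Method base::print
print.reference_graph <- function(x, ...) {
  cat(sprintf(
    "reference_graph: %d reads (%d retained), %d oriented edges, min_overlap %d bp\n",
    x$n_reads, length(x$retained), nrow(x$edges), x$min_overlap))
  invisible(x)
}

#' Write simulated reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output FASTQ path (`.gz` suffix compresses).
#' @export
write_reads_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write / read a ground-truth interval table
#'
#' Tab-separated with header: `read_id`, `ref_start`, `ref_end` (0-based
#' half-open), `strand`, `length`.
#'
#' @param truth truth data frame from [simulate_reads()].
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "ref_start", "ref_end", "strand", "length")
  if (!all(need %in% names(tr)))
    stop("truth TSV must have columns: ", paste(need, collapse = ", "))
  tr
}
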