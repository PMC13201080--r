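# Reference graphs from PAF alignments or truth tables, and the four
# overlap-graph quality metrics: error rate, mean overlap size, per-vertex
# correct-candidate degree (#COC) and connected components (#CC).

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory tab-separated columns; among optional tags only
#' `tp:A` (alignment type) is retained. Coordinates stay 0-based half-open
#' as in the format.
#'
#' @param path PAF file (optionally gzipped).
#' @return A data frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`,
#'   `tp`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad) > 0L)
    stop("unparseable PAF line ", bad[1], " in ", path)
  f <- function(i) vapply(parts, `[[`, character(1), i)
  tp <- vapply(parts, function(p) {
    hit <- p[startsWith(p, "tp:A:")]
    if (length(hit) > 0) substring(hit[1], 6L) else NA_character_
  }, character(1))
  num <- function(i) {
    x <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(x)) stop("unparseable PAF line ", which(is.na(x))[1], " in ", path)
    x
  }
  data.frame(qname = f(1), qlen = num(2), qstart = num(3), qend = num(4),
             strand = f(5), tname = f(6), tlen = num(7), tstart = num(8),
             tend = num(9), nmatch = num(10), alen = num(11), mapq = num(12),
             tp = tp, stringsAsFactors = FALSE)
}

#' Build a reference overlap graph from read-to-reference alignments
#'
#' Reads are filtered to remove ambiguous placements: minimum read length,
#' minimum aligned fraction of the read, and minimum mapping quality.
#' Secondary alignments (`tp:A:S`) are ignored; if a read still has several
#' primary records, the highest-MAPQ one is kept (ties: longest alignment
#' block). For every retained pair aligned to the same target whose target
#' intervals intersect by at least `min_overlap` bp, the two
#' strand-consistent oriented edges are emitted with the intersection length
#' as overlap size. Filtered reads keep their vertices (the vertex universe
#' stays `2n`) but contribute no reference edges; metrics exclude them from
#' the component and connectivity denominators (see [score_graph()]).
#'
#' @param paf PAF path or a data frame from [read_paf()].
#' @param read_names optional full read universe (so unaligned reads keep
#'   vertices); defaults to the reads present in the PAF.
#' @param min_read_len minimum read length in bp (default 5000).
#' @param min_aligned_frac minimum aligned fraction of the read (default 0.5).
#' @param min_mapq minimum mapping quality (default 30).
#' @param min_overlap minimum target-interval intersection in bp (default 1).
#' @return A `reference_graph` (see [truth_reference_graph()]).
#' @export
reference_from_paf <- function(paf, read_names = NULL, min_read_len = 5000,
                               min_aligned_frac = 0.5, min_mapq = 30,
                               min_overlap = 1L) {
  if (is.character(paf)) paf <- read_paf(paf)
  paf <- paf[is.na(paf$tp) | paf$tp == "P", , drop = FALSE]
  read_names <- read_names %||% unique(paf$qname)
  n <- length(read_names)

  # one primary alignment per read: best MAPQ, ties by alignment length
  ord <- order(paf$qname, -paf$mapq, -paf$alen)
  paf <- paf[ord, , drop = FALSE]
  paf <- paf[!duplicated(paf$qname), , drop = FALSE]
  paf <- paf[paf$qname %in% read_names, , drop = FALSE]

  pass <- paf$qlen >= min_read_len &
    (paf$qend - paf$qstart) / paf$qlen >= min_aligned_frac &
    paf$mapq >= min_mapq
  paf <- paf[pass, , drop = FALSE]
  retained <- sort(match(paf$qname, read_names))

  pairs <- list(i = integer(0), j = integer(0), same = logical(0),
                size = numeric(0))
  for (tgt in unique(paf$tname)) {
    sub <- paf[paf$tname == tgt, , drop = FALSE]
    if (nrow(sub) < 2L) next
    ir <- IRanges::IRanges(start = sub$tstart + 1L, end = sub$tend)
    hits <- IRanges::findOverlaps(ir, minoverlap = as.integer(min_overlap),
                                  drop.self = TRUE, drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    pairs$i <- c(pairs$i, match(sub$qname[qi], read_names))
    pairs$j <- c(pairs$j, match(sub$qname[si], read_names))
    pairs$same <- c(pairs$same, sub$strand[qi] == sub$strand[si])
    pairs$size <- c(pairs$size,
                    IRanges::width(IRanges::pintersect(ir[qi], ir[si])))
  }
  oriented_reference(n_reads = n, read_names = read_names, i = pairs$i,
                     j = pairs$j, same_strand = pairs$same, size = pairs$size,
                     retained = retained,
                     min_overlap = as.integer(min_overlap))
}

#' Score an overlap graph against a reference graph
#'
#' An edge is correct iff the same oriented pair is present in the reference.
#' Four metrics follow: `error_rate` = incorrect edges / total edges;
#' `mean_overlap_size` = arithmetic mean over all graph edges of the
#' reference overlap size, counting incorrect edges as zero; `coc` = each
#' vertex's degree counting only correct edges (a vertex with no correct edge
#' is a singleton); `n_cc` = connected components of the correct-edge
#' subgraph. Components and singleton/connectivity fractions are reported
#' over the retained (filter-passing) vertices, which keeps datasets with
#' and without alignment filtering comparable; `n_cc_all` additionally
#' counts components over the full `2n` vertex universe so either
#' convention is recoverable.
#'
#' @param graph an `overlap_graph`.
#' @param reference a `reference_graph` over the same read universe.
#' @return An object of class `graph_metrics`: list with `error_rate`,
#'   `mean_overlap_size`, `coc` (length `2n`), `n_singletons`, `n_cc`,
#'   `n_cc_all`, `n_edges`, `n_correct_edges`, `n_vertices`,
#'   `retained_vertices`.
#' @export
score_graph <- function(graph, reference) {
  stopifnot(inherits(graph, "overlap_graph"),
            inherits(reference, "reference_graph"))
  if (graph$n_reads != reference$n_reads)
    stop("graph has ", graph$n_reads, " reads but reference has ",
         reference$n_reads)
  ne <- nrow(graph$edges)
  if (ne == 0L) stop("overlap graph has no edges; metrics are undefined")
  n2 <- 2L * graph$n_reads

  ref_key <- edge_key(reference$edges$u, reference$edges$v)
  ref_size <- reference$edges$size[!duplicated(ref_key)]
  ref_key <- ref_key[!duplicated(ref_key)]
  pos <- match(edge_key(graph$edges$u, graph$edges$v), ref_key)
  correct <- !is.na(pos)
  sizes <- ifelse(correct, ref_size[pos], 0)

  coc <- tabulate(c(graph$edges$u[correct], graph$edges$v[correct]), nbins = n2)
  retained_v <- sort(c(vertex_id(reference$retained, "+"),
                       vertex_id(reference$retained, "-")))

  cc_count <- function(vertices) {
    eu <- graph$edges$u[correct]
    ev <- graph$edges$v[correct]
    in_set <- eu %in% vertices & ev %in% vertices
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(eu[in_set]),
                 to = as.character(ev[in_set])),
      directed = FALSE, vertices = data.frame(name = as.character(vertices)))
    igraph::components(g)$no
  }

  structure(
    list(error_rate = 1 - sum(correct) / ne,
         mean_overlap_size = sum(sizes) / ne,
         coc = coc,
         n_singletons = sum(coc[retained_v] == 0L),
         n_cc = cc_count(retained_v),
         n_cc_all = cc_count(seq_len(n2)),
         n_edges = ne,
         n_correct_edges = sum(correct),
         n_vertices = n2,
         retained_vertices = retained_v),
    class = "graph_metrics"
  )
}

#' @exportS3Method base::print
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "graph_metrics: error_rate %.4f, mean_overlap_size %.1f bp,\n",
    "  %d/%d correct edges, %d singletons, #CC %d (retained) / %d (all)\n"),
    x$error_rate, x$mean_overlap_size, x$n_correct_edges, x$n_edges,
    x$n_singletons, x$n_cc, x$n_cc_all))
  invisible(x)
}

#' Fraction of low-connectivity vertices per #COC threshold
#'
#' For each threshold `t`, the fraction of retained vertices whose
#' correct-candidate degree is below `t`.
#'
#' @param metrics a `graph_metrics`.
#' @param thresholds integer thresholds.
#' @return A data frame with `threshold` and `fraction`.
#' @export
low_connectivity_curve <- function(metrics, thresholds = 1:10) {
  stopifnot(inherits(metrics, "graph_metrics"))
  coc <- metrics$coc[metrics$retained_vertices]
  data.frame(threshold = as.integer(thresholds),
             fraction = vapply(thresholds, function(t) mean(coc < t),
                               numeric(1)))
}

#' Write graph metrics as a flat JSON report
#'
#' @param metrics a `graph_metrics`.
#' @param path output JSON path; the low-connectivity curve is written
#'   alongside as `<path>.coc_curve.tsv`.
#' @param thresholds thresholds for the curve.
#' @export
write_metrics_json <- function(metrics, path, thresholds = 1:10) {
  flat <- metrics[c("error_rate", "mean_overlap_size", "n_singletons",
                    "n_cc", "n_cc_all", "n_edges", "n_correct_edges",
                    "n_vertices")]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  curve <- low_connectivity_curve(metrics, thresholds)
  write.table(curve, paste0(path, ".coc_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
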