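# Oriented overlap graph construction from a neighbour table, and the
# candidate-table TSV serialization.

#' Build the undirected oriented overlap graph
#'
#' An edge `{u, v}` exists iff `v` is among the `k` nearest neighbours of `u`
#' or vice versa. Directed neighbour lists are deduplicated to undirected
#' edges; each edge keeps the best (lowest) rank and distance from either
#' direction. Self-loops and edges joining the two orientations of one read
#' are never emitted. With `n` reads and full neighbour lists of length `k`,
#' the edge count lies in `[k n, 2 k n]`: `kn` when every neighbour relation
#' is mutual, `2kn` when none is (counting both orientations, `2n` directed
#' lists of length `k` collapse to between `2nk/2` and `2nk` undirected
#' edges).
#'
#' @param neighbors a `neighbor_table`.
#' @return An object of class `overlap_graph`: list with `edges` (data frame
#'   `u`, `v`, `rank`, `distance`, with `u < v` vertex ids in the interleaved
#'   oriented order of [oriented_ids()]), `n_reads`, `read_names`, `k`.
#' @export
build_overlap_graph <- function(neighbors) {
  stopifnot(inherits(neighbors, "neighbor_table"))
  n <- nrow(neighbors$idx)
  k <- neighbors$k
  q <- rep(seq_len(n), times = k)
  t_ <- as.vector(neighbors$idx)
  r_ <- rep(seq_len(k), each = n)
  d_ <- as.vector(neighbors$dist)
  keep <- !is.na(t_) & t_ != q & t_ != partner_vertex(q)
  q <- q[keep]; t_ <- t_[keep]; r_ <- r_[keep]; d_ <- d_[keep]
  u <- pmin(q, t_); v <- pmax(q, t_)
  key <- edge_key(u, v)
  ord <- order(key, r_, d_)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  edges <- data.frame(u = u[sel], v = v[sel], rank = r_[sel],
                      distance = d_[sel])
  read_names <- if (!is.null(neighbors$ids))
    unique(neighbors$ids$name) else as.character(seq_len(n %/% 2L))
  structure(list(edges = edges, n_reads = n %/% 2L, read_names = read_names,
                 k = k),
            class = "overlap_graph")
}

#' @exportS3Method base::print
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d reads (%d oriented vertices), %d edges, k=%d\n",
              x$n_reads, 2L * x$n_reads, nrow(x$edges), x$k))
  invisible(x)
}

#' Write a candidate-overlap table as TSV
#'
#' One row per (query, neighbour) pair, ordered by query then rank, with
#' header `query_id`, `query_orient`, `target_id`, `target_orient`, `rank`,
#' `distance` (6 decimal places). Identifiers are the original sequence
#' names; a sidecar `<path>.names.tsv` maps names to 1-based read indices so
#' downstream consumers can recover the row order.
#'
#' @param neighbors a `neighbor_table` with oriented-read `ids`.
#' @param path output TSV path.
#' @export
write_candidates <- function(neighbors, path) {
  stopifnot(inherits(neighbors, "neighbor_table"))
  ids <- neighbors$ids
  if (is.null(ids))
    stop("neighbor table has no oriented-read identifiers")
  n <- nrow(neighbors$idx)
  k <- neighbors$k
  lines <- "query_id\tquery_orient\ttarget_id\ttarget_orient\trank\tdistance"
  if (n > 0L && k > 0L) {
    q <- rep(seq_len(n), each = k)
    r_ <- rep(seq_len(k), times = n)
    t_ <- as.vector(t(neighbors$idx))
    d_ <- as.vector(t(neighbors$dist))
    keep <- !is.na(t_)
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%d\t%.6f",
                              ids$name[q[keep]], ids$orient[q[keep]],
                              ids$name[t_[keep]], ids$orient[t_[keep]],
                              r_[keep], d_[keep]))
  }
  writeLines(lines, path)
  nm <- unique(ids$name)
  writeLines(c("name\tread_index",
               sprintf("%s\t%d", nm, seq_along(nm))),
             paste0(path, ".names.tsv"))
  invisible(path)
}

#' Read a candidate-overlap table
#'
#' Inverse of [write_candidates()] up to the 6-decimal distance rounding.
#' Read indices are taken from the sidecar `<path>.names.tsv` when present,
#' otherwise from the order in which query names first appear.
#'
#' @param path candidate TSV path.
#' @param read_names optional character vector fixing the read universe and
#'   order (e.g. the input FASTQ order).
#' @return A `neighbor_table`.
#' @export
read_candidates <- function(path, read_names = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty candidate file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("query_id", "query_orient", "target_id", "target_orient",
                "rank", "distance")
  if (!identical(header, expected))
    stop("malformed candidate header in ", path)
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L)
    stop("malformed candidate row at line ", bad[1] + 1L, " of ", path)
  if (is.null(read_names)) {
    sidecar <- paste0(path, ".names.tsv")
    if (file.exists(sidecar)) {
      sc <- read.delim(sidecar, stringsAsFactors = FALSE)
      read_names <- sc$name[order(sc$read_index)]
    }
  }
  if (length(body) == 0L) {
    ids <- oriented_ids(read_names %||% character(0))
    return(new_neighbor_table(matrix(NA_integer_, nrow(ids), 0L),
                              matrix(NA_real_, nrow(ids), 0L), 0L, ids,
                              logical(nrow(ids))))
  }
  f <- function(i) vapply(parts, `[[`, character(1), i)
  qid <- f(1); qor <- f(2); tid <- f(3); tor <- f(4)
  rnk <- as.integer(f(5)); dst <- as.numeric(f(6))
  if (anyNA(rnk) || anyNA(dst))
    stop("non-numeric rank or distance in ", path)
  read_names <- read_names %||% unique(qid)
  ridx <- match(qid, read_names)
  tidx <- match(tid, read_names)
  if (anyNA(ridx) || anyNA(tidx))
    stop("candidate file names reads absent from `read_names`")
  n <- 2L * length(read_names)
  k <- max(rnk)
  idx <- matrix(NA_integer_, n, k)
  dist <- matrix(NA_real_, n, k)
  qv <- vertex_id(ridx, qor)
  tv <- vertex_id(tidx, tor)
  idx[cbind(qv, rnk)] <- tv
  dist[cbind(qv, rnk)] <- dst
  flagged <- rowSums(!is.na(idx)) < k
  new_neighbor_table(idx, dist, k, oriented_ids(read_names), flagged)
}
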