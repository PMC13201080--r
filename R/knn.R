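# Exact brute-force k-NN (the oracle) and the approximate NN-descent search
# over embeddings, under cosine or Euclidean distance.

#' Cosine distance between two vectors
#'
#' `1 - <u, v> / (||u|| ||v||)`. Scale-invariant, which makes it robust to
#' read-length differences: a long read and a short read sampled from the
#' same locus point in similar directions even though their magnitudes
#' differ. A zero-norm input has no direction; its distance is defined as 1
#' with a warning.
#'
#' @param u,v numeric vectors of equal length.
#' @return A single number in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have the same length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-norm vector in cosine_distance; returning 1")
    return(1)
  }
  1 - sum(u * v) / (nu * nv)
}

# Normalize rows to unit length; zero rows stay zero (=> cosine distance 1
# against everything).
normalize_rows <- function(x) {
  rn <- sqrt(Matrix::rowSums(x^2))
  zero <- rn == 0
  rn[zero] <- 1
  if (is(x, "sparseMatrix")) {
    x <- Matrix::Diagonal(x = 1 / rn) %*% x
  } else {
    x <- x / rn
  }
  list(x = x, zero = zero)
}

knn_input <- function(x) {
  if (inherits(x, "embeddings")) {
    list(mat = x$matrix, ids = x$row_ids)
  } else if (inherits(x, "feature_batch")) {
    list(mat = x$rows, ids = x$row_ids)
  } else {
    list(mat = x, ids = NULL)
  }
}

# forbidden[i] = 1-based partner row to exclude for query i, or 0
forbidden_rows <- function(ids, n) {
  if (is.null(ids)) return(integer(n))
  partner_vertex(seq_len(n))
}

new_neighbor_table <- function(idx, dist, k, ids, flagged) {
  structure(list(idx = idx, dist = dist, k = k, ids = ids, flagged = flagged),
            class = "neighbor_table")
}

#' @exportS3Method base::print
print.neighbor_table <- function(x, ...) {
  cat(sprintf("neighbor_table: %d queries x k=%d (%d flagged)\n",
              nrow(x$idx), x$k, sum(x$flagged)))
  invisible(x)
}

#' Exact k-nearest neighbours by brute force
#'
#' Computes the true `k` smallest distances for every row against all other
#' rows, in blocks of dense linear algebra. When `x` carries oriented-read
#' identifiers (an `embeddings` or `feature_batch`), each query additionally
#' excludes the opposite orientation of its own read, since both orientations
#' derive from the same molecule. Ties are broken by smaller row index.
#'
#' @param x an `embeddings`, `feature_batch`, or plain (sparse or dense)
#'   matrix with one point per row.
#' @param k number of neighbours per query.
#' @param metric `"cosine"` or `"euclidean"`.
#' @param block queries per dense block (memory/speed trade-off).
#' @return A `neighbor_table`: list with `idx` and `dist` (`n x k` matrices,
#'   `NA`-padded when fewer than `k` eligible points exist, in which case the
#'   query is flagged), `k`, `ids`, `flagged`.
#' @export
exact_knn <- function(x, k, metric = c("cosine", "euclidean"), block = 1024L) {
  metric <- match.arg(metric)
  inp <- knn_input(x)
  n <- nrow(inp$mat)
  if (k < 1) stop("`k` must be >= 1")
  forb <- forbidden_rows(inp$ids, n)
  n_excl <- 1L + as.integer(!is.null(inp$ids))
  k_eff <- min(k, n - n_excl)
  flagged <- rep(k_eff < k, n)

  if (metric == "cosine") {
    nm <- normalize_rows(inp$mat)
    X <- nm$x
    flagged <- flagged | nm$zero
  } else {
    X <- inp$mat
    sq <- Matrix::rowSums(X^2)
  }
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    rows <- lo:hi
    if (metric == "cosine") {
      D <- 1 - as.matrix(Matrix::tcrossprod(X[rows, , drop = FALSE], X))
    } else {
      G <- as.matrix(Matrix::tcrossprod(X[rows, , drop = FALSE], X))
      D <- sqrt(pmax(outer(sq[rows], sq, "+") - 2 * G, 0))
    }
    for (r in seq_along(rows)) {
      q <- rows[r]
      d <- D[r, ]
      d[q] <- Inf
      if (forb[q] > 0L && forb[q] <= n) d[forb[q]] <- Inf
      ord <- order(d)[seq_len(k_eff)]  # stable: ties resolve to smaller index
      if (k_eff > 0L) {
        idx[q, seq_len(k_eff)] <- ord
        dst[q, seq_len(k_eff)] <- d[ord]
      }
    }
  }
  new_neighbor_table(idx, dst, as.integer(k), inp$ids, flagged)
}

#' Approximate k-nearest neighbours via NN-descent
#'
#' Builds the k-NN graph with the NN-descent algorithm: neighbour lists are
#' initialized from random-projection-tree leaves and iteratively refined by
#' exploring neighbours of neighbours until updates die out. Cosine distance
#' only, single-threaded, and fully seeded, so identical inputs and seed give
#' identical tables. The internal list length is larger than `k`
#' (`max(k + 2, 2k + 10)`, capped at `n - 1`) to absorb the self and
#' opposite-orientation exclusions and to improve convergence; results are
#' truncated to `k` afterwards.
#'
#' @param x an `embeddings` or plain dense matrix.
#' @param k neighbours per query.
#' @param n_trees random projection trees used for initialization; more trees
#'   improve starting recall at linear cost.
#' @param seed integer seed.
#' @param max_iter maximum NN-descent iterations.
#' @param max_candidates per-node candidate-list size for the local join.
#' @param tol convergence: stop when an iteration updates at most
#'   `tol * n * K` list entries.
#' @return A `neighbor_table` with the same schema and exclusion rules as
#'   [exact_knn()]; distances are exact cosine distances of the reported
#'   neighbours.
#' @export
ann_knn <- function(x, k, n_trees = 20L, seed = 1L, max_iter = 12L,
                    max_candidates = 24L, tol = 0.001) {
  inp <- knn_input(x)
  if (is(inp$mat, "sparseMatrix"))
    stop("ann_knn requires dense embeddings; project the features first")
  n <- nrow(inp$mat)
  if (k < 1) stop("`k` must be >= 1")
  if (n < 3) stop("need at least 3 points for ann_knn")
  nm <- normalize_rows(inp$mat)
  forb <- forbidden_rows(inp$ids, n)
  K <- min(n - 1L, max(k + 2L, 2L * k + 10L))
  res <- cpp_nndescent(t(nm$x), K, as.integer(forb), as.integer(n_trees),
                       leaf_size = max(15L, K), max_candidates = as.integer(max_candidates),
                       max_iter = as.integer(max_iter), tol = tol,
                       seed = as.integer(seed))
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  flagged <- nm$zero
  for (q in seq_len(n)) {
    row <- res$idx[q, ]
    ok <- which(!is.na(row))
    take <- head(ok, k)
    if (length(take) > 0L) {
      idx[q, seq_along(take)] <- row[take]
      dst[q, seq_along(take)] <- res$dist[q, take]
    }
    if (length(take) < k) flagged[q] <- TRUE
  }
  new_neighbor_table(idx, dst, as.integer(k), inp$ids, flagged)
}

#' Recall of an approximate neighbour table against the exact table
#'
#' Mean over queries of the fraction of exact neighbours recovered,
#' `|approx_q intersect exact_q| / k`.
#'
#' @param approx,exact `neighbor_table`s over the same queries and `k`.
#' @return A number in `[0, 1]`.
#' @export
recall_at_k <- function(approx, exact) {
  stopifnot(inherits(approx, "neighbor_table"),
            inherits(exact, "neighbor_table"))
  if (nrow(approx$idx) != nrow(exact$idx) || approx$k != exact$k)
    stop("neighbor tables must cover the same queries at the same k")
  n <- nrow(approx$idx)
  hits <- vapply(seq_len(n), function(q) {
    e <- exact$idx[q, ]
    e <- e[!is.na(e)]
    if (length(e) == 0L) return(NA_real_)
    length(intersect(approx$idx[q, ], e)) / exact$k
  }, numeric(1))
  mean(hits, na.rm = TRUE)
}
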