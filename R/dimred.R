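# Sparse random projection with IDF weighting fused into one reusable
# matrix, applied batch-wise so the full feature matrix is never
# materialized.

#' Generate a sparse random projection matrix
#'
#' Entries are i.i.d.: `+s` with probability `density/2`, `-s` with
#' probability `density/2`, zero otherwise, with `s = sqrt(1 / (density *
#' d))`. This is the very-sparse Achlioptas/Li scheme, whose projections have
#' unbiased inner products: `E[<Rx, Ry>] = <x, y>`. The default density
#' `1/sqrt(m)` makes the matrix cheap to build and apply while keeping the
#' variance of preserved distances small at the dimensions used here.
#'
#' @param m input dimension (alphabet size).
#' @param d target dimension; default 1000 balances distance fidelity against
#'   memory and nearest-neighbour search cost.
#' @param density nonzero fraction in `(0, 1]`; default `1/sqrt(m)`.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return An object of class `srp_matrix`: list with `entries` (sparse
#'   `m x d` `dgCMatrix`), `density`, `scale`, `seed`.
#' @export
srp_matrix <- function(m, d = 1000L, density = NULL, seed = 1L) {
  if (m < 1 || d < 1) stop("`m` and `d` must be >= 1")
  density <- density %||% (1 / sqrt(m))
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  s <- sqrt(1 / (density * d))
  withr::with_seed(seed, {
    total <- as.numeric(m) * as.numeric(d)
    nnz <- rbinom(1L, size = min(total, .Machine$integer.max), prob = density)
    # uniform positions without replacement over the m x d grid
    pos <- sample(total, nnz) - 1
    i <- as.integer(pos %% m)
    j <- as.integer(pos %/% m)
    x <- s * sample(c(-1, 1), nnz, replace = TRUE)
    entries <- Matrix::sparseMatrix(i = i, j = j, x = x, index1 = FALSE,
                                    dims = c(m, d))
  })
  structure(list(entries = entries, density = density, scale = s,
                 seed = as.integer(seed)),
            class = "srp_matrix")
}

#' @exportS3Method base::print
print.srp_matrix <- function(x, ...) {
  cat(sprintf("srp_matrix: %d x %d, density %.4g, scale %.4g\n",
              nrow(x$entries), ncol(x$entries), x$density, x$scale))
  invisible(x)
}

#' Fuse IDF weighting into the projection matrix
#'
#' IDF weighting and random projection are both linear, so weighting the
#' features then projecting equals projecting with a row-scaled matrix:
#' `(X diag(w)) R = X (diag(w) R)`. Pre-multiplying once and reusing the
#' fused matrix for every batch removes a full pass over the features.
#'
#' @param projection an `srp_matrix`.
#' @param idf an `idf_weights` vector of length `m`.
#' @return An object of class `weighted_projection` with the fused sparse
#'   `m x d` matrix in `entries`.
#' @export
fuse_projection <- function(projection, idf) {
  stopifnot(inherits(projection, "srp_matrix"))
  m <- nrow(projection$entries)
  if (length(idf) != m)
    stop("`idf` length (", length(idf), ") must equal projection rows (", m, ")")
  entries <- Matrix::Diagonal(x = as.numeric(idf)) %*% projection$entries
  structure(list(entries = methods::as(entries, "CsparseMatrix"),
                 density = projection$density, scale = projection$scale,
                 weighted = TRUE),
            class = "weighted_projection")
}

projection_entries <- function(wp) {
  if (inherits(wp, c("srp_matrix", "weighted_projection"))) wp$entries else wp
}

#' Project feature batches into the embedding space
#'
#' Multiplies each batch's sparse rows by the (weighted) projection matrix
#' and stacks the dense results in input order. Each row's product is
#' computed independently, so the result is identical for any partition of
#' the reads into batches.
#'
#' @param batches a `feature_batch`, or a list of them (a batch stream).
#' @param wp a `weighted_projection`, `srp_matrix`, or plain matrix.
#' @return An object of class `embeddings`: list with `matrix` (dense
#'   `2 n_reads x d`), `row_ids`, `flagged`.
#' @export
project_stream <- function(batches, wp) {
  if (inherits(batches, "feature_batch")) batches <- list(batches)
  R <- projection_entries(wp)
  if (length(batches) == 0L) {
    return(structure(list(matrix = matrix(0, 0L, ncol(R)),
                          row_ids = oriented_ids(character(0)),
                          flagged = logical(0)),
                     class = "embeddings"))
  }
  mats <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    fb <- batches[[b]]
    stopifnot(inherits(fb, "feature_batch"))
    if (ncol(fb$rows) != nrow(R))
      stop("feature batch has ", ncol(fb$rows), " columns but projection has ",
           nrow(R), " rows")
    mats[[b]] <- as.matrix(fb$rows %*% R)
  }
  # read indices restart within each batch; renumber over the whole stream
  names_in_order <- unlist(lapply(batches, function(b)
    b$row_ids$name[c(TRUE, FALSE)]), use.names = FALSE)
  structure(
    list(matrix = do.call(rbind, mats),
         row_ids = oriented_ids(names_in_order),
         flagged = unlist(lapply(batches, function(b) b$flagged),
                          use.names = FALSE)),
    class = "embeddings"
  )
}

#' @exportS3Method base::print
print.embeddings <- function(x, ...) {
  cat(sprintf("embeddings: %d oriented reads x %d dimensions\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Persist embeddings to disk
#'
#' Writes the dense matrix as a raw little-endian float64 binary file and the
#' row identifiers plus dimensions as a sidecar TSV (`<path>.ids.tsv` with a
#' `# dims` header line), so embeddings survive without any serialized R
#' objects.
#'
#' @param emb an `embeddings` object.
#' @param path output path for the matrix binary.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(emb$matrix)), con, size = 8L, endian = "little")
  ids <- emb$row_ids
  ids$flagged <- emb$flagged
  idpath <- paste0(path, ".ids.tsv")
  writeLines(sprintf("# dims\t%d\t%d", nrow(emb$matrix), ncol(emb$matrix)),
             idpath)
  suppressWarnings(write.table(ids, idpath, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  idpath <- paste0(path, ".ids.tsv")
  hdr <- strsplit(readLines(idpath, n = 1L), "\t")[[1]]
  nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
  ids <- read.delim(idpath, skip = 1L, stringsAsFactors = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = nr * nc, size = 8L,
               endian = "little")
  structure(list(matrix = matrix(x, nr, nc, byrow = TRUE),
                 row_ids = ids[c("name", "read", "orient")],
                 flagged = ids$flagged),
            class = "embeddings")
}
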