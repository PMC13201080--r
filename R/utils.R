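# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Oriented-read identifiers
#'
#' Every read contributes two vertices to the overlap graph: the read as given
#' (`+`) and its reverse complement (`-`). Rows of feature matrices,
#' embeddings and neighbour tables follow the interleaved order
#' read1+, read1-, read2+, read2-, ...; read `i` occupies rows `2i - 1` (`+`)
#' and `2i` (`-`).
#'
#' @param read_names character vector of read names.
#' @return A data frame with one row per oriented read: `name`, `read`
#'   (1-based read index), `orient` (`"+"` or `"-"`).
#' @export
oriented_ids <- function(read_names) {
  n <- length(read_names)
  data.frame(
    name = rep(read_names, each = 2L),
    read = rep(seq_len(n), each = 2L),
    orient = rep(c("+", "-"), times = n),
    stringsAsFactors = FALSE
  )
}

# vertex id of read i (1-based) with orientation "+"/"-"
vertex_id <- function(read, orient) {
  2L * read - ifelse(orient == "+", 1L, 0L)
}

# partner vertex (same read, opposite orientation)
partner_vertex <- function(v) {
  v + ifelse(v %% 2L == 1L, 1L, -1L)
}

# undirected edge key for vertex pairs; exact for < 2^26 vertices
edge_key <- function(u, v) {
  lo <- pmin(u, v)
  hi <- pmax(u, v)
  lo * 2^27 + hi
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
}
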