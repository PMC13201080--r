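# Shared fixtures and independent oracles for the test suite.

# random DNA strings
rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# construct a kmer_count_table directly (for filter/idf unit tests)
make_count_table <- function(kmers, counts, n_reads) {
  ord <- order(kmers)
  structure(list(k = unique(nchar(kmers)), kmer = kmers[ord],
                 count = as.integer(counts[ord]),
                 n_reads = as.integer(n_reads)),
            class = "kmer_count_table")
}

# independent brute-force k-NN oracle: full distance matrix, no blocking,
# plain sort; excludes self (and the opposite-orientation row when
# oriented = TRUE)
brute_force_knn <- function(mat, k, metric = "cosine", oriented = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- if (metric == "cosine") {
      ni <- sqrt(sum(mat[i, ]^2)); nj <- sqrt(sum(mat[j, ]^2))
      if (ni == 0 || nj == 0) 1 else 1 - sum(mat[i, ] * mat[j, ]) / (ni * nj)
    } else {
      sqrt(sum((mat[i, ] - mat[j, ])^2))
    }
  }
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    if (oriented) d[i + ifelse(i %% 2 == 1, 1L, -1L)] <- Inf
    ord <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    idx[i, seq_along(ord)] <- ord
    dst[i, seq_along(ord)] <- d[ord]
  }
  list(idx = idx, dist = dst)
}

# brute-force truth-graph oracle: all read pairs, interval arithmetic by hand
brute_force_truth_edges <- function(truth, min_overlap = 1) {
  n <- nrow(truth)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- min(truth$ref_end[i], truth$ref_end[j]) -
      max(truth$ref_start[i], truth$ref_start[j])
    if (ov >= min_overlap) {
      same <- truth$strand[i] == truth$strand[j]
      vp <- function(r, o) 2L * r - ifelse(o == "+", 1L, 0L)
      e <- if (same)
        rbind(c(vp(i, "+"), vp(j, "+")), c(vp(i, "-"), vp(j, "-")))
      else
        rbind(c(vp(i, "+"), vp(j, "-")), c(vp(i, "-"), vp(j, "+")))
      out[[length(out) + 1]] <- cbind(t(apply(e, 1, sort)), ov)
    }
  }
  if (length(out) == 0)
    return(data.frame(u = integer(0), v = integer(0), size = integer(0)))
  m <- do.call(rbind, out)
  data.frame(u = m[, 1], v = m[, 2], size = m[, 3])
}

# small simulated dataset reused by several module tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_genome(60000, 0.1, 2000, seed = 31)
      cache <<- c(simulate_reads(g, depth = 10, mean_len = 3000, len_sd = 300,
                                 sub_rate = 0.01, ins_rate = 0.005,
                                 del_rate = 0.005, seed = 32),
                  list(genome = g))
    }
    cache
  }
})

# canonical edge set of an overlap graph, as a sorted key vector
edge_keys <- function(edges) sort(edges$u * 1e6 + edges$v)
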