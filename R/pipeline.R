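# End-to-end orchestration: configuration, the overlap pipeline, and
# evaluation against a reference.

CONFIG_FIELDS <- list(
  k_mer_size = "integer", min_count = "integer", sampling_fraction = "numeric",
  dims = "integer", density = "numeric", n_neighbors = "integer",
  n_trees = "integer", batch_size = "integer", metric = "character",
  scheme = "character", seed = "integer", backend = "character"
)

#' Pipeline configuration
#'
#' Collects every tunable of the overlap pipeline with defaults matching the
#' published recommendations for large genomes: 1000 embedding dimensions,
#' 15% k-mer sampling, 600 initialization trees for NN-descent, 20 output
#' neighbours, batches of 100,000 reads, and a platform-specific k-mer size
#' (31 for HiFi, 13 for ONT, 11 for CycloneSEQ reads, reflecting each
#' platform's error profile).
#'
#' @param preset sequencing platform preset fixing `k_mer_size`: `"ont"`
#'   (13), `"hifi"` (31) or `"cyclone"` (11).
#' @param k_mer_size k-mer size; overrides the preset when given.
#' @param min_count minimum collection frequency for alphabet k-mers.
#' @param sampling_fraction alphabet sampling fraction in `(0, 1]`.
#' @param dims embedding dimension for the sparse random projection.
#' @param density projection density; `NA` means the `1/sqrt(m)` default.
#' @param n_neighbors candidates reported per oriented read (output k).
#' @param n_trees NN-descent initialization trees.
#' @param batch_size reads per feature batch.
#' @param metric `"cosine"` or `"euclidean"` (exact backend only).
#' @param scheme feature weighting scheme; see [featurize_batch()].
#' @param seed master seed; all stage seeds derive from it.
#' @param backend `"nndescent"` or `"exact"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("ont", "hifi", "cyclone"),
                            k_mer_size = NULL, min_count = 2L,
                            sampling_fraction = 0.15, dims = 1000L,
                            density = NA_real_, n_neighbors = 20L,
                            n_trees = 600L, batch_size = 100000L,
                            metric = c("cosine", "euclidean"),
                            scheme = "idf", seed = 1L,
                            backend = c("nndescent", "exact")) {
  preset <- match.arg(preset)
  k_mer_size <- as.integer(k_mer_size %||%
                             switch(preset, hifi = 31L, ont = 13L, cyclone = 11L))
  metric <- match.arg(metric)
  backend <- match.arg(backend)
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  cfg <- list(k_mer_size = k_mer_size, min_count = as.integer(min_count),
              sampling_fraction = sampling_fraction, dims = as.integer(dims),
              density = density, n_neighbors = as.integer(n_neighbors),
              n_trees = as.integer(n_trees),
              batch_size = as.integer(batch_size), metric = metric,
              scheme = scheme, seed = as.integer(seed), backend = backend)
  if (cfg$k_mer_size < 3 || cfg$k_mer_size > 31)
    stop("`k_mer_size` must be in [3, 31]")
  if (cfg$sampling_fraction <= 0 || cfg$sampling_fraction > 1)
    stop("`sampling_fraction` must be in (0, 1]")
  if (!is.na(cfg$density) && (cfg$density <= 0 || cfg$density > 1))
    stop("`density` must be in (0, 1]")
  if (cfg$dims < 1 || cfg$n_neighbors < 1 || cfg$batch_size < 1)
    stop("`dims`, `n_neighbors` and `batch_size` must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' @exportS3Method base::print
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (f in names(CONFIG_FIELDS))
    cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Write / read a pipeline configuration as a key=value file
#'
#' Round-trips losslessly: every field is written and typed back per the
#' configuration schema.
#'
#' @param config a `pipeline_config`.
#' @param path config file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(sprintf("%s=%s", names(CONFIG_FIELDS),
                     vapply(names(CONFIG_FIELDS),
                            function(f) format(config[[f]], digits = 17),
                            character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  unknown <- setdiff(keys, names(CONFIG_FIELDS))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- pipeline_config()
  for (i in seq_along(keys)) {
    type <- CONFIG_FIELDS[[keys[i]]]
    cfg[[keys[i]]] <- if (identical(vals[i], "NA")) {
      switch(type, integer = NA_integer_, numeric = NA_real_,
             character = NA_character_)
    } else {
      switch(type,
        integer = as.integer(vals[i]),
        numeric = as.numeric(vals[i]),
        character = vals[i])
    }
  }
  validate <- pipeline_config(
    k_mer_size = cfg$k_mer_size, min_count = cfg$min_count,
    sampling_fraction = cfg$sampling_fraction, dims = cfg$dims,
    density = cfg$density, n_neighbors = cfg$n_neighbors,
    n_trees = cfg$n_trees, batch_size = cfg$batch_size, metric = cfg$metric,
    scheme = cfg$scheme, seed = cfg$seed, backend = cfg$backend)
  validate
}

# split reads into batches of batch_size reads, preserving order
read_batches <- function(seqs, batch_size) {
  n <- length(seqs)
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Run the full overlap-detection pipeline
#'
#' Counts canonical k-mers, filters and samples the alphabet, computes IDF
#' weights, builds the (optionally IDF-fused) sparse random projection,
#' streams feature batches through it, retrieves each oriented read's top-k
#' neighbours, and writes the candidate TSV. A JSON run log with stage
#' timings, the alphabet size and flagged reads is written to
#' `<out>.log.json`.
#'
#' For the `idf` and `tf_idf` schemes the IDF weights are applied inside the
#' fused projection; for `binary`, `tf` and `raw_tf` the unweighted
#' projection is used.
#'
#' @param reads FASTA/FASTQ path (optionally gzipped) or a named
#'   [Biostrings::DNAStringSet].
#' @param config a `pipeline_config`.
#' @param out output candidate TSV path, or `NULL` to skip writing.
#' @return Invisibly, a list with the `neighbor_table`, the `embeddings`,
#'   the alphabet size and the run log.
#' @export
run_overlap <- function(reads, config = pipeline_config(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3]
  log <- list(stages = list())
  tick <- function() proc.time()[3]
  seqs <- if (is.character(reads) && length(reads) == 1L) read_sequences(reads)
    else Biostrings::DNAStringSet(reads)
  if (length(seqs) == 0L) stop("input: no reads found")
  if (length(seqs) < 2L) stop("input: need at least 2 reads, no eligible neighbors")

  t0 <- tick()
  tab <- count_kmers(seqs, config$k_mer_size)
  log$stages$count_kmers <- tick() - t0

  t0 <- tick()
  alphabet <- filter_and_sample(tab, min_count = config$min_count,
                                fraction = config$sampling_fraction,
                                seed = config$seed)
  idf <- idf_weights(tab, alphabet)
  m <- length(alphabet$kmers)
  log$alphabet_size <- m
  log$stages$alphabet <- tick() - t0

  t0 <- tick()
  density <- if (is.na(config$density)) NULL else config$density
  proj <- srp_matrix(m, d = config$dims, density = density,
                     seed = config$seed + 1L)
  weighted <- config$scheme %in% c("idf", "tf_idf")
  wp <- if (weighted) fuse_projection(proj, idf) else proj
  base_scheme <- switch(config$scheme, idf = "binary", tf_idf = "tf",
                        config$scheme)
  log$stages$projection <- tick() - t0

  t0 <- tick()
  batches <- lapply(read_batches(seqs, config$batch_size), function(ix)
    featurize_batch(seqs[ix], alphabet, scheme = base_scheme))
  emb <- project_stream(batches, wp)
  log$flagged_reads <- unique(emb$row_ids$name[emb$flagged])
  log$stages$featurize_project <- tick() - t0

  t0 <- tick()
  nt <- if (config$backend == "exact") {
    exact_knn(emb, k = config$n_neighbors, metric = config$metric)
  } else {
    if (config$metric != "cosine")
      stop("knn: the nndescent backend supports cosine distance only")
    ann_knn(emb, k = config$n_neighbors, n_trees = config$n_trees,
            seed = config$seed + 2L)
  }
  log$stages$knn <- tick() - t0

  if (!is.null(out)) {
    write_candidates(nt, out)
    log$output <- out
  }
  log$n_reads <- length(seqs)
  log$elapsed <- tick() - t_all
  if (!is.null(out))
    jsonlite::write_json(log, paste0(out, ".log.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(list(neighbors = nt, embeddings = emb, alphabet_size = m,
                 log = log))
}

# Is this path a truth TSV (vs a PAF)? Truth tables carry the header line.
is_truth_table <- function(path) {
  first <- readLines(path, n = 1L)
  startsWith(first, "read_id\t")
}

#' Evaluate a candidate table against a reference
#'
#' Builds the overlap graph from a candidate TSV (optionally truncated to
#' the top `top_j` candidates per oriented read) and the reference graph from
#' either a simulator truth TSV or a PAF of read-to-reference alignments,
#' then scores the graph. Candidate read names unknown to the reference are
#' counted; more than 1% unknown is an error.
#'
#' @param candidates candidate TSV path or a `neighbor_table`.
#' @param reference truth-TSV path, PAF path, or a `reference_graph`.
#' @param top_j keep only the top `top_j` candidates per oriented read
#'   (`NULL` keeps all).
#' @param min_overlap minimum reference intersection in bp.
#' @param out optional path for the metrics JSON (curve TSV alongside).
#' @param ... passed to [reference_from_paf()] for PAF references.
#' @return A `graph_metrics` object (invisibly when `out` is given).
#' @export
run_evaluate <- function(candidates, reference, top_j = NULL,
                         min_overlap = 1L, out = NULL, ...) {
  ref <- if (inherits(reference, "reference_graph")) reference
    else if (is_truth_table(reference))
      truth_reference_graph(read_truth_tsv(reference),
                            min_overlap = min_overlap)
    else reference_from_paf(reference, min_overlap = min_overlap, ...)

  nt <- if (inherits(candidates, "neighbor_table")) candidates
    else {
      cand_names <- unique(read_candidates(candidates)$ids$name)
      unknown <- setdiff(cand_names, ref$read_names)
      if (length(unknown) > length(cand_names) * 0.01)
        stop(length(unknown), " candidate read names unknown to the reference (",
             paste(head(unknown, 5), collapse = ", "), " ...)")
      read_candidates(candidates, read_names = ref$read_names)
    }
  if (all(is.na(nt$idx))) stop("candidate table is empty")

  if (!is.null(top_j)) {
    if (top_j > nt$k) stop("`top_j` exceeds the table's k = ", nt$k)
    nt$idx <- nt$idx[, seq_len(top_j), drop = FALSE]
    nt$dist <- nt$dist[, seq_len(top_j), drop = FALSE]
    nt$k <- as.integer(top_j)
  }
  metrics <- score_graph(build_overlap_graph(nt), ref)
  if (!is.null(out)) {
    write_metrics_json(metrics, out)
    return(invisible(metrics))
  }
  metrics
}

#' Simulate reads and write FASTQ plus truth table
#'
#' Thin wrapper over [generate_genome()] and [simulate_reads()] that writes
#' `<out_prefix>.fastq`, `<out_prefix>.truth.tsv` and
#' `<out_prefix>.genome.fa`.
#'
#' @param out_prefix output path prefix.
#' @param genome_length,repeat_fraction,repeat_unit_len see
#'   [generate_genome()].
#' @param depth,mean_len,len_sd,sub_rate,ins_rate,del_rate see
#'   [simulate_reads()].
#' @param seed master seed.
#' @return Invisibly, the list from [simulate_reads()] plus the genome.
#' @export
run_simulate <- function(out_prefix, genome_length = 500000,
                         repeat_fraction = 0.2, repeat_unit_len = 5000,
                         depth = 30, mean_len = 20000, len_sd = 2000,
                         sub_rate = 0.05 / 3, ins_rate = 0.05 / 3,
                         del_rate = 0.05 / 3, seed = 1L) {
  genome <- generate_genome(genome_length, repeat_fraction, repeat_unit_len,
                            seed = seed)
  sim <- simulate_reads(genome, depth = depth, mean_len = mean_len,
                        len_sd = len_sd, sub_rate = sub_rate,
                        ins_rate = ins_rate, del_rate = del_rate,
                        seed = seed + 1L)
  write_reads_fastq(sim$reads, paste0(out_prefix, ".fastq"))
  write_truth_tsv(sim$truth, paste0(out_prefix, ".truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genome$sequence, "synthetic_genome")),
    paste0(out_prefix, ".genome.fa"))
  invisible(c(sim, list(genome = genome)))
}
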