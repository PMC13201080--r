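# Synthetic genome generator, read simulator and truth reference graphs.

test_that("generate_genome honours length, repeat fraction and determinism", {
  g0 <- generate_genome(1000, 0, 100, seed = 1)
  expect_equal(nchar(g0$sequence), 1000)
  expect_equal(nrow(g0$repeat_annotations), 0)
  expect_false(grepl("[^ACGT]", g0$sequence))

  g <- generate_genome(1000, 0.3, 100, seed = 1)
  span <- sum(g$repeat_annotations$end - g$repeat_annotations$start)
  expect_gte(span, 200)
  expect_lte(span, 400)
  # every annotated copy is a verbatim repeat of its source
  for (r in seq_len(nrow(g$repeat_annotations))) {
    a <- g$repeat_annotations[r, ]
    expect_gte(a$start, 0)
    expect_lte(a$end, nchar(g$sequence))
    expect_identical(substr(g$sequence, a$start + 1, a$end),
                     substr(g$sequence, a$source_start + 1,
                            a$source_start + (a$end - a$start)))
  }
  expect_identical(generate_genome(1000, 0.3, 100, seed = 1)$sequence,
                   g$sequence)
  expect_false(identical(generate_genome(1000, 0.3, 100, seed = 2)$sequence,
                         g$sequence))

  expect_error(generate_genome(1000, 1.2, 100), "repeat_fraction")
  expect_error(generate_genome(1000, -0.1, 100), "repeat_fraction")
  expect_error(generate_genome(500, 0, 600), "repeat_unit_len")
})

test_that("error-free simulated reads are exact genome substrings", {
  g <- generate_genome(20000, 0, 1000, seed = 5)
  sim <- simulate_reads(g, depth = 5, mean_len = 2000, len_sd = 200, seed = 6)
  expect_equal(sim$truth$length, sim$truth$ref_end - sim$truth$ref_start)
  for (i in seq_len(nrow(sim$truth))) {
    src <- substr(g$sequence, sim$truth$ref_start[i] + 1, sim$truth$ref_end[i])
    obs <- as.character(sim$reads[[i]])
    if (sim$truth$strand[i] == "+") expect_identical(obs, src)
    else expect_identical(obs, revcomp_chr(src))
  }
})

test_that("read count and total bases track the requested depth", {
  g <- generate_genome(100000, 0, 5000, seed = 7)
  sim <- simulate_reads(g, depth = 30, mean_len = 2000, len_sd = 200, seed = 8)
  expect_lt(abs(nrow(sim$truth) - 30 * 100000 / 2000), 0.2 * 1500)
  expect_lt(abs(sum(sim$truth$length) / (30 * 100000) - 1), 0.10)
})

test_that("substitution rate is recovered as edit distance to the source", {
  g <- generate_genome(50000, 0, 2000, seed = 9)
  sim <- simulate_reads(g, depth = 1, mean_len = 2000, len_sd = 100,
                        sub_rate = 0.05, seed = 10)
  take <- head(seq_len(nrow(sim$truth)), 20)
  ed <- vapply(take, function(i) {
    src <- substr(g$sequence, sim$truth$ref_start[i] + 1, sim$truth$ref_end[i])
    if (sim$truth$strand[i] == "-") src <- revcomp_chr(src)
    aln <- Biostrings::pairwiseAlignment(
      as.character(sim$reads[[i]]), src, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(0, -1),
      gapOpening = 0, gapExtension = 1)
    -Biostrings::score(aln) / nchar(src)
  }, numeric(1))
  expect_gt(mean(ed), 0.04)
  expect_lt(mean(ed), 0.06)
})

test_that("simulation is byte-identical for a fixed seed", {
  g <- generate_genome(30000, 0.2, 2000, seed = 11)
  s1 <- simulate_reads(g, depth = 3, mean_len = 2000, sub_rate = 0.02,
                       ins_rate = 0.01, del_rate = 0.01, seed = 12)
  s2 <- simulate_reads(g, depth = 3, mean_len = 2000, sub_rate = 0.02,
                       ins_rate = 0.01, del_rate = 0.01, seed = 12)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  expect_error(simulate_reads(g, depth = 1, mean_len = 40000), "mean_len")
})

test_that("truth graphs follow the oriented strand rule on intervals", {
  truth <- data.frame(read_id = c("A", "B"),
                      ref_start = c(0, 5000), ref_end = c(10000, 15000),
                      strand = c("+", "+"), length = c(10000, 10000))
  rg <- truth_reference_graph(truth, min_overlap = 1)
  # vertices: A+ = 1, A- = 2, B+ = 3, B- = 4
  expect_equal(edge_keys(rg$edges), edge_keys(data.frame(u = c(1, 2),
                                                         v = c(3, 4))))
  expect_equal(rg$edges$size, c(5000, 5000))

  truth$strand <- c("+", "-")
  rg2 <- truth_reference_graph(truth)
  expect_equal(edge_keys(rg2$edges), edge_keys(data.frame(u = c(1, 2),
                                                          v = c(4, 3))))

  # half-open touch is not an overlap
  touch <- data.frame(read_id = c("A", "B"),
                      ref_start = c(0, 10000), ref_end = c(10000, 20000),
                      strand = c("+", "+"), length = c(10000, 10000))
  expect_equal(nrow(truth_reference_graph(touch)$edges), 0)
})

test_that("tiled reads give the hand-counted oriented edge set", {
  truth <- data.frame(read_id = paste0("r", 1:5),
                      ref_start = (0:4) * 5000,
                      ref_end = (0:4) * 5000 + 10000,
                      strand = "+", length = 10000)
  rg <- truth_reference_graph(truth)
  expect_equal(nrow(rg$edges), 8)  # 4 adjacent pairs x 2 orientations
  oracle <- brute_force_truth_edges(truth)
  expect_equal(edge_keys(rg$edges), edge_keys(oracle))
})

test_that("truth graphs match the brute-force oracle and are strand-symmetric", {
  sim <- small_sim()
  rg <- truth_reference_graph(sim$truth, min_overlap = 50)
  oracle <- brute_force_truth_edges(sim$truth, min_overlap = 50)
  expect_equal(edge_keys(rg$edges), edge_keys(oracle))
  expect_equal(sort(rg$edges$size), sort(oracle$size))
  # (A+,B+) present <=> (A-,B-) present, and likewise cross-strand
  partner <- function(v) v + ifelse(v %% 2 == 1, 1, -1)
  mirrored <- data.frame(u = pmin(partner(rg$edges$u), partner(rg$edges$v)),
                         v = pmax(partner(rg$edges$u), partner(rg$edges$v)))
  expect_equal(edge_keys(rg$edges), edge_keys(mirrored))
})

test_that("FASTQ and truth TSV round-trip through files", {
  sim <- small_sim()
  fq <- tempfile(fileext = ".fastq.gz")
  tsv <- tempfile(fileext = ".tsv")
  write_reads_fastq(sim$reads, fq)
  write_truth_tsv(sim$truth, tsv)
  back <- read_sequences(fq)
  expect_identical(as.character(back), as.character(sim$reads))
  expect_equal(read_truth_tsv(tsv), sim$truth)
})
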