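# PAF reference graphs and the four quality metrics.

paf_line <- function(qname, qlen, qstart, qend, strand, tstart, tend,
                     mapq, tname = "chr1", tags = "tp:A:P") {
  paste(qname, qlen, qstart, qend, strand, tname, 1e6, tstart, tend,
        qend - qstart, qend - qstart, mapq, tags, sep = "\t")
}

mk_reference <- function(n_reads, u, v, size, retained = seq_len(n_reads)) {
  structure(list(n_reads = n_reads, read_names = paste0("r", seq_len(n_reads)),
                 edges = data.frame(u = u, v = v, size = size),
                 retained = retained, min_overlap = 1L),
            class = "reference_graph")
}

mk_graph <- function(n_reads, u, v) {
  structure(list(edges = data.frame(u = u, v = v,
                                    rank = rep(1L, length(u)),
                                    distance = rep(0.1, length(u))),
                 n_reads = n_reads, read_names = paste0("r", seq_len(n_reads)),
                 k = 6L),
            class = "overlap_graph")
}

test_that("PAF reference applies the read filters and strand rule", {
  p <- tempfile(fileext = ".paf")
  writeLines(c(
    paf_line("A", 10000, 0, 10000, "+", 0, 10000, 60),
    paf_line("B", 10000, 0, 10000, "+", 5000, 15000, 60),
    paf_line("C", 4000, 0, 4000, "+", 6000, 10000, 60),    # < 5 kb read
    paf_line("D", 10000, 0, 10000, "+", 7000, 17000, 10),  # MAPQ < 30
    paf_line("E", 10000, 0, 3000, "+", 8000, 11000, 60)    # < 50% aligned
  ), p)
  rg <- reference_from_paf(p)
  expect_equal(rg$n_reads, 5)
  expect_equal(rg$retained, c(1, 2))  # only A and B pass
  # A+ = 1, B+ = 3: same-strand pair with 5 kb intersection
  expect_equal(edge_keys(rg$edges), edge_keys(data.frame(u = c(1, 2),
                                                         v = c(3, 4))))
  expect_equal(rg$edges$size, c(5000, 5000))

  # opposite strands cross the orientations
  writeLines(c(paf_line("A", 10000, 0, 10000, "+", 0, 10000, 60),
               paf_line("B", 10000, 0, 10000, "-", 5000, 15000, 60)), p)
  rg2 <- reference_from_paf(p)
  expect_equal(edge_keys(rg2$edges), edge_keys(data.frame(u = c(1, 2),
                                                          v = c(4, 3))))
})

test_that("PAF parsing keeps the best primary record and flags bad lines", {
  p <- tempfile(fileext = ".paf")
  writeLines(c(
    paf_line("A", 10000, 0, 10000, "+", 0, 10000, 60),
    paf_line("A", 10000, 0, 9000, "+", 50000, 59000, 50),   # lower MAPQ
    paf_line("A", 10000, 0, 8000, "+", 90000, 98000, 60, tags = "tp:A:S"),
    paf_line("B", 10000, 0, 10000, "+", 2000, 12000, 60)
  ), p)
  rg <- reference_from_paf(p)
  expect_equal(rg$edges$size, c(8000, 8000))  # A placed at [0,10000)

  writeLines("A\t10000\t0", p)
  expect_error(read_paf(p), "line 1")
})

test_that("score_graph computes the four metrics on worked examples", {
  # 10 edges among 12 reads, 2 missing from the reference
  u <- seq(1, by = 2, length.out = 10)
  v <- u + 2
  ref <- mk_reference(12, u[1:8], v[1:8], size = rep(100, 8))
  m <- score_graph(mk_graph(12, u, v), ref)
  expect_equal(m$error_rate, 0.2)

  # incorrect edges count as zero overlap in the mean
  ref2 <- mk_reference(3, c(1, 1), c(3, 5), size = c(2000, 1000))
  m2 <- score_graph(mk_graph(3, c(1, 1, 3), c(3, 5, 5)), ref2)
  expect_equal(m2$mean_overlap_size, 1000)
  expect_equal(m2$n_correct_edges, 2)

  expect_error(score_graph(mk_graph(3, integer(0), integer(0)), ref2),
               "no edges")
})

test_that("connected components count the correct-edge subgraph", {
  # 3 reads = 6 vertices; triangle on 1,3,5 plus pair 2-4; vertex 6 isolated
  ref <- mk_reference(3, c(1, 3, 1, 2), c(3, 5, 5, 4), size = rep(50, 4))
  m <- score_graph(mk_graph(3, c(1, 3, 1, 2), c(3, 5, 5, 4)), ref)
  expect_equal(m$error_rate, 0)
  expect_equal(m$n_cc, 3)
  expect_equal(m$n_singletons, 1)
  expect_equal(m$coc[1:6], c(2, 1, 2, 1, 2, 0))
})

test_that("a graph equal to its reference scores perfectly", {
  sim <- small_sim()
  ref <- truth_reference_graph(sim$truth, min_overlap = 100)
  g <- structure(list(edges = cbind(ref$edges[c("u", "v")],
                                    rank = 1L, distance = 0),
                      n_reads = ref$n_reads, read_names = ref$read_names,
                      k = 6L),
                 class = "overlap_graph")
  m <- score_graph(g, ref)
  expect_equal(m$error_rate, 0)
  expect_equal(m$mean_overlap_size, mean(ref$edges$size))
  touched <- unique(c(ref$edges$u, ref$edges$v))
  expect_equal(m$n_singletons, 2 * ref$n_reads - length(touched))
})

test_that("error rate cannot rise when the reference gains edges", {
  sim <- small_sim()
  g <- structure(list(edges = cbind(
    truth_reference_graph(sim$truth, 1)$edges[c("u", "v")],
    rank = 1L, distance = 0),
    n_reads = nrow(sim$truth),
    read_names = sim$truth$read_id, k = 6L), class = "overlap_graph")
  errs <- vapply(c(2000, 500, 1), function(mo)
    score_graph(g, truth_reference_graph(sim$truth, mo))$error_rate,
    numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("the low-connectivity curve counts vertices under each threshold", {
  mk_metrics <- function(coc) structure(
    list(coc = coc, retained_vertices = seq_along(coc)),
    class = "graph_metrics")
  expect_equal(low_connectivity_curve(mk_metrics(rep(6, 10)), 5)$fraction, 0)
  expect_equal(low_connectivity_curve(mk_metrics(rep(0, 10)), c(1, 4))$fraction,
               c(1, 1))
  expect_equal(low_connectivity_curve(mk_metrics(c(0, 1, 5, 9)), 5)$fraction,
               0.5)
})

test_that("metrics serialize to flat JSON with the curve alongside", {
  ref <- mk_reference(3, c(1, 3), c(3, 5), size = c(10, 20))
  m <- score_graph(mk_graph(3, c(1, 3), c(3, 5)), ref)
  p <- tempfile(fileext = ".json")
  write_metrics_json(m, p)
  flat <- jsonlite::read_json(p)
  expect_equal(flat$error_rate, 0)
  expect_equal(flat$n_edges, 2)
  expect_true(file.exists(paste0(p, ".coc_curve.tsv")))
})
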