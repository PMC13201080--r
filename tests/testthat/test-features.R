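# Canonical k-mer counting, alphabet sampling, IDF weights and featurization.

test_that("canonical_kmer takes the lexicographic min of strand pair", {
  expect_identical(canonical_kmer("ACG"), "ACG")
  expect_identical(canonical_kmer("CGT"), "ACG")  # revcomp(CGT) = ACG
  expect_identical(canonical_kmer("AT"), "AT")    # palindrome
  expect_error(canonical_kmer("ANG"), "A, C, G, T")
  # idempotence on random k-mers
  km <- rand_dna(50, 13, seed = 21)
  expect_identical(canonical_kmer(canonical_kmer(km)), canonical_kmer(km))
})

test_that("count_kmers matches hand enumeration and masks non-ACGT windows", {
  tab <- count_kmers("ACGTA", 3)
  expect_equal(tab$n_reads, 1)
  expect_equal(setNames(tab$count, tab$kmer), c(ACG = 2, GTA = 1))

  tab2 <- count_kmers(c("ACGT", "ACGT"), 4)
  expect_equal(setNames(tab2$count, tab2$kmer), c(ACGT = 2))

  expect_equal(length(count_kmers("ANGT", 3)$kmer), 0)
  empty <- count_kmers(character(0), 5)
  expect_equal(empty$n_reads, 0)
  expect_equal(length(empty$kmer), 0)
})

test_that("filter_and_sample filters by CF then samples deterministically", {
  tab <- make_count_table(c("AAA", "AAC", "AAG"), c(1, 5, 9), 10)
  a <- filter_and_sample(tab, min_count = 2, fraction = 1)
  expect_identical(a$kmers, c("AAC", "AAG"))
  expect_identical(unname(a$index[a$kmers]), seq_along(a$kmers))

  full <- filter_and_sample(tab, min_count = 1, fraction = 1)
  expect_identical(full$kmers, tab$kmer)

  big <- make_count_table(unique(rand_dna(1500, 8, seed = 22))[1:1000],
                          rep(5, 1000), 50)
  expect_equal(length(filter_and_sample(big, 1, 0.15, seed = 3)$kmers), 150)
  expect_identical(filter_and_sample(big, 1, 0.15, seed = 3)$kmers,
                   filter_and_sample(big, 1, 0.15, seed = 3)$kmers)
  expect_false(identical(filter_and_sample(big, 1, 0.15, seed = 4)$kmers,
                         filter_and_sample(big, 1, 0.15, seed = 3)$kmers))
  expect_error(filter_and_sample(tab, min_count = 100), "survive")
})

test_that("IDF weights are ln(N / CF), zero at CF = N, strictly monotone", {
  tab <- make_count_table(c("AAA", "AAC", "AAG", "AAT"),
                          c(100, round(100 / exp(1)), 10, 3), 100)
  a <- filter_and_sample(tab, 1, 1)
  w <- idf_weights(tab, a)
  expect_equal(unname(w[["AAA"]]), 0)
  expect_equal(unname(w[["AAC"]]), log(100 / round(100 / exp(1))))
  expect_lt(abs(w[["AAC"]] - 1), 0.02)
  # lower CF => strictly larger weight
  expect_true(w[["AAT"]] > w[["AAG"]], )
  expect_true(w[["AAG"]] > w[["AAC"]])
  bad <- structure(list(k = 3L, kmers = c("AAA", "CCC"),
                        index = c(AAA = 1L, CCC = 2L)),
                   class = "kmer_alphabet")
  expect_error(idf_weights(tab, bad), "missing")
})

test_that("featurize_batch matches hand-counted literal occurrences", {
  a <- structure(list(k = 3L, kmers = "ACG", index = c(ACG = 1L)),
                 class = "kmer_alphabet")
  fb <- featurize_batch(c(r1 = "ACGACG"), a, scheme = "binary")
  expect_equal(as.matrix(fb$rows), matrix(c(1, 0), 2, 1), ignore_attr = TRUE)

  raw <- featurize_batch(c(r1 = "ACGACG"), a, scheme = "raw_tf")
  expect_equal(as.numeric(raw$rows[1, ]), 2)  # two literal ACG matches
  expect_equal(as.numeric(raw$rows[2, ]), 0)  # revcomp CGTCGT has none

  # tf normalizes counts within the oriented read
  a2 <- structure(list(k = 3L, kmers = c("ACG", "CAC"),
                       index = c(ACG = 1L, CAC = 2L)),
                  class = "kmer_alphabet")
  tf <- featurize_batch(c(r1 = "CACGACG"), a2, scheme = "tf")
  expect_equal(as.numeric(tf$rows[1, ]), c(2 / 3, 1 / 3))

  # idf scheme multiplies presence by the weights
  w <- structure(c(2, 0.5), names = c("ACG", "CAC"), class = "idf_weights")
  fidf <- featurize_batch(c(r1 = "CACGACG"), a2, scheme = "idf", idf = w)
  expect_equal(as.numeric(fidf$rows[1, ]), c(2, 0.5))
})

test_that("degenerate reads produce flagged all-zero rows", {
  a <- structure(list(k = 5L, kmers = "AAAAA", index = c(AAAAA = 1L)),
                 class = "kmer_alphabet")
  fb <- featurize_batch(c(short = "ACG", nomatch = "CGCGCGCG"), a)
  expect_equal(sum(fb$rows), 0)
  expect_true(all(fb$flagged))
})

test_that("the minus row of a read equals the plus row of its revcomp", {
  sim <- small_sim()
  tab <- count_kmers(sim$reads, 11)
  a <- filter_and_sample(tab, 2, 0.2, seed = 23)
  reads <- as.character(sim$reads[1:10])
  fb <- featurize_batch(reads, a, scheme = "raw_tf")
  fb_rc <- featurize_batch(revcomp_chr(reads), a, scheme = "raw_tf")
  for (i in seq_along(reads)) {
    expect_equal(as.numeric(fb$rows[2 * i, ]), as.numeric(fb_rc$rows[2 * i - 1, ]))
    expect_equal(as.numeric(fb$rows[2 * i - 1, ]), as.numeric(fb_rc$rows[2 * i, ]))
  }
})

test_that("collection frequency dominates and tracks document frequency", {
  # depth matters for the surrogate claim: at realistic coverage most
  # k-mers occur once per read, so CF ~ DF on log scale
  g <- generate_genome(150000, 0.1, 2000, seed = 33)
  sim <- simulate_reads(g, depth = 25, mean_len = 5000, len_sd = 500,
                        sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
                        seed = 34)
  k <- 13
  tab <- count_kmers(sim$reads, k)
  a <- filter_and_sample(tab, 2, 0.25, seed = 24)
  df <- kmer_doc_freq(sim$reads, k, a$kmers)
  cf <- tab$count[match(a$kmers, tab$kmer)]
  expect_true(all(cf >= df))
  expect_gte(cor(log(cf), log(df))^2, 0.999)
})

test_that("external k-mer dumps import and canonicalize", {
  p <- tempfile()
  writeLines(c("ACG 4", "CGT 2", "TTT 1"), p)
  tab <- read_kmer_dump(p, n_reads = 5)
  # CGT folds into canonical ACG; TTT folds to AAA
  expect_equal(setNames(tab$count, tab$kmer), c(AAA = 1, ACG = 6))
  expect_equal(tab$n_reads, 5)
})
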