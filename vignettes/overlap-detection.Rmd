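---
title: "Long-read overlap detection with weighted k-mer features, sparse random projection and nearest-neighbour search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-read overlap detection with weighted k-mer features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

All-vs-all overlap detection is the first and most expensive step of
overlap-layout-consensus assembly: given n long reads (10-30 kb, 1-9%
error), find for each read the other reads sequenced from overlapping
genomic intervals. `olann` treats this as a nearest-neighbour search in a
bag-of-words space, the way single-cell pipelines treat cell similarity:

1. **Featurization.** A canonical k-mer alphabet is sampled from the
   dataset, and every read becomes two sparse rows of a feature matrix —
   one for the read as given (`+`), one for its reverse complement (`-`) —
   by literal matching of the alphabet k-mers. A dataset of n reads yields
   2n oriented rows; orientations are the vertices of the final overlap
   graph, so a same-strand overlap links `A+`-`B+`, a cross-strand overlap
   links `A+`-`B-`.
2. **IDF weighting.** Column j is scaled by `w_j = ln(N / c_j)`, where N is
   the read count and `c_j` the k-mer's total occurrence count (collection
   frequency, CF). Down-weighting ubiquitous k-mers — transposons, tandem
   repeats, low-complexity stretches — is what lets cosine similarity see
   through repeat-induced spurious similarity. CF stands in for the textbook
   document frequency (DF, reads containing the k-mer) because CF falls out
   of counting for free while DF needs a second pass; on long-read data the
   two are nearly identical on log scale (`kmer_doc_freq()` quantifies
   this per dataset, and the test suite checks R² ≥ 0.999 on the package's
   simulated fixtures).
3. **Sparse random projection.** The 2n x m matrix never exists in memory:
   features are built in read batches and multiplied by a sparse ±s
   projection matrix (density 1/sqrt(m), s = sqrt(1/(density·d)),
   Achlioptas/Li scheme, unbiased inner products). Because weighting and
   projection are both linear, the IDF diagonal is folded into the
   projection once (`fuse_projection()`), and each batch needs a single
   sparse product. The result is independent of the batch partition, which
   the tests assert bitwise.
4. **k-NN search.** Each oriented read's top-k neighbours under cosine
   distance become candidate overlaps. Cosine rather than Euclidean because
   it is scale-invariant: reads of different lengths from the same locus
   differ in vector magnitude, not direction. The exact backend is blocked
   dense linear algebra (the oracle); the approximate backend is a native
   NN-descent (random-projection-tree initialization, then neighbours-of-
   neighbours refinement), single-threaded and seeded so runs are
   reproducible.

The candidate table (`query`, `target`, orientation, rank, distance) is a
*best overlap graph* in the making: only each read's k strongest overlaps
are kept, which downstream layout stages prefer anyway since short
overlaps are pruned as transitive.

## Evaluation framework

An overlap graph over 2n oriented vertices is scored against a reference
graph built either from simulator truth intervals
(`truth_reference_graph()`) or from read-to-reference PAF alignments
(`reference_from_paf()`, filtering reads shorter than 5 kb, aligned over
less than 50% of their length, or mapped below MAPQ 30). Two intervals
overlap when their intersection is at least `min_overlap` bp (default 1,
the most permissive ground truth; intervals are 0-based half-open, so
touching intervals do not overlap). Four metrics:

- **error rate** — incorrect edges over total edges;
- **mean overlap size** — mean reference intersection over *all* edges,
  incorrect edges counted as zero;
- **#COC** — per-vertex degree among correct edges (0 makes the vertex a
  singleton), summarized by `low_connectivity_curve()`;
- **#CC** — connected components of the correct-edge subgraph, including
  isolated vertices (the standard component definition; vertex counts are
  reported so the other reading is recoverable).

Reads removed by the PAF filters keep their vertices, so |V| stays 2n and
any edge touching them is scored incorrect; they are excluded from the
component and connectivity denominators so filtered and unfiltered datasets
remain comparable. Both `n_cc` (retained vertices) and `n_cc_all` (all 2n)
are reported.

## The synthetic-data generator

`generate_genome()` builds an i.i.d.-uniform background in blocks of
`repeat_unit_len` and designates `round(repeat_fraction * n_blocks)` of the
non-initial blocks as verbatim copies of earlier segments. This emulates
dispersed duplications — the repeat class that actually confuses overlap
detection at read scale — with a deterministic repeat span. The default
unit of 5 kb is the scale of LINE-class elements: long enough that a 10 kb
read can sit mostly inside a repeat copy, short enough that 20 kb reads
span it.

`simulate_reads()` draws read count `round(depth * L / mean_len)`,
truncated-normal lengths (floor 500 bp in realistic regimes), uniform start
positions and strands, and applies independent per-base deletion,
substitution and insertion after extraction. The truth table records the
error-free source interval, strand and emitted length of every read.

What the generator does *not* emulate: platform error profiles (homopolymer
compression errors, strand bias, chimeras), non-uniform coverage, and
heterozygosity. Passing tests on these fixtures therefore demonstrates the
pipeline's geometry — that IDF-weighted cosine neighbourhoods recover true
overlaps under uniform error — not platform-calibrated accuracy on real
data, for which the PAF-based evaluation path exists.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_mer_size` | 13 (ONT preset) | 31 for HiFi, 11 for CycloneSEQ; higher accuracy supports longer k |
| `min_count` | 2 | CF filter removing error singletons at ≥10x depth |
| `sampling_fraction` | 0.15 | alphabet fraction after filtering |
| `dims` | 1000 | embedding dimension; distance fidelity rises with d |
| `density` | 1/sqrt(m) | projection sparsity |
| `n_neighbors` | 20 | candidates reported per oriented read |
| `n_trees` | 600 | NN-descent initialization trees |
| `batch_size` | 100000 | reads per feature batch (memory, not results) |

All defaults follow the published large-genome recommendations; only
results-neutral knobs (`batch_size`) trade memory for time.

## Numerical choices and degenerate inputs

- IDF uses the natural log; any fixed base only rescales columns jointly.
  `N` counts reads, not oriented reads.
- The alphabet is sorted before the seeded sampling draw, so alphabets are
  identical across platforms; alphabet size is `max(1, round(fraction *
  survivors))`.
- Ties in neighbour lists break toward the smaller row index; NN-descent is
  single-threaded with one RNG stream, so candidate tables are
  reproducible byte-for-byte at a fixed seed.
- A read shorter than k, or without any alphabet match, yields an all-zero
  row: it is flagged, embeds at the origin, and its cosine distance is
  defined as 1 against everything.
- Each query excludes itself and the opposite orientation of its own read;
  the two orientations share no literal k-mer matches but can collide after
  projection, so the exclusion is explicit.
- Fused-projection equivalence is exact in infinite precision; tests allow
  1e-9 relative error for float64 reassociation.

## Design choices where the design was open

- **Orientation vs canonicalization.** Counting uses canonical k-mers
  (strand-symmetric CF), but featurization matches alphabet k-mers
  literally against the read and its reverse complement. Canonicalizing
  read windows instead would make the `+` and `-` rows identical and
  orientation unrecoverable; literal matching is the only reading that
  reconciles canonical counting with a 2n-vertex oriented graph.
- **Filter before sampling.** The min-count filter runs before alphabet
  sampling, so the sampling fraction refers to plausibly-genomic k-mers.
- **Candidate TSV layout** (query, orientation, target, orientation, rank,
  distance at 6 decimals, query-then-rank order) is fixed so outputs diff
  cleanly; oriented pairs are reported, with a names sidecar mapping read
  names to indices.
- **NN-descent in-package.** The exact backend must be independent of the
  approximate one to serve as its oracle; the approximate backend is a
  from-scratch NN-descent with RP-tree initialization, the algorithm with
  the best accuracy/speed trade-off for this task among ANN families.

## Problem sizes used by the test suite

The acceptance fixtures use a 500 kb genome with 20% repeat content at 30x
coverage of 20 kb reads (95% accuracy) — about 750 reads, 1,500 oriented
vertices — and a 250 kb / 50x / 5 kb configuration (5,000 oriented
vertices) for the approximate-search recall check; ordering experiments
(weighting schemes, metrics, depth and length sweeps) run on 200-300 kb
genomes. These sizes exercise every code path, including repeat-induced
ambiguity, while keeping the full suite in the minutes range.

## Known limitations

- At 95% accuracy and k = 13, a k-mer survives error-free in *both* reads
  of a pair with probability ≈ 0.26, so even near-complete overlaps sit at
  cosine distances above ~0.6. The spread of pairwise distances on such
  fixtures is narrow, which caps the measurable pre/post-projection
  distance correlation near R² ≈ 0.97 at d = 3000 — the residual is the
  irreducible 1/sqrt(d) projection noise, not an implementation artifact
  (the test suite computes this number; see the distance-preservation
  test). Real datasets with broader distance spreads correlate higher.
- The simulator's uniform error model understates structured errors;
  platform-specific k-mer sizes are presets, not fitted.
- The NN-descent backend holds all embeddings densely in memory; datasets
  beyond a few million oriented reads would need the batch-streamed
  embedding store (`write_embeddings()`) plus an out-of-core search, which
  is not implemented.
- Assembly-side steps — transitive reduction, layout, consensus — are out
  of scope; the candidate TSV is the hand-off point to an assembler.
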