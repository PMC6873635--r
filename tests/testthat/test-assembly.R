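# De Bruijn construction, unitig extraction, multi-k assembly, greedy fallback.

test_that("k-mer edges enumerate both the read and its reverse complement", {
  g <- build_dbg("ACGTACGT", k = 5L, min_count = 1L)
  # ACGTACGT is its own reverse complement: 4 distinct 5-mers; counts pool the
  # read, its mirror, and each edge's reverse-complement partner
  expect_equal(g$kmer, sort(c("ACGTA", "CGTAC", "GTACG", "TACGT")))
  expect_equal(g$count, rep(4L, 4L))

  g2 <- build_dbg("AAACCCGGG", k = 5L, min_count = 1L)
  expect_true(all(revcomp_dna(g2$kmer) %in% g2$kmer))  # strand closure
})

test_that("degenerate graphs: empty read set, reads shorter than k", {
  expect_equal(length(build_dbg(character(), 21L)$kmer), 0L)
  expect_equal(length(build_dbg(c("ACGT", "GGCC"), 21L, 1L)$kmer), 0L)
  expect_equal(nrow(extract_unitigs(build_dbg(character(), 21L))), 0L)
})

test_that("deep error-free coverage of one allele compacts to one unitig", {
  withr::local_seed(61)
  allele <- rand_dna(500)
  reads <- tiling_reads(allele, 100L, 3L)  # ~33x
  g <- build_dbg(reads, 21L, min_count = 2L)
  contigs <- extract_unitigs(g)
  expect_equal(nrow(contigs), 1L)
  expect_equal(contigs$sequence, canonical_dna(allele))
  expect_gte(contigs$coverage, 20)
})

test_that("a mid-sequence SNP between two haplotypes leaves a bubble", {
  withr::local_seed(62)
  a1 <- rand_dna(400)
  a2 <- mutate_allele(a1, n_snps = 1L, seed = 62)
  reads <- rbind(tiling_reads(a1, 100L, 5L), tiling_reads(a2, 100L, 5L))
  contigs <- extract_unitigs(build_dbg(reads, 21L, min_count = 1L))
  # never a single full-length chimera-free contig
  expect_gte(nrow(contigs), 2L)
  expect_false(canonical_dna(a1) %in% contigs$sequence &&
               nrow(contigs) == 1L)
})

test_that("multi-k assembly is independent per k and length-gated", {
  withr::local_seed(63)
  allele <- rand_dna(450)
  reads <- tiling_reads(allele, 100L, 2L)  # ~50x
  by_k <- assemble_multi_k(reads)
  expect_named(by_k, c("11", "15", "21", "33", "35"))
  expect_true(canonical_dna(allele) %in% by_k[["35"]]$sequence)

  short <- tiling_reads(allele, 30L, 2L)   # too short for k=33/35
  by_k2 <- assemble_multi_k(short)
  expect_equal(nrow(by_k2[["35"]]), 0L)
  expect_gt(nrow(by_k2[["21"]]), 0L)

  empty <- assemble_multi_k(read_set(character(), character()))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("unitig extraction matches the brute-force rewriting oracle", {
  withr::local_seed(64)
  for (i in 1:30) {
    src <- rand_dna(sample(60:140, 1))
    n_reads <- sample(3:10, 1)
    starts <- sort(sample(max(1, nchar(src) - 40L), n_reads, replace = TRUE))
    reads <- substring(src, starts, pmin(starts + sample(25:40, n_reads,
                                                         replace = TRUE),
                                         nchar(src)))
    k <- sample(c(11L, 15L, 21L), 1)
    got <- extract_unitigs(build_dbg(reads, k, 1L), min_tip_count = 1L)
    expect_equal(sort(got$sequence), oracle_unitigs(reads, k))
  }
})

test_that("assembly is invariant to strand flips and read order", {
  withr::local_seed(65)
  allele <- rand_dna(400)
  reads <- tiling_reads(allele, 90L, 4L)
  ref <- extract_unitigs(build_dbg(reads, 21L))$sequence
  flipped <- read_set(reads$id, revcomp_dna(reads$sequence))
  expect_equal(extract_unitigs(build_dbg(flipped, 21L))$sequence, ref)
  shuffled <- reads[sample(nrow(reads)), ]
  expect_equal(extract_unitigs(build_dbg(shuffled, 21L))$sequence, ref)
})

test_that("near-complete reconstruction across random alleles at 20x", {
  withr::local_seed(66)
  hits <- vapply(1:100, function(i) {
    allele <- rand_dna(sample(400:600, 1))
    reads <- tiling_reads(allele, 100L, 5L)  # 20x
    by_k <- assemble_multi_k(reads)
    any(vapply(by_k, function(ct) canonical_dna(allele) %in% ct$sequence,
               logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("greedy fallback merges by longest exact overlap, deterministically", {
  withr::local_seed(67)
  src <- rand_dna(175)
  a <- substr(src, 1, 100)
  b <- substr(src, 76, 175)  # overlap exactly 25 = default min_overlap
  out <- greedy_assemble(c(a, b))
  expect_equal(out$sequence, canonical_dna(src))

  # tiling reads reconstruct the source
  reads <- tiling_reads(src, 60L, 20L)
  expect_equal(greedy_assemble(reads)$sequence, canonical_dna(src))

  # non-overlapping reads come back deduplicated
  r1 <- rand_dna(50); r2 <- rand_dna(50)
  out2 <- greedy_assemble(c(r1, r2, r1))
  expect_setequal(out2$sequence, canonical_dna(c(r1, r2)))

  # reverse-complemented input yields the same contigs
  expect_equal(greedy_assemble(revcomp_dna(c(a, b)))$sequence,
               canonical_dna(src))
})
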