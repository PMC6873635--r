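# FASTQ merging and perfect-match-fraction recruitment.

test_that("merge_fastq pools mates from paired files, disregarding pairing", {
  withr::local_seed(11)
  dir <- withr::local_tempdir()
  r1 <- read_set(sprintf("r%03d/1", 1:50), replicate(50, rand_dna(100)))
  r2 <- read_set(sprintf("r%03d/2", 1:50), replicate(50, rand_dna(100)))
  p1 <- write_fastq(r1, file.path(dir, "s_1.fastq"))
  p2 <- write_fastq(r2, file.path(dir, "s_2.fastq"))
  merged <- merge_fastq(c(p1, p2))
  expect_equal(nrow(merged), 100L)
  expect_true(all(c(r1$id, r2$id) %in% merged$id))  # mate tags retained
})

test_that("gzipped and plain FASTQ merge identically", {
  withr::local_seed(12)
  dir <- withr::local_tempdir()
  rs <- read_set(sprintf("r%03d", 1:30), replicate(30, rand_dna(80)))
  plain <- write_fastq(rs, file.path(dir, "a.fastq"))
  gz <- write_fastq(rs, file.path(dir, "a.fastq.gz"))
  expect_equal(merge_fastq(c(plain, plain)), merge_fastq(c(gz, plain)))
})

test_that("degenerate FASTQ inputs: empty file, malformed record", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.fastq")
  file.create(empty)
  expect_equal(nrow(merge_fastq(empty)), 0L)

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+"), bad)  # truncated 4-line record
  expect_error(merge_fastq(bad), "malformed FASTQ")
})

test_that("perfect_match_fraction agrees with the brute-force oracle", {
  withr::local_seed(21)
  locus <- toy_locus(n = 3L, len = 300L, seed = 21)

  # read equal to a substring of an allele
  a <- locus$sequence[2]
  expect_equal(perfect_match_fraction(substr(a, 50, 149), locus)$fraction, 1.0)

  # 100 bp read: first 60 bp from an allele, last 40 bp unrelated random
  repeat {
    tail40 <- rand_dna(40)
    read <- paste0(substr(a, 101, 160), tail40)
    if (oracle_lcs(read, locus$sequence) == 60L) break
  }
  pm <- perfect_match_fraction(read, locus)
  expect_equal(pm$fraction, 0.60)
  expect_equal(pm$orientation, "forward")

  # reverse complement of a 90 bp allele segment, padded to 100 bp
  repeat {
    pad <- rand_dna(10)
    read <- paste0(revcomp_dna(substr(a, 11, 100)), pad)
    if (oracle_lcs(read, locus$sequence) == 90L) break
  }
  pm <- perfect_match_fraction(read, locus)
  expect_equal(pm$fraction, 0.90)
  expect_equal(pm$orientation, "reverse")
})

test_that("fraction ties break toward forward orientation, lowest allele id", {
  seg <- rand_dna(60)
  locus <- mlst_locus("x", c(2L, 5L),
                      c(paste0(rand_dna(50), seg, rand_dna(50)),
                        paste0(rand_dna(40), seg, rand_dna(60))))
  pm <- perfect_match_fraction(seg, locus)
  expect_equal(pm$fraction, 1.0)
  expect_equal(pm$orientation, "forward")
  expect_equal(pm$best_allele_id, 2L)
})

test_that("recruitment tiers are nested and thresholds are inclusive", {
  withr::local_seed(31)
  locus <- toy_locus(n = 2L, len = 400L, seed = 31)
  reads <- tiling_reads(locus$sequence[1], 100L, 7L)
  tiers <- recruit_reads(reads, locus)
  # error-free interior reads all have fraction 1.0
  expect_equal(nrow(tier_reads(tiers, 0.9)), nrow(reads))
  expect_equal(nrow(tier_reads(tiers, 0)), nrow(reads))

  # one read with fraction exactly 0.60: member of 0/0.3/0.6, not 0.9
  repeat {
    tail40 <- rand_dna(40)
    r60 <- paste0(substr(locus$sequence[1], 1, 60), tail40)
    if (oracle_lcs(r60, locus$sequence) == 60L) break
  }
  t2 <- recruit_reads(read_set("r60", r60), locus)
  expect_equal(tier_reads(t2, 0.6)$id, "r60")
  expect_equal(tier_reads(t2, 0.3)$id, "r60")
  expect_equal(nrow(tier_reads(t2, 0.9)), 0L)
})

test_that("reads without a shared seed k-mer are never recruited", {
  withr::local_seed(41)
  locus <- toy_locus(n = 2L, len = 350L, seed = 41)
  repeat {
    bg <- rand_dna(3000)
    if (!oracle_shared_kmer(bg, locus$sequence, 20L)) break
  }
  reads <- tiling_reads(bg, 100L, 50L)
  tiers <- recruit_reads(reads, locus)
  expect_equal(nrow(tiers$hits), 0L)
  # reads shorter than the seed are never recruited either
  short <- read_set("s1", substr(locus$sequence[1], 1, 15))
  expect_equal(nrow(recruit_reads(short, locus)$hits), 0L)
})

test_that("recruitment is strand-symmetric and order-invariant", {
  withr::local_seed(51)
  locus <- toy_locus(n = 3L, len = 300L, seed = 51)
  for (i in 1:10) {
    reads <- read_set(sprintf("r%02d", 1:20),
                      c(replicate(10, substr(locus$sequence[1],
                                             s <- sample(200, 1), s + 99)),
                        replicate(10, rand_dna(100))))
    tiers <- recruit_reads(reads, locus)
    flipped <- read_set(reads$id, revcomp_dna(reads$sequence))
    tiers_rc <- recruit_reads(flipped, locus)
    shuffled <- reads[sample(nrow(reads)), ]
    tiers_sh <- recruit_reads(read_set(shuffled$id, shuffled$sequence), locus)
    for (th in tiers$thresholds) {
      ids <- sort(tier_reads(tiers, th)$id)
      expect_equal(sort(tier_reads(tiers_rc, th)$id), ids)
      expect_equal(sort(tier_reads(tiers_sh, th)$id), ids)
    }
  }
})
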