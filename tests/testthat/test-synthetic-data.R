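# Synthetic benchmark generator: databases, genomes, reads, mutants.

test_that("generated databases are valid, reproducible and SNP-structured", {
  cfg <- sim_config(seed = 7L)
  g1 <- generate_allele_db(cfg)
  g2 <- generate_allele_db(cfg)
  expect_identical(g1, g2)  # same seed, identical output
  expect_equal(length(g1$db$schema), 7L)
  expect_true(all(vapply(g1$db$loci, length, integer(1)) == 10L))
  expect_equal(nrow(validate_db(g1$db)), 0L)  # pairwise distinct, ACGT only
  expect_equal(length(g1$profiles$st), 20L)
  lens <- nchar(unlist(lapply(g1$db$loci, `[[`, "sequence")))
  expect_true(all(lens >= 400 & lens <= 600))

  g3 <- generate_allele_db(sim_config(seed = 8L))
  expect_false(identical(g1$db, g3$db))
})

test_that("sample genomes embed each chosen allele exactly once, both strands occur", {
  cfg <- sim_config(seed = 17L)
  gen <- generate_allele_db(cfg)
  chosen <- setNames(gen$profiles$alleles[1, ], gen$profiles$schema)
  genome <- build_sample_genome(gen$db, chosen, config = cfg, seed = 18L)
  pos <- attr(genome, "positions")
  expect_equal(pos$locus, gen$profiles$schema)
  for (i in seq_len(nrow(pos))) {
    emb <- substring(genome, pos$start[i], pos$end[i])
    truth <- mlstyper:::locus_seq(gen$db$loci[[pos$locus[i]]],
                                  chosen[[pos$locus[i]]])
    expect_equal(if (pos$strand[i] == "+") emb else revcomp_dna(emb), truth,
                 ignore_attr = TRUE)
  }
  # background chunks share no seed-length k-mer with any allele
  alleles <- unlist(lapply(gen$db$loci, `[[`, "sequence"), use.names = FALSE)
  bounds <- rbind(c(1, pos$start[1] - 1),
                  cbind(pos$end[-nrow(pos)] + 1, pos$start[-1] - 1),
                  c(pos$end[nrow(pos)] + 1, nchar(genome)))
  for (r in seq_len(nrow(bounds))) {
    chunk <- substring(genome, bounds[r, 1], bounds[r, 2])
    expect_lt(mlstyper:::.max_match_run(chunk, alleles), cfg$seed_length)
  }
  # zero background: alleles separated by 1 kb spacers
  g0 <- build_sample_genome(gen$db, chosen, background_length = 0L,
                            config = cfg, seed = 19L)
  emb_len <- sum(vapply(gen$profiles$schema, function(l)
    nchar(mlstyper:::locus_seq(gen$db$loci[[l]], chosen[[l]])), integer(1)))
  expect_equal(nchar(g0), 8L * 1000L + emb_len)
})

test_that("read simulation honours coverage, error rate and determinism", {
  withr::local_seed(23)
  genome <- rand_dna(20000)
  cfg <- sim_config(seed = 23L, coverage = 30, read_length = 100L)
  reads <- simulate_reads(genome, cfg, seed = 24L)
  expected <- 30 * 20000 / 100
  expect_lt(abs(nrow(reads) - expected) / expected, 0.10)

  # error-free reads are exact substrings of the genome or its revcomp
  idx <- sample(nrow(reads), 200)
  rc <- revcomp_dna(genome)
  expect_true(all(vapply(reads$sequence[idx], function(s)
    grepl(s, genome, fixed = TRUE) || grepl(s, rc, fixed = TRUE),
    logical(1))))

  # same seed, byte-identical FASTQ
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, c("a_1.fastq", "a_2.fastq"))
  p2 <- file.path(dir, c("b_1.fastq", "b_2.fastq"))
  simulate_reads(genome, cfg, seed = 25L, paths = p1)
  simulate_reads(genome, cfg, seed = 25L, paths = p2)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  # substitution errors appear at roughly the requested rate
  cfg_err <- sim_config(seed = 23L, coverage = 5, error_rate = 0.01)
  er <- simulate_reads(genome, cfg_err, seed = 26L)
  mism <- vapply(er$sequence[1:200], function(s)
    !(grepl(s, genome, fixed = TRUE) || grepl(s, rc, fixed = TRUE)),
    logical(1))
  expect_gt(mean(mism), 0.3)   # 100 bp at 1%: most reads carry >= 1 error
})

test_that("mutate_allele applies exact edits and avoids collisions", {
  locus <- toy_locus(n = 5L, len = 300L, seed = 27)
  a <- locus$sequence[1]
  snp <- mutate_allele(a, n_snps = 1L, avoid = locus$sequence, seed = 28L)
  expect_equal(nchar(snp), nchar(a))
  expect_equal(sum(strsplit(snp, "")[[1]] != strsplit(a, "")[[1]]), 1L)

  del <- mutate_allele(a, n_snps = 0L,
                       indel = list(position = 100L, length = 3L,
                                    type = "del"),
                       avoid = locus$sequence, seed = 29L)
  expect_equal(nchar(del), nchar(a) - 3L)
  ins <- mutate_allele(a, n_snps = 0L,
                       indel = list(position = 100L, length = 3L,
                                    type = "ins"),
                       avoid = locus$sequence, seed = 30L)
  expect_equal(nchar(ins), nchar(a) + 3L)
  expect_false(snp %in% locus$sequence)
  expect_false(del %in% locus$sequence)

  # impossible to avoid collision: every 1-SNP neighbour is already taken
  tiny <- c("A", "C", "G", "T")
  expect_error(mutate_allele("A", n_snps = 1L, avoid = tiny, max_tries = 10L),
               "non-colliding")
})

test_that("a full synthetic sample round-trips through the pipeline", {
  cfg <- sim_config(seed = 33L)
  gen <- generate_allele_db(cfg)
  for (i in 1:3) {
    s <- simulate_sample(gen$db, gen$profiles, config = cfg,
                         sample_id = paste0("s", i), seed = 33L + i)
    st <- type_sample(s$reads, gen$db, gen$profiles, sample_id = s$sample_id)
    expect_equal(st$st_status, "known")
    expect_equal(st$st_id, s$true_st)
    got <- vapply(st$locus_calls, `[[`, integer(1), "allele_id")
    expect_equal(got, s$truth_alleles)
  }
})

test_that("mutated-allele samples surface as novel at the mutated locus", {
  cfg <- sim_config(seed = 43L)
  gen <- generate_allele_db(cfg)
  hits <- 0L
  for (i in 1:5) {
    locus <- gen$db$schema[(i %% 7) + 1]
    s <- simulate_sample(gen$db, gen$profiles, config = cfg,
                         mutate = list(locus = locus, n_snps = 1L),
                         sample_id = paste0("m", i), seed = 43L + i)
    st <- type_sample(s$reads, gen$db, gen$profiles, sample_id = s$sample_id)
    cl <- st$locus_calls[[locus]]
    if (cl$status == "new" &&
        identical(cl$novel_sequence, s$mutated_sequence)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
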