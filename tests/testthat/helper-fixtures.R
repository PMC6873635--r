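# Small builders shared across test files. Heavyweight benchmark runs used by
# several acceptance checks are generated once and cached for the session.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# uniformly tiling error-free reads over a sequence, both output as given
# strand (recruitment/assembly handle strands themselves)
tiling_reads <- function(seqn, read_length = 100L, step = 10L) {
  n <- nchar(seqn)
  last <- max(1L, n - read_length + 1L)
  starts <- unique(c(seq(1L, last, by = step), last))  # always cover the end
  read_set(sprintf("t%04d", seq_along(starts)),
           substring(seqn, starts, pmin(starts + read_length - 1L, n)))
}

toy_locus <- function(name = "adk", n = 3L, len = 450L, seed = 42L) {
  withr::local_seed(seed)
  base <- rand_dna(len)
  seqs <- base
  while (length(seqs) < n) {
    cand <- mutate_allele(base, n_snps = sample(1:3, 1L), avoid = seqs)
    seqs <- c(seqs, cand)
  }
  mlst_locus(name, seq_len(n), seqs)
}

write_tmp_fasta <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "alleles.fasta")
  writeLines(unlist(Map(function(h, s) c(paste0(">", h), s),
                        names(records), records)), path)
  path
}

write_tmp_profile <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "profiles.tsv")
  writeLines(lines, path)
  path
}

# Hand-built 10-sample prediction/truth fixture over two loci, exercising the
# full label vocabulary including starred third-party calls. The expected
# fractions are hand-counted in the tests that use it.
hand_fixture <- function() {
  samples <- sprintf("s%02d", 1:10)
  truth <- data.frame(sample = samples, A = 1L, B = 2L, ST = 1L,
                      stringsAsFactors = FALSE)
  preds_full <- data.frame(
    sample = samples,
    A = c("1", "1*", "3", "New?", "", "low coverage", "1", "1", "2", "1"),
    B = c("2", "2", "2", "2", "2", "2", "5*", "2", "2", "2"),
    ST = c("1", "1", "new", "new", "ND", "ND", "new", "1", "new", "1"),
    stringsAsFactors = FALSE)
  preds_reduced <- data.frame(
    sample = samples,
    A = c("New?", "4*", "5", "New?", "", "New?", "2*", "New?", "New?",
          "New?"),
    B = c("New?", "New?", "New?", "7", "New?", "New?", "New?", "New?",
          "New?", "low coverage"),
    ST = c("new", "new", "new", "new", "ND", "new", "new", "new", "new",
           "ND"),
    stringsAsFactors = FALSE)
  list(truth = truth, preds_full = preds_full, preds_reduced = preds_reduced)
}

# session cache for the expensive synthetic benchmark shared by the
# correct-allele and new-allele recovery checks
.bench_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.bench_cache$run)) {
    cfg <- sim_config(seed = 104729L)
    bench <- simulate_benchmark(50L, cfg)
    .bench_cache$bench <- bench
    .bench_cache$run <- run_benchmark(bench$samples, bench$db, bench$profiles,
                                      bench$truth)
  }
  list(bench = .bench_cache$bench, run = .bench_cache$run)
}
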