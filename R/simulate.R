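# Synthetic benchmark generator: allele databases, profile tables, genomes
# with embedded alleles, mutated (novel) alleles, and paired short reads.
#
# The generator emulates the leave-correct-allele-out benchmark protocol at
# desk scale: a 7-locus scheme with 400-600 bp alleles, within-locus variants
# a few SNPs apart, uniform paired 100 bp reads with substitution-only
# errors, and a background genome guaranteed to share no seed-length-mer with
# any allele so that recruitment specificity is airtight.

#' Simulation configuration
#'
#' @param n_loci number of housekeeping loci (default 7).
#' @param alleles_per_locus reference alleles per locus (default 10).
#' @param allele_length_range allele length range in bp (default 400-600).
#' @param n_st number of rows in the generated profile table (default 20).
#' @param read_length read length in bp (default 100).
#' @param coverage fold coverage of the sample genome (default 30).
#' @param error_rate per-base substitution probability, in \[0, 0.05\].
#' @param insert_size,insert_sd paired-end fragment length mean and sd.
#' @param background_length background genome length in bp (default 20000).
#' @param seed_length recruitment seed length the background is screened
#'   against (no shared k-mer of this length with any allele).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 7L, alleles_per_locus = 10L,
                       allele_length_range = c(400L, 600L), n_st = 20L,
                       read_length = 100L, coverage = 30, error_rate = 0,
                       insert_size = 300L, insert_sd = 30,
                       background_length = 20000L, seed_length = 20L,
                       seed = 1L) {
  stopifnot(n_loci >= 1L, alleles_per_locus >= 1L,
            allele_length_range[1] >= 1L,
            allele_length_range[2] >= allele_length_range[1],
            read_length >= 1L, coverage > 0,
            error_rate >= 0, error_rate <= 0.05)
  structure(list(n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 allele_length_range = as.integer(allele_length_range),
                 n_st = as.integer(n_st),
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 insert_size = as.integer(insert_size), insert_sd = insert_sd,
                 background_length = as.integer(background_length),
                 seed_length = as.integer(seed_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Random DNA sequence
#'
#' @param n length in bp.
#' @return a single DNA string (uniform over A/C/G/T; uses the current RNG
#'   state).
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

apply_snps <- function(seq, positions, rng_bases = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- sample(alt, 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic allele database and profile table
#'
#' Per locus, allele 1 is random; alleles `2..n` are derivatives of allele 1
#' carrying 1-5 SNPs each (realistic within-locus similarity), pairwise
#' distinct. The profile table enumerates `n_st` random allele combinations
#' with unique STs. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `db` ([mlst_db()]) and `profiles`
#'   ([mlst_profiles()]).
#' @export
generate_allele_db <- function(config = sim_config()) {
  with_seed(config$seed, {
    locus_names <- sprintf("locus%02d", seq_len(config$n_loci))
    loci <- lapply(locus_names, function(nm) {
      len <- sample(seq(config$allele_length_range[1],
                        config$allele_length_range[2]), 1L)
      base <- random_dna(len)
      seqs <- base
      while (length(seqs) < config$alleles_per_locus) {
        cand <- apply_snps(base, sample(len, sample(1:5, 1L)))
        if (!cand %in% seqs) seqs <- c(seqs, cand)
      }
      mlst_locus(nm, seq_along(seqs), seqs)
    })
    db <- mlst_db(loci)
    if (config$n_st > config$alleles_per_locus^config$n_loci)
      stop_mlst("cannot build ", config$n_st, " distinct profiles from ",
                config$alleles_per_locus, "^", config$n_loci,
                " allele combinations")
    combos <- matrix(NA_integer_, config$n_st, config$n_loci,
                     dimnames = list(NULL, locus_names))
    seen <- character()
    i <- 1L
    while (i <= config$n_st) {
      tuple <- vapply(loci, function(l)
        sample(l$allele_id, 1L), integer(1))
      key <- paste(tuple, collapse = "-")
      if (key %in% seen) next
      combos[i, ] <- tuple
      seen <- c(seen, key)
      i <- i + 1L
    }
    list(db = db, profiles = mlst_profiles(locus_names, seq_len(config$n_st),
                                           combos))
  })
}

# random DNA of length n sharing no `seed_length`-mer with any allele
clean_background <- function(n, allele_seqs, seed_length, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    bg <- random_dna(n)
    if (length(allele_seqs) == 0L ||
        .max_match_run(bg, allele_seqs) < seed_length)
      return(bg)
  }
  stop_mlst("could not sample background free of shared ", seed_length,
            "-mers after ", max_tries, " tries")
}

#' Build a sample genome embedding chosen alleles
#'
#' A random background sequence (screened to share no seed-length-mer with
#' any allele in the database) with the chosen allele sequences embedded at
#' non-overlapping positions in random orientation. With
#' `background_length = 0` the alleles are concatenated with 1 kb random
#' spacers.
#'
#' @param db an [mlst_db()].
#' @param chosen named integer vector, locus name to allele id.
#' @param background_length background bp (default from `config`).
#' @param config a [sim_config()] (seed length, default background).
#' @param seed optional RNG seed (defaults to the current RNG state).
#' @return a DNA string with attribute `positions` (data frame: locus, start,
#'   end, strand).
#' @export
build_sample_genome <- function(db, chosen, background_length = NULL,
                                config = sim_config(), seed = NULL) {
  if (is.null(background_length)) background_length <- config$background_length
  chosen <- unlist(chosen)
  seqs <- vapply(names(chosen), function(l) {
    loc <- db$loci[[l]]
    if (is.null(loc)) stop_mlst("no such locus: '", l, "'")
    s <- locus_seq(loc, chosen[[l]])
    if (is.na(s)) stop_mlst("allele ", chosen[[l]], " not in locus '", l, "'")
    s
  }, character(1))
  all_alleles <- unlist(lapply(db$loci, `[[`, "sequence"), use.names = FALSE)
  L <- length(seqs)
  with_seed(seed, {
    if (background_length == 0L) {
      chunk_len <- rep(1000L, L + 1L)
    } else {
      if (background_length < 50L * (L + 1L))
        stop_mlst("background too short to embed ", L,
                  " alleles without overlap")
      # random composition with a floor per chunk so loci stay isolated
      min_chunk <- min(200L, background_length %/% (2L * (L + 1L)))
      extra <- background_length - min_chunk * (L + 1L)
      bars <- sort(sample(0:extra, L, replace = TRUE))
      chunk_len <- min_chunk + diff(c(0L, bars, extra))
    }
    chunks <- vapply(chunk_len, clean_background, character(1),
                     allele_seqs = all_alleles,
                     seed_length = config$seed_length)
    strand <- sample(c("+", "-"), L, replace = TRUE)
    emb <- ifelse(strand == "+", seqs, revcomp_dna(seqs))
    genome <- chunks[1L]
    pos <- data.frame(locus = names(seqs), start = NA_integer_,
                      end = NA_integer_, strand = strand,
                      stringsAsFactors = FALSE)
    for (i in seq_len(L)) {
      pos$start[i] <- nchar(genome) + 1L
      genome <- paste0(genome, emb[i])
      pos$end[i] <- nchar(genome)
      genome <- paste0(genome, chunks[i + 1L])
    }
    attr(genome, "positions") <- pos
    genome
  })
}

#' Simulate paired short reads from a genome
#'
#' Uniform random fragment positions to the configured expected coverage,
#' mates from opposite strands at fragment length `insert_size` (sd
#' `insert_sd`), per-base substitution errors at `error_rate`, constant
#' quality scores.
#'
#' @param genome a DNA string.
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @param paths optional character vector of length 2; when given, the mates
#'   are also written as FASTQ (`.gz` honoured) to these paths.
#' @return a [read_set()] of all mates (pairing disregarded, as consumed by
#'   the pipeline); ids carry `/1`, `/2` mate suffixes.
#' @export
simulate_reads <- function(genome, config = sim_config(), seed = NULL,
                           paths = NULL) {
  gl <- nchar(genome)
  rl <- config$read_length
  stopifnot(rl < gl)
  with_seed(seed, {
    n_pairs <- max(1L, round(config$coverage * gl / (2 * rl)))
    frag <- pmin(pmax(round(rnorm(n_pairs, config$insert_size,
                                  config$insert_sd)), rl), gl)
    start <- vapply(frag, function(f)
      sample.int(gl - f + 1L, 1L), integer(1))
    fragment <- substring(genome, start, start + frag - 1L)
    r1 <- substr(fragment, 1L, rl)
    r2 <- revcomp_dna(substring(fragment, frag - rl + 1L))
    add_errors <- function(reads) {
      if (config$error_rate == 0) return(reads)
      vapply(reads, function(s) {
        n <- nchar(s)
        hits <- which(runif(n) < config$error_rate)
        if (length(hits)) s <- apply_snps(s, hits)
        s
      }, character(1), USE.NAMES = FALSE)
    }
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)
    rs1 <- read_set(sprintf("sim_%06d/1", seq_len(n_pairs)), r1)
    rs2 <- read_set(sprintf("sim_%06d/2", seq_len(n_pairs)), r2)
    if (!is.null(paths)) {
      write_fastq(rs1, paths[1])
      write_fastq(rs2, paths[2])
    }
    read_set(c(rs1$id, rs2$id), c(rs1$sequence, rs2$sequence))
  })
}

#' Mutate an allele into a novel variant
#'
#' Applies exactly `n_snps` substitutions (and optionally one indel) and
#' guarantees the result differs from every sequence in `avoid`; colliding
#' draws are resampled.
#'
#' @param allele DNA string.
#' @param n_snps number of substitutions.
#' @param indel optional list `(position, length, type)` with type `"ins"` or
#'   `"del"`.
#' @param avoid character vector of sequences the result must not equal
#'   (typically the locus's alleles).
#' @param seed optional RNG seed.
#' @param max_tries resampling budget before erroring.
#' @return the mutated DNA string.
#' @export
mutate_allele <- function(allele, n_snps = 1L, indel = NULL,
                          avoid = character(), seed = NULL,
                          max_tries = 100L) {
  n <- nchar(allele)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      out <- allele
      if (n_snps > 0L) out <- apply_snps(out, sample.int(n, n_snps))
      if (!is.null(indel)) {
        p <- indel$position
        len <- indel$length
        if (identical(indel$type, "del")) {
          stopifnot(p >= 1L, p + len - 1L <= nchar(out))
          out <- paste0(substr(out, 1L, p - 1L),
                        substring(out, p + len))
        } else {
          stopifnot(p >= 1L, p <= nchar(out) + 1L)
          out <- paste0(substr(out, 1L, p - 1L), random_dna(len),
                        substring(out, p))
        }
      }
      if (!out %in% avoid && out != allele) return(out)
    }
    stop_mlst("could not generate a non-colliding mutant in ", max_tries,
              " tries")
  })
}

#' Simulate one typed sample
#'
#' Picks (or accepts) a profile row, optionally mutates one locus's allele
#' into a novel variant, builds the genome and simulates reads.
#'
#' @param db,profiles from [generate_allele_db()].
#' @param st ST row to use (default: sampled uniformly from the table).
#' @param config a [sim_config()].
#' @param mutate optional list with `locus` and either `n_snps` or `indel`
#'   (see [mutate_allele()]); the genome then embeds the mutant at that locus.
#' @param sample_id identifier for the truth record.
#' @param seed optional RNG seed.
#' @return list: `sample_id`, `reads` ([read_set()]), `truth_alleles` (named
#'   integer vector), `true_st`, `mutated_locus`, `mutated_sequence`.
#' @export
simulate_sample <- function(db, profiles, st = NULL, config = sim_config(),
                            mutate = NULL, sample_id = "sample",
                            seed = NULL) {
  with_seed(seed, {
    if (is.null(st)) st <- sample(profiles$st, 1L)
    row <- which(profiles$st == st)
    if (length(row) != 1L) stop_mlst("no such ST in profile table: ", st)
    truth <- setNames(profiles$alleles[row, ], profiles$schema)
    mutated_locus <- NA_character_
    mutated_sequence <- NA_character_
    genome_db <- db
    if (!is.null(mutate)) {
      mutated_locus <- mutate$locus
      loc <- db$loci[[mutated_locus]]
      orig <- locus_seq(loc, truth[[mutated_locus]])
      mutated_sequence <- mutate_allele(
        orig,
        n_snps = if (is.null(mutate$n_snps)) 0L else mutate$n_snps,
        indel = mutate$indel,
        avoid = loc$sequence)
      # swap the mutant in for genome construction only
      tmp <- loc
      tmp$sequence[match(truth[[mutated_locus]], tmp$allele_id)] <-
        mutated_sequence
      genome_db$loci[[mutated_locus]] <- tmp
    }
    genome <- build_sample_genome(genome_db, truth,
                                  background_length = config$background_length,
                                  config = config)
    reads <- simulate_reads(genome, config)
    list(sample_id = sample_id, reads = reads, truth_alleles = truth,
         true_st = st, mutated_locus = mutated_locus,
         mutated_sequence = mutated_sequence)
  })
}

#' Simulate a benchmark set of samples
#'
#' @param n_samples number of samples.
#' @param config a [sim_config()]; `config$seed` seeds the whole set.
#' @param db,profiles optional pre-built database/profiles (generated from
#'   `config` when omitted).
#' @param out_dir optional directory; when given, paired FASTQ files, the
#'   allele FASTAs, the profile TSV and the truth TSV are written there.
#' @return list: `db`, `profiles`, `samples` (list from [simulate_sample()]),
#'   `truth` (data frame `sample`, locus columns, `ST`).
#' @export
simulate_benchmark <- function(n_samples, config = sim_config(),
                               db = NULL, profiles = NULL, out_dir = NULL) {
  if (is.null(db) || is.null(profiles)) {
    gen <- generate_allele_db(config)
    db <- gen$db
    profiles <- gen$profiles
  }
  samples <- with_seed(config$seed + 1L, {
    lapply(seq_len(n_samples), function(i)
      simulate_sample(db, profiles, config = config,
                      sample_id = sprintf("sample%03d", i)))
  })
  truth <- do.call(rbind, lapply(samples, function(s) {
    as.data.frame(c(list(sample = s$sample_id), as.list(s$truth_alleles),
                    list(ST = s$true_st)),
                  stringsAsFactors = FALSE, check.names = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "db"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "reads"), showWarnings = FALSE)
    for (l in db$loci)
      write_allele_fasta(l, file.path(out_dir, "db",
                                      paste0(l$name, ".fasta")))
    prof <- data.frame(ST = profiles$st, profiles$alleles,
                       check.names = FALSE)
    write.table(prof, file.path(out_dir, "profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (s in samples) {
      rs <- s$reads
      mate1 <- grepl("/1$", rs$id)
      write_fastq(read_set(rs$id[mate1], rs$sequence[mate1]),
                  file.path(out_dir, "reads",
                            paste0(s$sample_id, "_1.fastq.gz")))
      write_fastq(read_set(rs$id[!mate1], rs$sequence[!mate1]),
                  file.path(out_dir, "reads",
                            paste0(s$sample_id, "_2.fastq.gz")))
    }
  }
  list(db = db, profiles = profiles, samples = samples, truth = truth)
}
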