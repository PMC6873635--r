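# Read merging and per-locus recruitment by perfect-match fraction.
#
# A read is recruited when its longest exact (mismatch- and gap-free) run
# against any reference allele of the locus, on either strand, reaches the
# seed length; the run length divided by the read length is the read's
# perfect-match fraction. Tier sets at fractions 0 / 0.30 / 0.60 / 0.90 of
# read length feed the targeted assembler, mirroring soft-clip-tolerant local
# mapping without a scoring aligner.

#' Construct a read set
#'
#' @param id character read identifiers.
#' @param sequence character DNA sequences (upper-cased).
#' @return a `read_set` (data frame with columns `id`, `sequence`).
#' @export
read_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) && any(nchar(sequence) == 0L))
    stop_mlst("empty read sequence(s)")
  structure(data.frame(id = as.character(id), sequence = sequence,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Merge FASTQ files into a single read set, disregarding pairing
#'
#' Both mates of paired files are loaded as independent reads (a run of two
#' paired files of one million reads yields two million reads). Mate suffixes
#' (`/1`, `/2`, space-delimited tags) are retained in the read id but never
#' interpreted. Plain and gzipped FASTQ may be mixed. Qualities are not used
#' by the pipeline and are not kept.
#'
#' @param paths character vector of FASTQ / FASTQ.gz files.
#' @return a [read_set()].
#' @export
merge_fastq <- function(paths) {
  check_fastq_structure <- function(p) {
    con <- gzfile(p, "r")   # transparently reads plain files too
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    if (length(lines) %% 4L != 0L)
      stop_mlst("malformed FASTQ in '", p, "': truncated record ",
                length(lines) %/% 4L + 1L)
    if (length(lines) == 0L) return(invisible())
    heads <- lines[seq(1L, length(lines), by = 4L)]
    seps <- lines[seq(3L, length(lines), by = 4L)]
    sq <- lines[seq(2L, length(lines), by = 4L)]
    ql <- lines[seq(4L, length(lines), by = 4L)]
    bad <- !startsWith(heads, "@") | !startsWith(seps, "+") |
      nchar(sq) != nchar(ql)
    if (any(bad))
      stop_mlst("malformed FASTQ in '", p, "': record ", which(bad)[1])
    invisible()
  }
  pieces <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_mlst("no such file: '", p, "'")
    check_fastq_structure(p)
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = FALSE),
      error = function(e)
        stop_mlst("malformed FASTQ in '", p, "': ", conditionMessage(e)))
    data.frame(id = if (length(seqs)) names(seqs) else character(),
               sequence = toupper(as.character(seqs)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(all)) all <- data.frame(id = character(), sequence = character())
  read_set(all$id, all$sequence)
}

#' Write a read set as FASTQ
#'
#' Constant quality scores (the pipeline never reads them).
#'
#' @param reads a [read_set()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Perfect-match fraction of a read against a locus
#'
#' The fraction is the length of the longest substring of the read occurring
#' exactly in any allele of the locus, on either strand, divided by the read
#' length. Ties are broken toward the forward orientation, then the lowest
#' allele id.
#'
#' @param read a single DNA string (or a `read_set` row sequence).
#' @param locus an [mlst_locus()].
#' @return list with `fraction`, `orientation` (`"forward"`/`"reverse"`, `NA`
#'   if no common substring) and `best_allele_id` (`NA` likewise).
#' @export
perfect_match_fraction <- function(read, locus) {
  stopifnot(length(locus) > 0L)
  read <- toupper(read)
  sc <- .recruit_scores(read, locus$sequence, 1L)
  list(fraction = sc$run / nchar(read),
       orientation = c("forward", "reverse")[sc$orientation],
       best_allele_id = locus$allele_id[sc$allele])
}

#' Recruit reads for a locus into match-fraction tiers
#'
#' Tier 0 ("all mapped reads") holds every read whose longest exact run
#' reaches `seed_length`; tiers 0.30 / 0.60 / 0.90 filter it by perfect-match
#' fraction at or above the threshold (inclusive), so the tiers are nested.
#' Reads shorter than `seed_length` are never recruited.
#'
#' @param reads a [read_set()].
#' @param locus an [mlst_locus()].
#' @param seed_length minimum exact-run length to count as mapped (default 20).
#' @param thresholds tier thresholds (fractions of read length).
#' @return a `recruitment_tiers` object; see [tier_reads()].
#' @export
recruit_reads <- function(reads, locus, seed_length = 20L,
                          thresholds = c(0, 0.30, 0.60, 0.90)) {
  stopifnot(seed_length >= 1L, length(locus) > 0L)
  thresholds <- sort(unique(thresholds))
  if (nrow(reads) == 0L) {
    hits <- data.frame(id = character(), sequence = character(),
                       fraction = numeric(), orientation = character(),
                       best_allele_id = integer())
  } else {
    sc <- .recruit_scores(reads$sequence, locus$sequence, as.integer(seed_length))
    keep <- which(sc$run >= seed_length)
    hits <- data.frame(
      id = reads$id[keep],
      sequence = reads$sequence[keep],
      fraction = sc$run[keep] / nchar(reads$sequence[keep]),
      orientation = c("forward", "reverse")[sc$orientation[keep]],
      best_allele_id = locus$allele_id[sc$allele[keep]],
      stringsAsFactors = FALSE)
    hits <- hits[order(hits$id, hits$sequence), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(locus = locus$name, seed_length = seed_length,
                 thresholds = thresholds, hits = hits),
            class = "recruitment_tiers")
}

#' Reads of one recruitment tier
#'
#' @param tiers a `recruitment_tiers` object from [recruit_reads()].
#' @param threshold one of the tier thresholds (e.g. `0.9`).
#' @return a [read_set()] of the reads at or above the threshold.
#' @export
tier_reads <- function(tiers, threshold) {
  if (!any(abs(tiers$thresholds - threshold) < 1e-9))
    stop_mlst("no tier at threshold ", threshold)
  h <- tiers$hits[tiers$hits$fraction >= threshold - 1e-9, , drop = FALSE]
  read_set(h$id, h$sequence)
}

#' @export
print.recruitment_tiers <- function(x, ...) {
  cat(sprintf("<recruitment_tiers> locus %s, seed %d\n", x$locus, x$seed_length))
  for (t in x$thresholds)
    cat(sprintf("  >= %3.0f%%: %5d reads\n", 100 * t,
                sum(x$hits$fraction >= t - 1e-9)))
  invisible(x)
}
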