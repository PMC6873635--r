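# Per-locus allele calling: the tier loop.
#
# Tiers are scanned most-stringent first (0.90 -> 0.60 -> 0.30 -> 0); within a
# tier every k is assembled and contigs are evaluated largest k first. The
# first exact full-length allele match anywhere wins. If no tier yields an
# exact match but a sufficiently long contig exists, the locus is reported as
# a putative novel allele ("New?") with its trimmed sequence; otherwise the
# outcome is "low coverage".

#' Default calling parameters
#'
#' @param seed_length minimum exact run for a read to count as mapped.
#' @param thresholds recruitment tier thresholds.
#' @param ks k-mer sizes for the multi-k assembler.
#' @param min_count de Bruijn edge multiplicity threshold.
#' @param small_set read count under which `min_count` drops to 1.
#' @param min_tip_count tip-trimming threshold, see [extract_unitigs()].
#' @param min_overlap greedy-fallback overlap floor.
#' @param min_new_frac a candidate novel contig must reach this fraction of
#'   the locus's shortest allele, else the call downgrades to low coverage.
#' @return a named list of parameters.
#' @export
typing_params <- function(seed_length = 20L,
                          thresholds = c(0, 0.30, 0.60, 0.90),
                          ks = c(11L, 15L, 21L, 33L, 35L),
                          min_count = 2L,
                          small_set = 50L,
                          min_tip_count = 2L,
                          min_overlap = 25L,
                          min_new_frac = 0.5) {
  list(seed_length = as.integer(seed_length),
       thresholds = sort(unique(thresholds)),
       ks = sort(unique(as.integer(ks))),
       min_count = as.integer(min_count),
       small_set = as.integer(small_set),
       min_tip_count = as.integer(min_tip_count),
       min_overlap = as.integer(min_overlap),
       min_new_frac = min_new_frac)
}

allele_call <- function(locus_name, status, allele_id = NA_integer_,
                        novel_sequence = NA_character_, tier_used = NA_real_,
                        k_used = NA_integer_, note = NA_character_) {
  structure(list(locus_name = locus_name, status = status,
                 allele_id = allele_id, novel_sequence = novel_sequence,
                 tier_used = tier_used, k_used = k_used, note = note),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  lab <- switch(x$status,
                exact = paste0("allele ", x$allele_id),
                new = sprintf("New? (%d bp)", nchar(x$novel_sequence)),
                low_coverage = "low coverage",
                no_output = "no output")
  prov <- if (!is.na(x$tier_used))
    sprintf(" [tier %.2f, k %s]", x$tier_used,
            ifelse(is.na(x$k_used), "fallback", x$k_used)) else ""
  cat(sprintf("<allele_call> %s: %s%s\n", x$locus_name, lab, prov))
  invisible(x)
}

#' Match a contig against a locus by exact full-length allele match
#'
#' An allele matches when the contig is string-equal to it, or when the
#' allele's full-length sequence occurs exactly (no mismatches, no indels)
#' inside the contig, on either strand. Whole-contig equality takes priority;
#' among containment matches, a single distinct matching allele is required
#' (two distinct alleles inside one contig is ambiguous and yields no call).
#'
#' @param contig a DNA string (contig sequence).
#' @param locus an [mlst_locus()].
#' @return the matching allele id, or `NA_integer_` when no unique full-length
#'   match exists. Matching several alleles of identical sequence (an invalid
#'   database) is an error.
#' @export
match_contig <- function(contig, locus) {
  contig <- toupper(contig)
  rc <- revcomp_dna(contig)
  eq <- locus$sequence == contig | locus$sequence == rc
  hit <- if (any(eq)) eq else {
    len_ok <- nchar(locus$sequence) <= nchar(contig)
    h <- logical(length(locus$sequence))
    h[len_ok] <- vapply(locus$sequence[len_ok], function(a)
      grepl(a, contig, fixed = TRUE) || grepl(a, rc, fixed = TRUE),
      logical(1))
    h
  }
  if (!any(hit)) return(NA_integer_)
  ids <- locus$allele_id[hit]
  seqs <- locus$sequence[hit]
  if (anyDuplicated(seqs))
    stop_mlst("contig matches several alleles with identical sequence in ",
              "locus '", locus$name, "' (duplicate-sequence database): ids ",
              paste(ids, collapse = ", "))
  if (length(ids) > 1L) return(NA_integer_)
  ids
}

# trim a candidate novel contig to the region homologous to its closest
# reference allele (global in the reference, local in the contig)
trim_novel <- function(contig, locus) {
  if (length(locus) == 0L)
    return(list(sequence = contig, score = -Inf, ref_id = NA_integer_))
  per <- vapply(locus$sequence, function(a)
    .max_match_run(contig, a), integer(1), USE.NAMES = FALSE)
  ref_i <- which.max(per)
  ref <- locus$sequence[ref_i]
  # orient the contig like the reference
  oriented <- if (.forward_match_run(contig, ref) >=
                  .forward_match_run(revcomp_dna(contig), ref))
    contig else revcomp_dna(contig)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(oriented),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  sub <- Biostrings::subject(aln)
  list(sequence = substr(oriented, Biostrings::start(sub),
                         Biostrings::end(sub)),
       score = Biostrings::score(aln),
       ref_id = locus$allele_id[ref_i])
}

#' Call one locus from a read set
#'
#' Runs the full tier loop: recruit, assemble each tier at every k, and stop
#' at the first exact full-length allele match (tiers most stringent first,
#' larger k first within a tier). Without an exact match, a contig reaching
#' `min_new_frac` of the locus's shortest allele yields status `"new"` with
#' the trimmed novel sequence; no recruited reads or no contigs yield
#' `"low_coverage"`. The greedy fallback assembler runs only when every k
#' produces no contig from a non-empty tier. Deterministic for fixed inputs.
#'
#' @param reads a [read_set()] (the merged sample reads).
#' @param locus an [mlst_locus()].
#' @param params see [typing_params()].
#' @return an `allele_call` object.
#' @export
call_locus <- function(reads, locus, params = typing_params()) {
  if (length(locus) == 0L)
    return(allele_call(locus$name, "low_coverage", note = "empty locus"))
  tiers <- recruit_reads(reads, locus, params$seed_length, params$thresholds)
  order_desc <- rev(params$thresholds)
  ks_desc <- rev(params$ks)

  assemblies <- list()   # one entry per tier: list(ids, contigs_by_k)
  prev_key <- NULL
  candidates <- list()
  any_reads <- FALSE
  any_contig <- FALSE

  for (th in order_desc) {
    rs <- tier_reads(tiers, th)
    if (nrow(rs) == 0L) next
    any_reads <- TRUE
    key <- paste(sort(rs$id), collapse = "\r")
    if (!is.null(prev_key) && identical(key, prev_key$key)) {
      by_k <- prev_key$by_k
    } else {
      by_k <- assemble_multi_k(rs, params$ks, params$min_count,
                               params$small_set, params$min_tip_count)
      prev_key <- list(key = key, by_k = by_k)
    }
    produced <- any(vapply(by_k, nrow, integer(1)) > 0L)
    if (!produced) {
      fb <- greedy_assemble(rs, params$min_overlap)
      if (nrow(fb)) {
        by_k <- c(by_k, list(fallback = fb))
        produced <- TRUE
      }
    }
    if (produced) any_contig <- TRUE
    for (kn in c(as.character(ks_desc),
                 if ("fallback" %in% names(by_k)) "fallback")) {
      contigs <- by_k[[kn]]
      if (is.null(contigs) || nrow(contigs) == 0L) next
      for (i in seq_len(nrow(contigs))) {
        id <- match_contig(contigs$sequence[i], locus)
        if (!is.na(id))
          return(allele_call(locus$name, "exact", allele_id = id,
                             tier_used = th,
                             k_used = if (kn == "fallback") NA_integer_
                                      else as.integer(kn)))
      }
      candidates[[length(candidates) + 1L]] <-
        data.frame(sequence = contigs$sequence, tier = th,
                   k = if (kn == "fallback") NA_integer_ else as.integer(kn),
                   stringsAsFactors = FALSE)
    }
  }

  if (!any_reads || !any_contig)
    return(allele_call(locus$name, "low_coverage"))

  cand <- do.call(rbind, candidates)
  min_len <- min(nchar(locus$sequence))
  cand <- cand[nchar(cand$sequence) >= params$min_new_frac * min_len, ,
               drop = FALSE]
  if (nrow(cand) == 0L)
    return(allele_call(locus$name, "low_coverage",
                       note = "contigs below min_new_frac"))
  # keep the most stringent tier / largest k per distinct sequence
  cand <- cand[order(-cand$tier, -ifelse(is.na(cand$k), -1L, cand$k),
                     cand$sequence), , drop = FALSE]
  cand <- cand[!duplicated(cand$sequence), , drop = FALSE]
  trims <- lapply(cand$sequence, trim_novel, locus = locus)
  score <- vapply(trims, `[[`, numeric(1), "score")
  novel <- vapply(trims, `[[`, character(1), "sequence")
  pick <- order(-score, -cand$tier, -ifelse(is.na(cand$k), -1L, cand$k),
                novel)[1L]
  novel_seq <- novel[pick]
  id <- match_contig(novel_seq, locus)
  if (!is.na(id) && novel_seq %in% c(locus$sequence, revcomp_dna(locus$sequence)))
    return(allele_call(locus$name, "exact", allele_id = id,
                       tier_used = cand$tier[pick], k_used = cand$k[pick]))
  allele_call(locus$name, "new", novel_sequence = novel_seq,
              tier_used = cand$tier[pick], k_used = cand$k[pick])
}

#' Write novel allele sequences to a `new_alleles/` directory
#'
#' One FASTA per status-`new` call, header `<sample>_<locus>_new`.
#'
#' @param calls list of `allele_call` objects (or an `st_call`).
#' @param out_dir parent output directory.
#' @param sample_id sample identifier used in file and header names.
#' @return character vector of the files written (possibly empty).
#' @export
write_new_alleles <- function(calls, out_dir, sample_id = "sample") {
  if (inherits(calls, "st_call")) calls <- calls$locus_calls
  new_calls <- Filter(function(x) x$status == "new", calls)
  if (length(new_calls) == 0L) return(character())
  dir <- file.path(out_dir, "new_alleles")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(new_calls, function(cl) {
    path <- file.path(dir, paste0(sample_id, "_", cl$locus_name, "_new.fasta"))
    set <- Biostrings::DNAStringSet(cl$novel_sequence)
    names(set) <- paste0(sample_id, "_", cl$locus_name, "_new")
    Biostrings::writeXStringSet(set, path)
    path
  }, character(1))
}
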