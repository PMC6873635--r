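# Targeted assembly: de Bruijn graph over recruited reads, unitig compaction,
# independent assemblies at several k, and a greedy-overlap fallback.
#
# No read error correction is performed; the only noise filter is the edge
# multiplicity threshold min_count (errors at low rates yield k-mers seen
# once, which the threshold removes).

#' Build a de Bruijn graph from reads
#'
#' Edges are k-mers with multiplicity counts; nodes are (k-1)-mers. Each read
#' contributes its forward k-mers and, for strand symmetry, the k-mers of its
#' reverse complement; an edge and its mirror carry their combined count, so a
#' k-mer covered by `r` reads has count `2r`. Edges with count below
#' `min_count` are removed: the default 2 retains everything a single read
#' supports (allele ends are often covered by one read), while 4 and above
#' demands corroboration by multiple reads.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param k odd k-mer size, 3-127 (pipeline defaults use 11-35).
#' @param min_count minimum k-mer multiplicity for an edge to survive.
#' @return a `dbg` object (fields `k`, `kmer`, `count`).
#' @export
build_dbg <- function(reads, k, min_count = 2L) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 3L, k <= 127L, min_count >= 1L)
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  cnt <- .count_kmers(seqs, k, as.integer(min_count))
  structure(list(k = k, kmer = cnt$kmer, count = cnt$count), class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("<dbg> k=%d, %d edge(s)\n", x$k, length(x$kmer)))
  invisible(x)
}

# walk-based unitig compaction over the raw edge list; returns a data frame
# with one row per (directed) unitig
compact_edges <- function(kmer, count, k) {
  e <- length(kmer)
  if (e == 0L)
    return(data.frame(sequence = character(), coverage = numeric(),
                      first = integer(), last = integer()))
  pref <- substr(kmer, 1L, k - 1L)
  suf  <- substr(kmer, 2L, k)
  nodes <- unique(c(pref, suf))
  pi <- match(pref, nodes)
  si <- match(suf, nodes)
  outdeg <- tabulate(pi, length(nodes))
  indeg  <- tabulate(si, length(nodes))
  # through[v]: paths may pass straight through node v
  through <- outdeg == 1L & indeg == 1L
  out_edge <- integer(length(nodes))        # the single out-edge where outdeg==1
  out_edge[pi] <- seq_len(e)                # unique writer when outdeg==1
  out_edge[outdeg != 1L] <- 0L

  nxt <- ifelse(through[si], out_edge[si], 0L)
  visited <- logical(e)
  res_seq <- character(); res_cov <- numeric()
  res_first <- integer(); res_last <- integer()

  walk <- function(start) {
    chain <- integer(0)
    i <- start
    repeat {
      chain <- c(chain, i)
      visited[i] <<- TRUE
      j <- nxt[i]
      if (j == 0L || visited[j]) break
      i <- j
    }
    chain
  }
  emit <- function(chain) {
    seqn <- paste0(kmer[chain[1L]],
                   paste(substr(kmer[chain[-1L]], k, k), collapse = ""))
    res_seq  <<- c(res_seq, seqn)
    res_cov  <<- c(res_cov, mean(count[chain]))
    res_first <<- c(res_first, chain[1L])
    res_last  <<- c(res_last, chain[length(chain)])
  }
  # starts: edges that cannot be entered by a merge (walk in lexicographic
  # edge order so output is independent of input read order)
  starts <- which(!through[pi])
  for (s in starts) if (!visited[s]) emit(walk(s))
  # anything left lies on pure cycles
  for (s in seq_len(e)) if (!visited[s]) emit(walk(s))
  data.frame(sequence = res_seq, coverage = res_cov,
             first = res_first, last = res_last, stringsAsFactors = FALSE)
}

#' Extract unitigs (contigs) from a de Bruijn graph
#'
#' Maximal non-branching paths, each reported once: a sequence and its reverse
#' complement are the same contig, represented by the lexicographically
#' smaller strand. Dead-end side branches ("tips") shorter than `2k` whose
#' edge counts all fall below `min_tip_count` are removed before final
#' compaction.
#'
#' @param graph a [build_dbg()] result.
#' @param min_tip_count tips with all edge counts below this are trimmed
#'   (default 2; with the default `min_count = 2` this is a no-op, raise it to
#'   enable coverage-based tip trimming).
#' @return data frame of contigs: `sequence` (canonical strand), `k`,
#'   `coverage` (mean edge count), sorted by decreasing length then sequence.
#' @export
extract_unitigs <- function(graph, min_tip_count = 2L) {
  k <- graph$k
  kmer <- graph$kmer
  count <- graph$count
  if (length(kmer) && min_tip_count > 1L) {
    u <- compact_edges(kmer, count, k)
    if (nrow(u) > 1L) {
      pref <- substr(kmer, 1L, k - 1L)
      suf  <- substr(kmer, 2L, k)
      u_pref <- substr(u$sequence, 1L, k - 1L)
      u_suf  <- substring(u$sequence, nchar(u$sequence) - k + 2L)
      dead_start <- !(u_pref %in% suf)           # nothing feeds into the unitig
      dead_end   <- !(u_suf %in% pref)           # unitig leads nowhere
      u_cov_max <- vapply(seq_len(nrow(u)), function(i) {
        n <- nchar(u$sequence[i]) - k + 1L
        max(count[match(substring(u$sequence[i], 1:n, k:(n + k - 1L)), kmer)])
      }, numeric(1))
      is_tip <- xor(dead_start, dead_end) &      # dangling at exactly one side
        nchar(u$sequence) < 2L * k &
        u_cov_max < min_tip_count
      if (any(is_tip)) {
        drop <- unlist(lapply(u$sequence[is_tip], function(s) {
          n <- nchar(s) - k + 1L
          tk <- substring(s, 1:n, k:(n + k - 1L))
          match(c(tk, revcomp_dna(tk)), kmer)
        }))
        drop <- unique(drop[!is.na(drop)])
        kmer <- kmer[-drop]; count <- count[-drop]
      }
    }
  }
  u <- compact_edges(kmer, count, k)
  if (nrow(u) == 0L)
    return(data.frame(sequence = character(), k = integer(),
                      coverage = numeric()))
  canon <- canonical_dna(u$sequence)
  keep <- !duplicated(canon)
  out <- data.frame(sequence = canon[keep], k = k,
                    coverage = u$coverage[keep], stringsAsFactors = FALSE)
  out <- out[order(-nchar(out$sequence), out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a read set independently at several k-mer sizes
#'
#' Single-k assemblies (no iterative composition); downstream calling consumes
#' them largest k first. For read sets with fewer than `small_set` reads the
#' multiplicity filter drops to 1 so sparse tiers still assemble.
#'
#' @param reads a [read_set()] or character vector.
#' @param ks k-mer sizes (default `c(11, 15, 21, 33, 35)`).
#' @param min_count edge multiplicity threshold (default 2).
#' @param small_set read-count threshold under which `min_count` drops to 1.
#' @param min_tip_count see [extract_unitigs()].
#' @return named list, one contig data frame per k.
#' @export
assemble_multi_k <- function(reads, ks = c(11L, 15L, 21L, 33L, 35L),
                             min_count = 2L, small_set = 50L,
                             min_tip_count = 2L) {
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  mc <- if (n < small_set) 1L else as.integer(min_count)
  out <- lapply(ks, function(k)
    extract_unitigs(build_dbg(reads, k, mc), min_tip_count))
  names(out) <- as.character(ks)
  out
}

#' Greedy overlap assembly (fallback)
#'
#' Backup assembler for read sets on which the de Bruijn graph yields no
#' contig (very low or uneven coverage): repeatedly merges the pair of
#' sequences with the longest exact suffix-prefix overlap (both orientations)
#' until no overlap of at least `min_overlap` remains. Deterministic
#' tie-breaking: longest overlap, then lexicographically smallest merged
#' sequence. Contained sequences are absorbed; with no overlaps the
#' deduplicated reads are returned.
#'
#' @param reads a [read_set()] or character vector.
#' @param min_overlap minimum exact overlap (default 25, floor 15).
#' @return contig data frame as in [extract_unitigs()] (`k` is `NA`).
#' @export
greedy_assemble <- function(reads, min_overlap = 25L) {
  stopifnot(min_overlap >= 15L)
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  seqs <- sort(unique(canonical_dna(seqs)))
  drop_contained <- function(ss) {
    if (length(ss) < 2L) return(ss)
    ss <- ss[order(-nchar(ss), ss)]
    keep <- rep(TRUE, length(ss))
    for (i in seq_along(ss)[-1L]) {
      s <- ss[i]; r <- revcomp_dna(s)
      for (j in seq_len(i - 1L)) {
        if (keep[j] && (grepl(s, ss[j], fixed = TRUE) ||
                        grepl(r, ss[j], fixed = TRUE))) {
          keep[i] <- FALSE
          break
        }
      }
    }
    ss[keep]
  }
  best_overlap <- function(a, b) {
    # longest ov with suffix(a, ov) == prefix(b, ov), ov < min(|a|, |b|)
    lim <- min(nchar(a), nchar(b)) - 1L
    for (ov in rev(seq_len(lim))) {
      if (ov < min_overlap) break
      if (substring(a, nchar(a) - ov + 1L) == substr(b, 1L, ov)) return(ov)
    }
    0L
  }
  seqs <- drop_contained(seqs)
  repeat {
    if (length(seqs) < 2L) break
    oriented <- c(seqs, revcomp_dna(seqs))
    origin <- rep(seq_along(seqs), 2L)
    best <- NULL
    for (i in seq_along(oriented)) {
      for (j in seq_along(oriented)) {
        if (origin[i] == origin[j]) next
        ov <- best_overlap(oriented[i], oriented[j])
        if (ov >= min_overlap) {
          merged <- paste0(oriented[i],
                           substring(oriented[j], ov + 1L))
          cand <- list(ov = ov, merged = canonical_dna(merged),
                       drop = c(origin[i], origin[j]))
          if (is.null(best) || cand$ov > best$ov ||
              (cand$ov == best$ov && cand$merged < best$merged))
            best <- cand
        }
      }
    }
    if (is.null(best)) break
    seqs <- c(seqs[-best$drop], best$merged)
    seqs <- drop_contained(sort(seqs))
  }
  out <- data.frame(sequence = sort(seqs), k = NA_integer_,
                    coverage = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(-nchar(out$sequence), out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
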