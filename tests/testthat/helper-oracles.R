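# Independent brute-force oracles used to verify the fast implementations.

# longest substring of `query` occurring exactly in `ref` (forward strand),
# by enumerating all substrings, longest first
oracle_lcs_one <- function(query, ref) {
  n <- nchar(query)
  for (L in rev(seq_len(n))) {
    subs <- unique(substring(query, 1:(n - L + 1L), L:n))
    for (s in subs) if (grepl(s, ref, fixed = TRUE)) return(L)
  }
  0L
}

# longest exact run of `query` against a set of alleles, both strands
oracle_lcs <- function(query, alleles) {
  rc <- revcomp_dna(query)
  max(c(vapply(alleles, function(a) oracle_lcs_one(query, a), integer(1)),
        vapply(alleles, function(a) oracle_lcs_one(rc, a), integer(1))))
}

# does `seqn` (either strand) share any k-mer with any of `refs`?
oracle_shared_kmer <- function(seqn, refs, k = 20L) {
  mers <- function(s) {
    n <- nchar(s)
    if (n < k) character() else substring(s, 1:(n - k + 1L), k:n)
  }
  q <- unique(c(mers(seqn), mers(revcomp_dna(seqn))))
  any(q %in% unlist(lapply(refs, mers), use.names = FALSE))
}

# independent unitig computation: start from the raw k-mer edge multiset and
# repeatedly rewrite (merge a pair of segments across a node with in-degree
# and out-degree one) until fixed point; compare as canonical sequence sets.
# Assumes acyclic graphs (the test cases are built that way).
oracle_unitigs <- function(reads, k, min_count = 1L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  seqs <- c(seqs, revcomp_dna(seqs))
  km <- unlist(lapply(seqs[nchar(seqs) >= k], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (length(km) == 0L) return(character())
  r <- rle(sort(km))
  edges <- r$values[r$lengths >= min_count]
  if (length(edges) == 0L) return(character())
  pref_all <- substr(edges, 1L, k - 1L)
  suf_all <- substr(edges, 2L, k)
  outdeg <- table(pref_all)
  indeg <- table(suf_all)
  deg <- function(tab, v) ifelse(is.na(tab[v]), 0L, tab[v])
  segs <- edges
  repeat {
    starts <- substr(segs, 1L, k - 1L)
    ends <- substring(segs, nchar(segs) - k + 2L)
    merged <- FALSE
    for (v in unique(ends)) {
      if (deg(outdeg, v) != 1L || deg(indeg, v) != 1L) next
      i <- which(ends == v)
      j <- which(starts == v)
      if (length(i) == 1L && length(j) == 1L && i != j) {
        segs[i] <- paste0(segs[i], substring(segs[j], k))
        segs <- segs[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sort(unique(canonical_dna(segs)))
}
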