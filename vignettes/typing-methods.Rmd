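---
title: "Targeted-assembly MLST typing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted-assembly MLST typing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstyper)
```

## The problem

Multi-locus sequence typing (MLST) labels a bacterial isolate by the allele
variant it carries at each of a small set of housekeeping loci (typically
seven); the combination of allele numbers maps, through a profile table, to a
sequence type (ST). With whole-genome short-read data the classical routes are
whole-genome assembly followed by BLAST (slow, assembly-quality dependent) or
read-mapping with per-column consensus (fast, but unable to emit the sequence
of an allele that is not yet in the database). `mlstyper` implements a hybrid:
it *recruits* the reads that belong to each locus, *assembles only those*, and
calls alleles by exact full-length comparison against the reference database —
so it is as precise as assembly-based typing, as targeted as mapping-based
typing, and able to report the full sequence of a novel allele.

## The pipeline

For one sample and one locus:

1. **Merge** all input FASTQ files into a single pool, disregarding pairing
   (both mates enter as independent reads). Qualities are ignored throughout;
   trimming is deliberately not part of the pipeline.
2. **Recruit** reads by *perfect-match fraction*: the length of the longest
   exact (mismatch- and gap-free) run of the read occurring in any reference
   allele of the locus, on either strand, divided by the read length. A read
   is "mapped" when that run reaches the seed length (default 20 bp). Four
   nested tier sets are formed at fractions ≥ 0, ≥ 0.30, ≥ 0.60 and ≥ 0.90 of
   read length. The stringent tiers exclude reads that only brush the locus
   borders, which otherwise seed chimeric contigs; the permissive tiers keep
   enough material when coverage is thin.
3. **Assemble** each tier independently at k = 11, 15, 21, 33 and 35 with a
   de Bruijn graph (no read error correction) compacted to unitigs. A greedy
   maximal-exact-overlap assembler acts as a backup when no k yields a contig
   from a non-empty tier.
4. **Call**: tiers are scanned most stringent first and, within a tier,
   largest k first; the first contig containing an exact full-length match to
   exactly one reference allele decides the locus. If no tier matches but a
   contig reaches half the locus's shortest allele length, the locus is
   reported as a putative novel allele (`New?`) together with its trimmed
   sequence; otherwise the locus is `low coverage`.
5. **Type**: the per-locus calls are looked up in the profile table — `known`
   ST, `new` (novel allele or unseen combination) or `ND` (some locus
   unresolved).

Loci are processed independently and may run on forked workers; results are
identical for any worker count because no step after input parsing uses
randomness and every tie-break is total.

## Definitions that the literature leaves open

**"Perfectly matching X% of read length".** We define it as the longest
exact run, not the total matched bases of a gapped local alignment. The
longest run is deterministic, verifiable against a brute-force
longest-common-substring oracle (the test suite does exactly that), and
captures the intended effect: a border-spanning read matches only over the
portion inside the locus. Soft-clip tolerance of a local aligner is inherited
for free — flanks simply do not count toward the run.

**What counts as a "perfect match" of a contig.** An assembled contig from
genome-derived reads virtually always carries a few bases of flanking
sequence beyond the allele boundaries: boundary k-mers supported by reads
that extend past the locus survive any reasonable multiplicity filter. We
therefore accept an allele when its full-length sequence occurs exactly —
no mismatches, no indels, either strand — *within* the contig, with
whole-contig equality checked first and any contig matching two distinct
alleles rejected as ambiguous. This mirrors what a BLASTN full-length
perfect-identity hit reports, and it is the only reading under which exact
calling is achievable from reads sampled out of a genome rather than out of
an isolated allele.

**The reported novel-allele sequence.** Raw contigs carry the same flanks, so
a novel allele is reported after trimming the candidate contig to the region
homologous to its closest reference allele (`Biostrings::pairwiseAlignment`,
global in the reference, local in the contig; match 2, mismatch −3, gap open
5, extend 2). Candidates from every tier/k are trimmed and the one with the
best alignment score wins (ties: most stringent tier, largest k,
lexicographically smallest sequence). Score-based selection matters: the most
stringent tier occasionally misses the outermost bases of the locus (the
read windows that cover an allele end at ≥ 90% match fraction are only ~10
positions wide), while a less stringent tier contains them; the alignment
score prefers the complete candidate. This is also how novel MLST alleles
are curated in practice — a new variant is delimited by alignment to its
nearest known relative.

**Tier order.** Most stringent first. A perfect match found among reads that
match ≥ 90% of their length is maximally trustworthy; permissive tiers act
only as fallbacks. All tiers are searched for an exact match before a novel
allele is declared, so tier order cannot flip a correct call into a `New?`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `seed_length` | 20 bp | minimum exact run for a read to count as mapped (tier 0); reads shorter than this are never recruited |
| `thresholds` | 0, 0.30, 0.60, 0.90 | recruitment tiers, inclusive fractions of read length |
| `ks` | 11, 15, 21, 33, 35 | de Bruijn k-mer sizes, each assembled independently |
| `min_count` | 2 | minimum edge count; counts pool a k-mer and its reverse complement over both strands of every read, so a k-mer covered by one read has count 2 and survives. Raise to 4+ to demand multi-read support |
| `small_set` | 50 reads | below this, `min_count` drops to 1 |
| `min_tip_count` | 2 | dead-end branches shorter than 2k with all edge counts below this are trimmed (a no-op at the defaults; raise it for coverage-based tip clipping) |
| `min_overlap` | 25 bp | greedy-fallback merge floor |
| `min_new_frac` | 0.5 | a novel candidate must reach this fraction of the locus's shortest allele, else `low coverage` |

The `min_count` convention deserves a note: because allele *ends* are often
covered by a single read even at 30× (only reads starting within a few
positions of the boundary cover the terminal k-mer at high match fraction),
any filter that discards single-read k-mers guarantees truncated contigs and
failed exact calls. Pooling the two strands keeps single-read evidence at the
default threshold while still exposing a knob for noisy data.

## The synthetic benchmark

`generate_allele_db()` builds a 7-locus scheme with 10 alleles per locus
(allele 1 random over 400–600 bp, alleles 2–10 at 1–5 SNPs from allele 1 —
the within-locus similarity structure of real PubMLST schemes), and a
20-row profile table. `build_sample_genome()` embeds one chosen allele per
locus, in random orientation, into a 20 kb random background that is
rejection-sampled to share no 20-mer with any allele, so any recruited read
demonstrably originates from a locus. `simulate_reads()` draws uniform
paired 100 bp reads (insert 300 ± 30) to 30× coverage with substitution-only
errors (default 0). Benchmarks in the test suite and acceptance script use
50 samples — 350 allele calls per pass — which keeps a full
double run (full database + per-sample leave-correct-allele-out databases)
in a few minutes on one core; the corresponding real-data protocol uses
hundreds of external read sets and ~150× coverage, which is out of scope
here.

What the generator does *not* emulate: platform-specific, quality-dependent
error profiles; indel sequencing errors; uneven coverage (GC bias); multiple
locus copies; contamination; paralogous near-matches in the background.
Passing the synthetic benchmark therefore demonstrates the algorithm's
correctness under its stated assumptions, not its robustness to every
real-world artefact.

The leave-correct-allele-out protocol measures novel-allele detection
without engineering mutant isolates: each sample is retyped against a
database from which its true alleles were removed; the right answer is then
`New?` at every locus, ideally with the removed sequence reported verbatim.
`mutate_allele()` supports the complementary experiment — planting a 1-SNP
or small-indel variant and typing against the *full* database.

## Benchmark metrics

Over all samples × loci: **percentage of no-output** (blank labels —
`low coverage` counts as blank, since it names no allele and flags no new
one); **capability to identify correct alleles** (labels equal to the true
allele number; blanks and `New?` are misses); **capability to identify new
alleles** (labels flagging a novel allele in the leave-out run; naming any
remaining reference allele is a miss). Blanks always stay in the
denominator. The same three fractions are computed at ST level. For
comparability with mapping-based tools that star uncertain calls
(`allele*`), both capabilities accept a stringency switch: under *high*
stringency a starred call counts as a new-allele flag (and never as a
correct call); under *low* stringency the star is ignored. These conventions
make `capability_correct` monotone non-increasing and `capability_new`
monotone non-decreasing in stringency, which the property tests assert.

## Numerical and degenerate-input choices

* Thresholds are inclusive (a fraction of exactly 0.60 belongs to the 0.60
  tier); fractions use the full read length including any bases a trimmer
  would have removed.
* Recruitment ties prefer the forward orientation, then the lowest allele
  id. Contigs are reported on the lexicographically smaller strand, sorted
  by decreasing length then sequence, so output never depends on read order.
* An empty read set, an empty tier, or contigs all shorter than
  `min_new_frac` × (shortest allele) yield `low coverage`, never an error;
  an internal fault in one locus yields `no_output` for that locus only.
* Reference alleles with ambiguity codes are rejected at load time (or
  dropped on request): exact matching is undefined on IUPAC wildcards.
* k is odd throughout, so no k-mer equals its own reverse complement and
  strand pooling is unambiguous.

## Known limitations

* Exact full-length matching cannot rescue an allele whose terminal bases
  are uncovered; such loci surface as `New?` (with a truncated candidate) or
  `low coverage` rather than as a best-effort call.
* The greedy fallback assembler is quadratic in read count and is intended
  only for the sparse read sets on which the de Bruijn stage fails.
* Two alleles of different loci sharing a 20-mer would cross-recruit reads;
  real housekeeping loci are distinct enough that this does not occur, and
  the generator guarantees it.
* Profile tables are loaded whole into memory; PubMLST-scale tables (tens of
  thousands of rows) are no problem, but the implementation does not stream.
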