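// Longest exact-match run scoring between reads and reference alleles.
//
// Recruitment scores every read by the length of its longest substring that
// occurs exactly (mismatch-free, gap-free) in any reference allele, on either
// strand.  A suffix automaton over the reference set answers that query in
// O(|read|) per strand, which is what makes whole-read-set recruitment cheap
// enough to run per locus.

#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

// alphabet: A,C,G,T -> 0..3; anything else (separator, N) -> 4
inline int code(char ch) {
  switch (ch) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

struct Sam {
  std::vector<std::array<int, 5> > next;
  std::vector<int> link;
  std::vector<int> len;
  int last;

  Sam() {
    next.push_back(empty_row());
    link.push_back(-1);
    len.push_back(0);
    last = 0;
  }

  static std::array<int, 5> empty_row() {
    std::array<int, 5> r;
    r.fill(-1);
    return r;
  }

  void extend(int c) {
    int cur = (int) next.size();
    next.push_back(empty_row());
    len.push_back(len[last] + 1);
    link.push_back(-1);
    int p = last;
    while (p != -1 && next[p][c] == -1) {
      next[p][c] = cur;
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = next[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = (int) next.size();
        next.push_back(next[q]);
        len.push_back(len[p] + 1);
        link.push_back(link[q]);
        while (p != -1 && next[p][c] == q) {
          next[p][c] = clone;
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }

  void add(const std::string& s) {
    for (size_t i = 0; i < s.size(); ++i) extend(code(s[i]));
  }

  // longest substring of q (ACGT positions only) present in the indexed text
  int longest_run(const std::string& q) const {
    int v = 0, l = 0, best = 0;
    for (size_t i = 0; i < q.size(); ++i) {
      int c = code(q[i]);
      if (c == 4) { v = 0; l = 0; continue; }
      while (v != 0 && next[v][c] == -1) {
        v = link[v];
        l = len[v];
      }
      if (next[v][c] != -1) {
        v = next[v][c];
        ++l;
      } else {
        v = 0;
        l = 0;
      }
      if (l > best) best = l;
    }
    return best;
  }
};

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

Sam combined_sam(const std::vector<std::string>& refs) {
  Sam sam;
  for (size_t i = 0; i < refs.size(); ++i) {
    sam.add(refs[i]);
    sam.extend(4);  // separator: no match can span two references
  }
  return sam;
}

}  // namespace

// [[Rcpp::export(name = ".max_match_run")]]
IntegerVector max_match_run_cpp(CharacterVector queries, CharacterVector refs) {
  std::vector<std::string> rs(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) rs[i] = as<std::string>(refs[i]);
  Sam sam = combined_sam(rs);
  IntegerVector out(queries.size());
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    int fwd = sam.longest_run(q);
    int rev = sam.longest_run(revcomp(q));
    out[i] = fwd > rev ? fwd : rev;
  }
  return out;
}

// [[Rcpp::export(name = ".count_kmers")]]
List count_kmers_cpp(CharacterVector seqs, int k, int min_count) {
  std::unordered_map<std::string, int> counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int) s.size() < k) continue;
    for (size_t j = 0; j + k <= s.size(); ++j)
      ++counts[s.substr(j, k)];
    std::string r = revcomp(s);
    for (size_t j = 0; j + k <= r.size(); ++j)
      ++counts[r.substr(j, k)];
  }
  // an edge and its mirror are one double-stranded feature: report the
  // combined count on both (k odd, so no k-mer is its own reverse complement)
  std::vector<std::pair<std::string, int> > kept;
  kept.reserve(counts.size());
  for (std::unordered_map<std::string, int>::const_iterator it =
           counts.begin(); it != counts.end(); ++it) {
    std::unordered_map<std::string, int>::const_iterator mirror =
        counts.find(revcomp(it->first));
    int total = it->second +
        (mirror == counts.end() ? 0 : mirror->second);
    if (total >= min_count)
      kept.push_back(std::make_pair(it->first, total));
  }
  std::sort(kept.begin(), kept.end());
  CharacterVector kmer(kept.size());
  IntegerVector count(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    kmer[i] = kept[i].first;
    count[i] = kept[i].second;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// [[Rcpp::export(name = ".forward_match_run")]]
int forward_match_run_cpp(std::string query, CharacterVector refs) {
  std::vector<std::string> rs(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) rs[i] = as<std::string>(refs[i]);
  Sam sam = combined_sam(rs);
  return sam.longest_run(query);
}

// [[Rcpp::export(name = ".recruit_scores")]]
List recruit_scores_cpp(CharacterVector reads, CharacterVector alleles,
                        int min_run) {
  const R_xlen_t n = reads.size();
  const R_xlen_t m = alleles.size();
  std::vector<std::string> as_(m);
  for (R_xlen_t j = 0; j < m; ++j) as_[j] = as<std::string>(alleles[j]);
  Sam pooled = combined_sam(as_);

  // per-allele automatons, built lazily (most reads never pass min_run)
  std::vector<Sam> per;
  bool built = false;

  IntegerVector run(n), ori(n), idx(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(reads[i]);
    std::string qr = revcomp(q);
    int fwd = pooled.longest_run(q);
    int rev = pooled.longest_run(qr);
    int best = fwd > rev ? fwd : rev;
    run[i] = best;
    if (best < min_run || best < 1) {
      ori[i] = NA_INTEGER;
      idx[i] = NA_INTEGER;
      continue;
    }
    if (!built) {
      per.reserve(m);
      for (R_xlen_t j = 0; j < m; ++j) {
        Sam s;
        s.add(as_[j]);
        per.push_back(s);
      }
      built = true;
    }
    // ties: forward before reverse, then lowest allele index
    int bi = NA_INTEGER, bo = NA_INTEGER;
    for (R_xlen_t j = 0; j < m && bi == NA_INTEGER; ++j) {
      if (per[j].longest_run(q) == best) { bi = (int) j + 1; bo = 1; }
    }
    if (bi == NA_INTEGER) {
      for (R_xlen_t j = 0; j < m && bi == NA_INTEGER; ++j) {
        if (per[j].longest_run(qr) == best) { bi = (int) j + 1; bo = 2; }
      }
    }
    ori[i] = bo;
    idx[i] = bi;
  }
  return List::create(_["run"] = run, _["orientation"] = ori,
                      _["allele"] = idx);
}
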