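#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Exact mismatch-limited read placement (no indels). Semantics: a read
// is assigned to the gene holding its lowest-mismatch placement across
// both strands, provided that count is <= max_mismatch; equal best
// counts on two different genes make the read ambiguous.
//
// Search uses pigeonhole seeding: a read with at most m mismatches must
// contain at least one of m+1 disjoint exact segments, so k-mer seeds
// at m+1 offsets enumerate every qualifying placement. Short reads fall
// back to a full scan.

static inline int encode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static bool encode_kmer(const std::string &s, int pos, int k,
                        uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = encode(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// mismatches of read placed at gene[start..], early exit above limit
static int verify(const std::string &read, const std::string &gene,
                  long start, int limit) {
  const long rl = (long)read.size();
  if (start < 0 || start + rl > (long)gene.size()) return limit + 1;
  int mm = 0;
  for (long i = 0; i < rl; ++i) {
    if (gene[start + i] != read[i] && ++mm > limit) return limit + 1;
  }
  return mm;
}

static int best_mm_scan(const std::string &read, const std::string &gene,
                        int limit) {
  const long rl = (long)read.size(), gl = (long)gene.size();
  int best = limit + 1;
  for (long s = 0; s + rl <= gl; ++s) {
    int mm = verify(read, gene, s, best - 1 < limit ? best - 1 : limit);
    if (mm < best) {
      best = mm;
      if (best == 0) break;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
IntegerVector map_reads_cpp(CharacterVector reads, CharacterVector genes,
                            CharacterVector genes_rc, int max_mismatch) {
  const int nr = reads.size();
  const int ng = genes.size();
  std::vector<std::string> seqs(2 * ng);  // fwd then rc, per gene
  for (int j = 0; j < ng; ++j) {
    seqs[2 * j] = as<std::string>(genes[j]);
    seqs[2 * j + 1] = as<std::string>(genes_rc[j]);
  }
  std::vector<std::string> rd(nr);
  long min_len = -1;
  for (int i = 0; i < nr; ++i) {
    rd[i] = as<std::string>(reads[i]);
    long l = (long)rd[i].size();
    if (min_len < 0 || l < min_len) min_len = l;
  }
  const int n_seeds = max_mismatch + 1;
  int k = nr > 0 ? (int)(min_len / n_seeds) : 0;
  if (k > 31) k = 31;
  const bool seeded = k >= 8;

  // k-mer index over all gene strands: kmer -> packed (seq idx, pos)
  std::unordered_multimap<uint64_t, uint64_t> index;
  if (seeded) {
    size_t total = 0;
    for (auto &s : seqs) total += s.size();
    index.reserve(total);
    for (size_t j = 0; j < seqs.size(); ++j) {
      const std::string &s = seqs[j];
      for (long p = 0; p + k <= (long)s.size(); ++p) {
        uint64_t key;
        if (encode_kmer(s, p, k, key)) {
          index.emplace(key, ((uint64_t)j << 32) | (uint64_t)p);
        }
      }
    }
  }

  IntegerVector out(nr);  // gene (1-based), 0 unassigned, -1 ambiguous
  std::vector<int> gene_best(ng);
  std::vector<int> touched;
  for (int i = 0; i < nr; ++i) {
    const std::string &r = rd[i];
    int best = max_mismatch + 1;
    int best_gene = 0;
    bool tie = false;
    if (seeded) {
      std::fill(gene_best.begin(), gene_best.end(), max_mismatch + 1);
      touched.clear();
      for (int s = 0; s < n_seeds; ++s) {
        long off = (long)s * k;
        uint64_t key;
        if (!encode_kmer(r, off, k, key)) continue;
        auto range = index.equal_range(key);
        for (auto it = range.first; it != range.second; ++it) {
          int j = (int)(it->second >> 32);
          long pos = (long)(it->second & 0xffffffffULL);
          int g = j / 2;
          int mm = verify(r, seqs[j], pos - off, max_mismatch);
          if (mm < gene_best[g]) {
            if (gene_best[g] > max_mismatch) touched.push_back(g);
            gene_best[g] = mm;
          }
        }
      }
      for (int g : touched) {
        int mm = gene_best[g];
        if (mm < best) {
          best = mm; best_gene = g + 1; tie = false;
        } else if (mm == best) {
          tie = true;
        }
      }
    } else {
      for (int g = 0; g < ng; ++g) {
        int limit = best <= max_mismatch ? best : max_mismatch;
        int mm = best_mm_scan(r, seqs[2 * g], limit);
        int mm2 = best_mm_scan(r, seqs[2 * g + 1], limit);
        if (mm2 < mm) mm = mm2;
        if (mm < best) {
          best = mm; best_gene = g + 1; tie = false;
        } else if (mm == best && best <= max_mismatch) {
          tie = true;
        }
      }
    }
    if (best > max_mismatch) out[i] = 0;
    else if (tie) out[i] = -1;
    else out[i] = best_gene;
  }
  return out;
}
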