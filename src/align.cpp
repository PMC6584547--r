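#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <array>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;  // N or anything else: never indexed
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// encode s[pos, pos+k) as 2-bit k-mer; false when it contains a non-ACGT base
static bool encode_kmer(const std::string &s, size_t pos, int k,
                        uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// Ungapped seed-and-extend alignment of reads against a set of reference
// sequences.  For each read (both strands), exact k-mer seeds taken at the
// start, middle and end of the read propose diagonals; each candidate
// placement fully contained in the reference is scored by Hamming distance
// with early abort beyond max_mm.  One best placement (fewest mismatches;
// forward strand, then leftmost position on ties) is reported per
// (read, reference) pair.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(CharacterVector reads, CharacterVector refs,
                          int k, int max_mm) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int j = 0; j < nref; ++j) R[j] = as<std::string>(refs[j]);

  // k-mer index over all references: kmer -> packed (ref << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  for (int j = 0; j < nref; ++j) {
    const std::string &s = R[j];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (encode_kmer(s, p, k, key))
        index[key].push_back(((uint64_t)j << 32) | (uint64_t)p);
    }
  }

  std::vector<int> out_read, out_ref, out_mm, out_pos, out_strand;

  for (int i = 0; i < reads.size(); ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    if (L < k) continue;
    std::string rc(L, 'N');
    for (int p = 0; p < L; ++p) rc[p] = comp(fwd[L - 1 - p]);

    // best per ref: mm, strand (0 fwd / 1 rev), pos
    std::unordered_map<int, std::array<int, 3> > best;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = (strand == 0) ? fwd : rc;
      std::set<std::pair<int, int> > tried;  // (ref, start) already scored
      int offs[3] = {0, (L - k) / 2, L - k};
      for (int oi = 0; oi < 3; ++oi) {
        int off = offs[oi];
        if (oi > 0 && off == offs[oi - 1]) continue;
        uint64_t key;
        if (!encode_kmer(s, off, k, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (uint64_t packed : it->second) {
          int rj = (int)(packed >> 32);
          int rp = (int)(packed & 0xffffffffULL);
          int start = rp - off;
          if (start < 0 || start + L > (int)R[rj].size()) continue;
          if (!tried.insert(std::make_pair(rj, start)).second) continue;
          const std::string &ref = R[rj];
          int mm = 0;
          for (int p = 0; p < L; ++p) {
            if (s[p] != ref[start + p]) {
              if (++mm > max_mm) break;
            }
          }
          if (mm > max_mm) continue;
          auto b = best.find(rj);
          if (b == best.end() || mm < b->second[0] ||
              (mm == b->second[0] &&
               (strand < b->second[1] ||
                (strand == b->second[1] && start < b->second[2])))) {
            best[rj] = {mm, strand, start};
          }
        }
      }
    }

    std::vector<int> refs_hit;
    refs_hit.reserve(best.size());
    for (auto &kv : best) refs_hit.push_back(kv.first);
    std::sort(refs_hit.begin(), refs_hit.end());
    for (int rj : refs_hit) {
      out_read.push_back(i + 1);
      out_ref.push_back(rj + 1);
      out_mm.push_back(best[rj][0]);
      out_strand.push_back(best[rj][1]);
      out_pos.push_back(best[rj][2]);
    }
  }

  return DataFrame::create(
    _["read"] = out_read, _["ref"] = out_ref, _["mismatches"] = out_mm,
    _["strand"] = out_strand, _["pos"] = out_pos);
}
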