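#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything not A/C/G/T
static inline int code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N'; break;
    }
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string& s, int k) {
  KmerIndex idx;
  const int n = (int) s.size();
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = code(s[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++valid >= k) idx[kmer].push_back(i - k + 1);
  }
  return idx;
}

// Banded semi-global alignment: the whole fragment is aligned; leading and
// trailing gaps on the window side are free. Band column t in [0, 2*band]
// maps row i to window position wstart + i + t. Out-of-range window
// positions behave as mismatching pad. Linear gap penalty.
// Returns matches and aligned (match+mismatch) column counts via out-params;
// returns best score (INT_MIN/2 if infeasible).
static const int NEG = -1000000000;

static int band_align(const std::string& frag, const std::string& target,
                      long wstart, int band, int& matches, int& aligned) {
  const int m = (int) frag.size();
  const int W = 2 * band + 1;
  const long tlen = (long) target.size();
  std::vector<int> prev(W, NEG), cur(W, NEG);
  // traceback: 0 diag, 1 up (gap in window), 2 left (gap in fragment), 3 free start
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 3);
  for (int t = 0; t < W; ++t) prev[t] = 0;  // row 0: free window prefix
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  for (int i = 1; i <= m; ++i) {
    int fc = code(frag[i - 1]);
    for (int t = 0; t < W; ++t) {
      long j = wstart + (i - 1) + t;       // window position consumed by diag move
      int best = NEG; uint8_t dir = 3;
      // diagonal from (i-1, t)
      if (prev[t] > NEG) {
        int tc = (j >= 0 && j < tlen) ? code(target[(size_t) j]) : -2;
        int sc = prev[t] + ((fc >= 0 && fc == tc) ? MATCH : MISMATCH);
        if (sc > best) { best = sc; dir = 0; }
      }
      // up from (i-1, t+1): gap in window
      if (t + 1 < W && prev[t + 1] > NEG) {
        int sc = prev[t + 1] + GAP;
        if (sc > best) { best = sc; dir = 1; }
      }
      // left from (i, t-1): gap in fragment
      if (t - 1 >= 0 && cur[t - 1] > NEG) {
        int sc = cur[t - 1] + GAP;
        if (sc > best) { best = sc; dir = 2; }
      }
      cur[t] = best;
      tb[(size_t) i * W + t] = dir;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), NEG);
  }
  // best end cell in last row (free window suffix)
  int bestT = -1, bestScore = NEG;
  for (int t = 0; t < W; ++t) {
    if (prev[t] > bestScore) { bestScore = prev[t]; bestT = t; }
  }
  matches = 0; aligned = 0;
  if (bestT < 0 || bestScore <= NEG) return NEG;
  int i = m, t = bestT;
  while (i > 0) {
    uint8_t dir = tb[(size_t) i * W + t];
    if (dir == 0) {
      long j = wstart + (i - 1) + t;
      int fc = code(frag[i - 1]);
      int tc = (j >= 0 && j < (long) target.size()) ? code(target[(size_t) j]) : -2;
      ++aligned;
      if (fc >= 0 && fc == tc) ++matches;
      --i;
    } else if (dir == 1) {
      --i; ++t;
    } else if (dir == 2) {
      --t;
    } else {
      break;
    }
  }
  return bestScore;
}

// One direction of fragment-seeded genome ANI: cut `query` into consecutive
// full-length fragments, seed each on exact k-mers against `target` (both
// strands optionally), align around the best-supported diagonal.
// [[Rcpp::export(name = ".frag_align_dir")]]
DataFrame frag_align_dir(std::string query, std::string target,
                         int fragment_len, int seed_k, int seed_step,
                         int band, bool both_strands) {
  const std::string target_rc = both_strands ? revcomp(target) : std::string();
  KmerIndex idx_f = build_index(target, seed_k);
  KmerIndex idx_r = both_strands ? build_index(target_rc, seed_k) : KmerIndex();
  const int n_frags = (int) (query.size() / (size_t) fragment_len);
  std::vector<int> frag_start(n_frags), n_seeds(n_frags), strand(n_frags);
  std::vector<double> identity(n_frags), coverage(n_frags);
  std::vector<int> aligned_cols(n_frags);
  uint64_t mask = (seed_k < 32) ? ((1ULL << (2 * seed_k)) - 1) : ~0ULL;
  for (int f = 0; f < n_frags; ++f) {
    frag_start[f] = f * fragment_len;
    std::string frag = query.substr((size_t) f * fragment_len, fragment_len);
    // diagonal votes per strand: diag = target_pos - frag_offset
    std::unordered_map<long, int> votes_f, votes_r;
    for (int off = 0; off + seed_k <= fragment_len; off += seed_step) {
      uint64_t kmer = 0; bool ok = true;
      for (int p = 0; p < seed_k; ++p) {
        int c = code(frag[off + p]);
        if (c < 0) { ok = false; break; }
        kmer = ((kmer << 2) | (uint64_t) c) & mask;
      }
      if (!ok) continue;
      KmerIndex::const_iterator it = idx_f.find(kmer);
      if (it != idx_f.end())
        for (size_t q = 0; q < it->second.size(); ++q)
          votes_f[(long) it->second[q] - off] += 1;
      if (both_strands) {
        it = idx_r.find(kmer);
        if (it != idx_r.end())
          for (size_t q = 0; q < it->second.size(); ++q)
            votes_r[(long) it->second[q] - off] += 1;
      }
    }
    long best_diag = 0; int best_votes = 0, best_strand = 0;
    for (std::unordered_map<long, int>::iterator it = votes_f.begin(); it != votes_f.end(); ++it) {
      if (it->second > best_votes ||
          (it->second == best_votes && best_votes > 0 && it->first < best_diag)) {
        best_votes = it->second; best_diag = it->first; best_strand = 1;
      }
    }
    for (std::unordered_map<long, int>::iterator it = votes_r.begin(); it != votes_r.end(); ++it) {
      if (it->second > best_votes) {  // forward strand wins ties
        best_votes = it->second; best_diag = it->first; best_strand = -1;
      }
    }
    n_seeds[f] = best_votes;
    if (best_votes == 0) {
      strand[f] = 0; identity[f] = NA_REAL; coverage[f] = 0.0; aligned_cols[f] = 0;
      continue;
    }
    const std::string& tgt = (best_strand == 1) ? target : target_rc;
    int matches = 0, aligned = 0;
    band_align(frag, tgt, best_diag - band, band, matches, aligned);
    strand[f] = best_strand;
    aligned_cols[f] = aligned;
    identity[f] = aligned > 0 ? 100.0 * matches / aligned : NA_REAL;
    coverage[f] = (double) aligned / fragment_len;
  }
  return DataFrame::create(
    _["frag_start"] = frag_start, _["n_seeds"] = n_seeds, _["strand"] = strand,
    _["identity"] = identity, _["aligned_cols"] = aligned_cols,
    _["coverage"] = coverage);
}
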