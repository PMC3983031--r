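#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Bases are encoded 0=A,1=C,2=G,3=T,4=N. N never matches anything
// (including another N), so it always scores as a mismatch.
static inline int mm(int a, int b) {
  return (a != b || a == 4 || b == 4) ? 1 : 0;
}

// Exhaustive ungapped scan: every start position of `read` along `genome`
// with at most max_mm mismatches. Returns a 2-column matrix (pos, mm),
// pos 1-based.
// [[Rcpp::export]]
IntegerMatrix scan_ungapped_cpp(IntegerVector read, IntegerVector genome,
                                int max_mm) {
  const int L = read.size(), N = genome.size();
  std::vector<uint8_t> r(read.begin(), read.end());
  std::vector<uint8_t> g(genome.begin(), genome.end());
  std::vector<int> pos, mms;
  for (int p = 0; p + L <= N; ++p) {
    int m = 0;
    for (int i = 0; i < L; ++i) {
      m += mm(r[i], g[p + i]);
      if (m > max_mm) break;
    }
    if (m <= max_mm) { pos.push_back(p + 1); mms.push_back(m); }
  }
  IntegerMatrix out(pos.size(), 2);
  for (size_t i = 0; i < pos.size(); ++i) {
    out(i, 0) = pos[i]; out(i, 1) = mms[i];
  }
  colnames(out) = CharacterVector::create("pos", "mm");
  return out;
}

// Exhaustive single-gap scan: every placement of `read` split into a prefix
// of length s (>= min_anchor) at genome position p and a suffix at position
// q, with gap = q - (p + s) in [min_gap, max_gap] and total mismatches
// <= max_mm. Returns a 4-column matrix (pos, split, qpos, mm); pos and qpos
// 1-based, split = prefix length.
//
// Prefix-mismatch counts P_s[p] and suffix counts T_s[q] are built as
// rolling byte rows (counts capped at max_mm + 1); only the positions at
// or below the ceiling survive as candidates, so the pair loop touches a
// handful of (p, q) combinations per split on random sequence.
// [[Rcpp::export]]
IntegerMatrix scan_gapped_cpp(IntegerVector read, IntegerVector genome,
                              int max_mm, int min_gap, int max_gap,
                              int min_anchor) {
  const int L = read.size(), N = genome.size();
  std::vector<int> o_pos, o_split, o_q, o_mm;
  const int s_lo = min_anchor, s_hi = L - min_anchor;
  if (L < 2 * min_anchor || N < L + min_gap || s_lo > s_hi) {
    IntegerMatrix out(0, 4);
    colnames(out) = CharacterVector::create("pos", "split", "qpos", "mm");
    return out;
  }
  std::vector<uint8_t> r(read.begin(), read.end());
  std::vector<uint8_t> g(genome.begin(), genome.end());
  const uint8_t cap = (uint8_t)(max_mm + 1);

  // suffix candidates per split: positions q (sorted) with T_s[q] <= max_mm
  std::vector<std::vector<int> > suf_q(s_hi + 1);
  std::vector<std::vector<uint8_t> > suf_m(s_hi + 1);
  {
    std::vector<uint8_t> nxt(N + 1, 0), cur(N + 1, cap);
    for (int j = L - 1; j >= s_lo; --j) {
      const uint8_t rj = r[j];
      const int maxq = N - (L - j);
      for (int q = 0; q <= maxq; ++q) {
        int v = nxt[q + 1] + mm(rj, g[q]);
        cur[q] = v > cap ? cap : (uint8_t)v;
      }
      for (int q = maxq + 1; q <= N; ++q) cur[q] = cap;
      if (j <= s_hi) {
        for (int q = 0; q <= maxq; ++q) {
          if (cur[q] <= max_mm) {
            suf_q[j].push_back(q);
            suf_m[j].push_back(cur[q]);
          }
        }
      }
      nxt.swap(cur);
    }
  }

  // rolling prefix row; pair candidates per split through binary search
  std::vector<uint8_t> P(N, 0);
  for (int s = 1; s <= s_hi; ++s) {
    const uint8_t rs = r[s - 1];
    const int maxp = N - s;
    for (int p = 0; p <= maxp; ++p) {
      int v = P[p] + mm(rs, g[p + s - 1]);
      P[p] = v > cap ? cap : (uint8_t)v;
    }
    if (s < s_lo) continue;
    const std::vector<int> &qs = suf_q[s];
    if (qs.empty()) continue;
    const std::vector<uint8_t> &qm = suf_m[s];
    const int suf_len = L - s;
    const int p_max = N - suf_len - min_gap - s;
    for (int p = 0; p <= p_max; ++p) {
      if (P[p] > max_mm) continue;
      const int q_lo = p + s + min_gap;
      const int q_hi = p + s + max_gap;
      std::vector<int>::const_iterator it =
          std::lower_bound(qs.begin(), qs.end(), q_lo);
      for (; it != qs.end() && *it <= q_hi; ++it) {
        int tot = P[p] + qm[it - qs.begin()];
        if (tot <= max_mm) {
          o_pos.push_back(p + 1); o_split.push_back(s);
          o_q.push_back(*it + 1); o_mm.push_back(tot);
        }
      }
    }
  }
  IntegerMatrix out(o_pos.size(), 4);
  for (size_t i = 0; i < o_pos.size(); ++i) {
    out(i, 0) = o_pos[i]; out(i, 1) = o_split[i];
    out(i, 2) = o_q[i];   out(i, 3) = o_mm[i];
  }
  colnames(out) = CharacterVector::create("pos", "split", "qpos", "mm");
  return out;
}
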