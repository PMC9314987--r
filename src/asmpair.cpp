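#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// 2-bit base codes; anything but ACGT (case-insensitive) breaks a k-mer.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t revcomp_kmer(uint64_t km, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (km & 3ULL));
    km >>= 2;
  }
  return rc;
}

struct KmerPos {
  uint64_t kmer;
  uint64_t packed; // chrom index << 40 | position
  bool operator<(const KmerPos& o) const {
    return kmer < o.kmer || (kmer == o.kmer && packed < o.packed);
  }
};

// enumerate all clean k-mers of a set of sequences
static void collect_kmers(const std::vector<std::string>& seqs, int k,
                          std::vector<KmerPos>& out) {
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    if ((int)s.size() < k) continue;
    uint64_t km = 0;
    int run = 0; // clean bases accumulated
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        uint64_t pos = i + 1 - k;
        out.push_back({km, ((uint64_t)ci << 40) | pos});
      }
    }
  }
}

struct Anchor {
  int qc, tc;     // chromosome indices
  int64_t q, t;   // start positions
  int strand;     // 0 = '+', 1 = '-'
};

struct OpenChain {
  int64_t q0, t0, lastq, lastt, diag; // diag = t-q (+) or t+q (-)
  long long matches, columns, nanchors;
};

// [[Rcpp::export]]
DataFrame cpp_anchor_chain(CharacterVector query_seqs, CharacterVector target_seqs,
                           int k, int max_target_hits, int gap_tol,
                           int max_anchor_gap, int min_block) {
  std::vector<std::string> qs(query_seqs.size()), ts(target_seqs.size());
  for (int i = 0; i < query_seqs.size(); ++i) qs[i] = as<std::string>(query_seqs[i]);
  for (int i = 0; i < target_seqs.size(); ++i) ts[i] = as<std::string>(target_seqs[i]);

  // target k-mer index (sorted), query k-mer multiset for uniqueness testing
  std::vector<KmerPos> tk, qk;
  collect_kmers(ts, k, tk);
  collect_kmers(qs, k, qk);
  std::sort(tk.begin(), tk.end());
  std::vector<uint64_t> qkeys(qk.size());
  for (size_t i = 0; i < qk.size(); ++i) qkeys[i] = qk[i].kmer;
  std::sort(qkeys.begin(), qkeys.end());

  auto query_unique = [&](uint64_t km) {
    auto lo = std::lower_bound(qkeys.begin(), qkeys.end(), km);
    return lo != qkeys.end() && *lo == km && (lo + 1 == qkeys.end() || *(lo + 1) != km);
  };

  std::vector<Anchor> anchors;
  // scan query positions in natural order (qk preserves chrom-major order)
  for (size_t i = 0; i < qk.size(); ++i) {
    uint64_t km = qk[i].kmer;
    if (!query_unique(km)) continue;
    int qc = (int)(qk[i].packed >> 40);
    int64_t qpos = (int64_t)(qk[i].packed & ((1ULL << 40) - 1));
    for (int strand = 0; strand < 2; ++strand) {
      uint64_t key = strand == 0 ? km : revcomp_kmer(km, k);
      if (strand == 1 && key == km) continue; // palindromic k-mer: skip '-' duplicate
      auto lo = std::lower_bound(tk.begin(), tk.end(), KmerPos{key, 0});
      auto hi = lo;
      while (hi != tk.end() && hi->kmer == key) ++hi;
      int nhit = (int)(hi - lo);
      if (nhit == 0 || nhit > max_target_hits) continue;
      for (auto it = lo; it != hi; ++it) {
        int tc = (int)(it->packed >> 40);
        int64_t tpos = (int64_t)(it->packed & ((1ULL << 40) - 1));
        anchors.push_back({qc, tc, qpos, tpos, strand});
      }
    }
  }

  std::sort(anchors.begin(), anchors.end(), [](const Anchor& a, const Anchor& b) {
    if (a.qc != b.qc) return a.qc < b.qc;
    if (a.tc != b.tc) return a.tc < b.tc;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.q != b.q) return a.q < b.q;
    return a.t < b.t;
  });

  // output block accumulators
  std::vector<int> o_qc, o_tc, o_strand;
  std::vector<double> o_qs, o_qe, o_ts, o_te, o_match, o_blen, o_nanch;

  std::vector<OpenChain> open;
  int cur_qc = -1, cur_tc = -1, cur_strand = -1;

  auto close_chain = [&](const OpenChain& ch, int qc, int tc, int strand) {
    long long matches = ch.matches + k, columns = ch.columns + k;
    int64_t qstart = ch.q0, qend = ch.lastq + k;
    int64_t tstart, tend;
    if (strand == 0) { tstart = ch.t0; tend = ch.lastt + k; }
    else { tstart = ch.lastt; tend = ch.t0 + k; }
    if (qend - qstart < min_block || tend - tstart < min_block) return;
    o_qc.push_back(qc); o_tc.push_back(tc); o_strand.push_back(strand);
    o_qs.push_back((double)qstart); o_qe.push_back((double)qend);
    o_ts.push_back((double)tstart); o_te.push_back((double)tend);
    o_match.push_back((double)matches); o_blen.push_back((double)columns);
    o_nanch.push_back((double)ch.nanchors);
  };

  auto flush_open = [&]() {
    for (const auto& ch : open) close_chain(ch, cur_qc, cur_tc, cur_strand);
    open.clear();
  };

  for (const auto& a : anchors) {
    if (a.qc != cur_qc || a.tc != cur_tc || a.strand != cur_strand) {
      flush_open();
      cur_qc = a.qc; cur_tc = a.tc; cur_strand = a.strand;
    }
    // retire chains that fell too far behind
    for (size_t i = 0; i < open.size();) {
      if (a.q - open[i].lastq > max_anchor_gap) {
        close_chain(open[i], cur_qc, cur_tc, cur_strand);
        open[i] = open.back(); open.pop_back();
      } else ++i;
    }
    int64_t adiag = (a.strand == 0) ? (a.t - a.q) : (a.t + a.q);
    // find best-matching open chain (smallest diagonal drift)
    int best = -1; int64_t bestd = gap_tol + 1;
    for (size_t i = 0; i < open.size(); ++i) {
      if (a.q <= open[i].lastq) continue;
      int64_t d = adiag - open[i].diag; if (d < 0) d = -d;
      if (d < bestd) { bestd = d; best = (int)i; }
    }
    if (best < 0) {
      open.push_back({a.q, a.t, a.q, a.t, adiag, 0, 0, 1});
      continue;
    }
    OpenChain& ch = open[best];
    const std::string& qseq = qs[a.qc];
    const std::string& tseq = ts[a.tc];
    int64_t dq = a.q - ch.lastq;
    int64_t dt = (a.strand == 0) ? (a.t - ch.lastt) : (ch.lastt - a.t);
    if (dt < 0) dt = 0; // guarded by diag tolerance; degenerate overlap
    int64_t dmin = std::min(dq, dt), dmax = std::max(dq, dt);
    long long m = 0;
    if (a.strand == 0) {
      for (int64_t j = 1; j <= dmin; ++j)
        if (base_code(qseq[ch.lastq + j]) >= 0 &&
            qseq[ch.lastq + j] == tseq[ch.lastt + j]) ++m;
    } else {
      for (int64_t j = 1; j <= dmin; ++j)
        if (base_code(qseq[ch.lastq + j]) >= 0 &&
            qseq[ch.lastq + j] == comp_char(tseq[ch.lastt + k - 1 - j])) ++m;
    }
    ch.columns += dmax; ch.matches += m;
    ch.lastq = a.q; ch.lastt = a.t; ch.diag = adiag; ch.nanchors++;
  }
  flush_open();

  return DataFrame::create(
    _["qc"] = o_qc, _["tc"] = o_tc, _["strand"] = o_strand,
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["tstart"] = o_ts, _["tend"] = o_te,
    _["matches"] = o_match, _["block_length"] = o_blen,
    _["n_anchors"] = o_nanch);
}

// Banded global alignment under unit match/mismatch/gap scoring.
// Objective (lexicographic): minimize edit cost, then maximize matches,
// then minimize alignment columns. Returns c(identity, matches, columns, cost).
// [[Rcpp::export]]
NumericVector cpp_banded_identity(std::string s1, std::string s2, int band) {
  int n1 = (int)s1.size(), n2 = (int)s2.size();
  const int INF = 1 << 29;
  if (band < std::abs(n1 - n2) + 1) band = std::abs(n1 - n2) + 1;
  int W = 2 * band + 1;

  std::vector<int> cost(W), mat(W), col(W), ncost(W), nmat(W), ncol(W);

  auto better = [](int c1, int m1, int l1, int c2, int m2, int l2) {
    if (c1 != c2) return c1 < c2;
    if (m1 != m2) return m1 > m2;
    return l1 < l2;
  };

  // row 0: j in [max(0, -band), min(n2, band)]
  for (int w = 0; w < W; ++w) { cost[w] = INF; mat[w] = 0; col[w] = INF; }
  for (int j = 0; j <= std::min(n2, band); ++j) {
    int w = j + band; // w = j - i + band, i = 0
    cost[w] = j; mat[w] = 0; col[w] = j;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int w = 0; w < W; ++w) { ncost[w] = INF; nmat[w] = 0; ncol[w] = INF; }
    int jlo = std::max(0, i - band), jhi = std::min(n2, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int w = j - i + band;
      int bc = INF, bm = 0, bl = INF;
      if (j > 0 && cost[w] < INF) { // diagonal: prev row, j-1 -> same w
        bool eq = s1[i - 1] == s2[j - 1] && base_code(s1[i - 1]) >= 0;
        int c = cost[w] + (eq ? 0 : 1), m = mat[w] + (eq ? 1 : 0), l = col[w] + 1;
        if (better(c, m, l, bc, bm, bl)) { bc = c; bm = m; bl = l; }
      }
      if (w + 1 < W && cost[w + 1] < INF) { // up: gap in s2 (consume s1[i-1])
        int c = cost[w + 1] + 1, m = mat[w + 1], l = col[w + 1] + 1;
        if (better(c, m, l, bc, bm, bl)) { bc = c; bm = m; bl = l; }
      }
      if (j > 0 && w - 1 >= 0 && ncost[w - 1] < INF) { // left: gap in s1
        int c = ncost[w - 1] + 1, m = nmat[w - 1], l = ncol[w - 1] + 1;
        if (better(c, m, l, bc, bm, bl)) { bc = c; bm = m; bl = l; }
      }
      ncost[w] = bc; nmat[w] = bm; ncol[w] = bl;
    }
    std::swap(cost, ncost); std::swap(mat, nmat); std::swap(col, ncol);
  }
  int w = n2 - n1 + band;
  if (w < 0 || w >= W || cost[w] >= INF)
    stop("band too narrow for this sequence pair");
  double columns = col[w], matches = mat[w];
  double identity = columns > 0 ? matches / columns : 1.0;
  return NumericVector::create(identity, matches, columns, (double)cost[w]);
}

// Count positions at which two equal-length sequences differ (ACGT-aware).
// [[Rcpp::export]]
int cpp_hamming(std::string s1, std::string s2) {
  if (s1.size() != s2.size()) stop("sequences must have equal length");
  int d = 0;
  for (size_t i = 0; i < s1.size(); ++i) if (s1[i] != s2[i]) ++d;
  return d;
}
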