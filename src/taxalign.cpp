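// Core index and alignment kernels.
//
// The concatenated index text uses a 7-symbol integer alphabet:
//   0 = terminal sentinel '$' (unique, lexicographically smallest)
//   1 = record separator '#' (between member sequences; blocks matches
//       from spanning record boundaries)
//   2 = A, 3 = C, 4 = G, 5 = N, 6 = T
// N is an ordinary symbol that matches only itself; the R layer rejects
// query patterns containing N before they reach the search routines.
// All coordinates in this layer are 0-based.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <set>
using namespace Rcpp;

static const int ALPHA = 7;

static inline int char_code(char ch) {
  switch (ch) {
    case 'A': case 'a': return 2;
    case 'C': case 'c': return 3;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 6;
    default: return 5;  // anything else is treated as N
  }
}

static inline int comp_code(int c) {
  switch (c) {
    case 2: return 6;
    case 6: return 2;
    case 3: return 4;
    case 4: return 3;
    default: return c;  // N complements to N
  }
}

// ---------------------------------------------------------------------------
// Suffix array: rank-doubling with LSD counting sort, O(n log n).
// The text must end with the unique smallest sentinel (code 0), so suffix
// order equals cyclic-shift order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector text) {
  const int n = text.size();
  if (n == 0) stop("cannot build a suffix array over an empty text");
  std::vector<int> sa(n), rnk(n), tmp(n), sa2(n);
  for (int i = 0; i < n; ++i) rnk[i] = text[i];
  for (int i = 0; i < n; ++i) sa[i] = i;
  std::vector<int> cnt;
  // initial ranks are raw symbol codes, which may exceed n on tiny texts
  const int K = std::max(n, ALPHA) + 2;
  for (int k = 1;; k <<= 1) {
    // secondary key: rank of the suffix k positions ahead (+1; absent = 0)
    cnt.assign(K, 0);
    for (int i = 0; i < n; ++i) {
      int key = (i + k < n) ? rnk[i + k] + 1 : 0;
      cnt[key + 1]++;
    }
    for (int i = 1; i < (int)cnt.size(); ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) {
      int key = (i + k < n) ? rnk[i + k] + 1 : 0;
      sa2[cnt[key]++] = i;
    }
    // primary key: current rank, stable over the secondary ordering
    cnt.assign(K, 0);
    for (int i = 0; i < n; ++i) cnt[rnk[i] + 1]++;
    for (int i = 1; i < (int)cnt.size(); ++i) cnt[i] += cnt[i - 1];
    for (int idx = 0; idx < n; ++idx) {
      int s = sa2[idx];
      sa[cnt[rnk[s]]++] = s;
    }
    // recompute ranks
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      int a2 = (a + k < n) ? rnk[a + k] : -1;
      int b2 = (b + k < n) ? rnk[b + k] : -1;
      bool same = (rnk[a] == rnk[b]) && (a2 == b2);
      tmp[b] = tmp[a] + (same ? 0 : 1);
    }
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// ---------------------------------------------------------------------------
// FM-index query machinery: checkpointed Occ ranks + backward search.
// occ is an (n_checkpoints x ALPHA) matrix; occ(k, c) = count of symbol c in
// bwt[0 .. k*occ_rate). Suffix-array values may be row-subsampled: sa_vals
// stores SA[row] for rows with row %% sa_rate == 0; other rows are recovered
// by walking LF until a sampled row is reached (row 0 is always sampled, so
// the walk terminates).
// ---------------------------------------------------------------------------

struct FM {
  const int* bwt;
  int n;
  const int* ctab;       // ctab[c] = number of text symbols with code < c
  const int* occ;        // column-major, ncp rows
  int ncp;
  int occ_rate;
  const int* sa_vals;
  int sa_rate;

  inline int rank(int c, int i) const {
    int k = i / occ_rate;
    int cntv = occ[(size_t)c * ncp + k];
    for (int j = k * occ_rate; j < i; ++j) cntv += (bwt[j] == c);
    return cntv;
  }

  bool search(const int* pat, int m, int& sp, int& ep) const {
    sp = 0;
    ep = n;
    for (int i = m - 1; i >= 0; --i) {
      int c = pat[i];
      if (c < 0 || c >= ALPHA) return false;
      sp = ctab[c] + rank(c, sp);
      ep = ctab[c] + rank(c, ep);
      if (sp >= ep) return false;
    }
    return true;
  }

  int locate(int row) const {
    int steps = 0;
    while (row % sa_rate != 0) {
      int c = bwt[row];
      row = ctab[c] + rank(c, row);
      ++steps;
    }
    long p = (long)sa_vals[row / sa_rate] + steps;
    if (p >= n) p -= n;
    return (int)p;
  }
};

static FM make_fm(const IntegerVector& bwt, const IntegerVector& ctab,
                  const IntegerMatrix& occ, int occ_rate,
                  const IntegerVector& sa_vals, int sa_rate) {
  FM fm;
  fm.bwt = INTEGER(bwt);
  fm.n = bwt.size();
  fm.ctab = INTEGER(ctab);
  fm.occ = INTEGER(occ);
  fm.ncp = occ.nrow();
  fm.occ_rate = occ_rate;
  fm.sa_vals = INTEGER(sa_vals);
  fm.sa_rate = sa_rate;
  return fm;
}

// [[Rcpp::export]]
IntegerVector fm_search_cpp(IntegerVector bwt, IntegerVector ctab,
                            IntegerMatrix occ, int occ_rate,
                            IntegerVector sa_vals, int sa_rate,
                            IntegerVector pattern) {
  FM fm = make_fm(bwt, ctab, occ, occ_rate, sa_vals, sa_rate);
  int sp, ep;
  std::vector<int> pat(pattern.begin(), pattern.end());
  if (!fm.search(pat.data(), (int)pat.size(), sp, ep)) { sp = 0; ep = 0; }
  return IntegerVector::create(sp, ep);
}

// [[Rcpp::export]]
IntegerVector sa_lookup_cpp(IntegerVector rows, IntegerVector bwt,
                            IntegerVector ctab, IntegerMatrix occ, int occ_rate,
                            IntegerVector sa_vals, int sa_rate) {
  FM fm = make_fm(bwt, ctab, occ, occ_rate, sa_vals, sa_rate);
  IntegerVector out(rows.size());
  for (int i = 0; i < rows.size(); ++i) out[i] = fm.locate(rows[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Semi-global unit-cost edit distance: the full read must be aligned; gaps at
// either end of the reference window are free. Tie-break preference when
// costs are equal is diagonal > up (read gap) > left (window gap), and the
// smallest window end position; this makes the reported span deterministic.
// Returns {distance, window_start, window_end} with a half-open span.
// ---------------------------------------------------------------------------

static void align_semiglobal(const int* r, int m, const int* w, int n,
                             std::vector<int>& D, std::vector<int>& S,
                             std::vector<int>& Dp, std::vector<int>& Sp,
                             int out[3]) {
  D.assign(n + 1, 0); S.assign(n + 1, 0);
  Dp.assign(n + 1, 0); Sp.assign(n + 1, 0);
  for (int j = 0; j <= n; ++j) { Dp[j] = 0; Sp[j] = j; }
  for (int i = 1; i <= m; ++i) {
    D[0] = i; S[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int best = Dp[j - 1] + (r[i - 1] != w[j - 1] ? 1 : 0);
      int src = Sp[j - 1];
      int up = Dp[j] + 1;
      if (up < best) { best = up; src = Sp[j]; }
      int left = D[j - 1] + 1;
      if (left < best) { best = left; src = S[j - 1]; }
      D[j] = best; S[j] = src;
    }
    std::swap(D, Dp); std::swap(S, Sp);
  }
  int bj = 0, bd = Dp[0];
  for (int j = 1; j <= n; ++j)
    if (Dp[j] < bd) { bd = Dp[j]; bj = j; }
  out[0] = bd; out[1] = Sp[bj]; out[2] = bj;
}

// [[Rcpp::export]]
IntegerVector align_semiglobal_cpp(IntegerVector read, IntegerVector window) {
  std::vector<int> D, S, Dp, Sp;
  int out[3];
  std::vector<int> r(read.begin(), read.end());
  std::vector<int> w(window.begin(), window.end());
  align_semiglobal(r.data(), (int)r.size(), w.data(), (int)w.size(),
                   D, S, Dp, Sp, out);
  return IntegerVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export]]
IntegerVector encode_read_cpp(std::string s, bool reverse_complement) {
  int L = (int)s.size();
  IntegerVector out(L);
  if (!reverse_complement) {
    for (int i = 0; i < L; ++i) out[i] = char_code(s[i]);
  } else {
    for (int i = 0; i < L; ++i) out[i] = comp_code(char_code(s[L - 1 - i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batched read assignment: seed extraction, FM lookup, diagonal clustering,
// candidate ordering, threshold-bounded alignment with per-taxon early stop.
// One call processes all reads against one chunk index; merging across
// chunks happens in R.
//
// Candidate regions are evaluated in descending seed-support order with
// deterministic tie-breaking (taxid, accession rank, projected start,
// strand). In early-stop mode a taxon is retired as soon as one passing
// alignment is recorded for it; the exhaustive mode (early_stop = FALSE)
// aligns every candidate and records every passing alignment, and exists to
// audit the early-stop equivalence property.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List assign_reads_cpp(IntegerVector text, IntegerVector bnd, IntegerVector mlen,
                      IntegerVector mtax, IntegerVector arank,
                      IntegerVector bwt, IntegerVector ctab, IntegerMatrix occ,
                      int occ_rate, IntegerVector sa_vals, int sa_rate,
                      CharacterVector reads,
                      int seed_len, int seed_interval, int min_seed_hits,
                      int diag_tol, int max_edits, int pad, bool early_stop) {
  FM fm = make_fm(bwt, ctab, occ, occ_rate, sa_vals, sa_rate);
  const int* txt = INTEGER(text);
  const int* B = INTEGER(bnd);
  const int nm = bnd.size();

  std::vector<int> out_read, out_member, out_strand, out_rs, out_re, out_ed;
  double align_calls = 0;
  std::vector<int> D, S, Dp, Sp;

  struct M { int member, strand, diag, roff; };
  struct Cand { int member, strand, proj, support, taxid, arank; };

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rs = as<std::string>(reads[ri]);
    const int L = (int)rs.size();
    if (L < seed_len) continue;

    std::vector<int> fc(L), rc(L);
    for (int i = 0; i < L; ++i) fc[i] = char_code(rs[i]);
    for (int i = 0; i < L; ++i) rc[i] = comp_code(fc[L - 1 - i]);

    // spaced seed schedule, plus a final seed flush with the read end
    std::vector<int> offs;
    for (int o = 0; o + seed_len <= L; o += seed_interval) offs.push_back(o);
    if (offs.empty() || offs.back() != L - seed_len) offs.push_back(L - seed_len);

    std::vector<M> ms;
    for (int st = 0; st < 2; ++st) {
      const std::vector<int>& codes = (st == 0) ? fc : rc;
      for (size_t oi = 0; oi < offs.size(); ++oi) {
        int o = offs[oi];
        bool clean = true;
        for (int j = o; j < o + seed_len; ++j)
          if (codes[j] == 5) { clean = false; break; }  // seeds with N never match
        if (!clean) continue;
        int sp, ep;
        if (!fm.search(codes.data() + o, seed_len, sp, ep)) continue;
        for (int row = sp; row < ep; ++row) {
          int pos = fm.locate(row);
          int mi = (int)(std::upper_bound(B, B + nm, pos) - B) - 1;
          ms.push_back({mi, st, pos - B[mi] - o, o});
        }
      }
    }
    if (ms.empty()) continue;

    std::sort(ms.begin(), ms.end(), [](const M& a, const M& b) {
      if (a.member != b.member) return a.member < b.member;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.roff < b.roff;
    });

    // greedy diagonal clustering anchored at the smallest diagonal in run
    std::vector<Cand> cands;
    size_t i0 = 0;
    while (i0 < ms.size()) {
      size_t j = i0 + 1;
      while (j < ms.size() && ms[j].member == ms[i0].member &&
             ms[j].strand == ms[i0].strand &&
             ms[j].diag - ms[i0].diag <= diag_tol)
        ++j;
      int support = (int)(j - i0);
      if (support >= min_seed_hits) {
        int mi = ms[i0].member;
        cands.push_back({mi, ms[i0].strand, ms[i0].diag, support,
                         mtax[mi], arank[mi]});
      }
      i0 = j;
    }
    if (cands.empty()) continue;

    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.support != b.support) return a.support > b.support;
      if (a.taxid != b.taxid) return a.taxid < b.taxid;
      if (a.arank != b.arank) return a.arank < b.arank;
      if (a.proj != b.proj) return a.proj < b.proj;
      return a.strand < b.strand;
    });

    std::set<int> done;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Cand& cd = cands[ci];
      if (early_stop && done.count(cd.taxid)) continue;
      int ws = cd.proj - pad;
      if (ws < 0) ws = 0;
      long we_l = (long)cd.proj + L + pad;
      int we = (we_l > mlen[cd.member]) ? mlen[cd.member] : (int)we_l;
      if (we <= ws) continue;
      const std::vector<int>& codes = (cd.strand == 0) ? fc : rc;
      int res[3];
      align_semiglobal(codes.data(), L, txt + B[cd.member] + ws, we - ws,
                       D, S, Dp, Sp, res);
      align_calls += 1;
      if (res[0] <= max_edits) {
        out_read.push_back(ri + 1);
        out_member.push_back(cd.member + 1);
        out_strand.push_back(cd.strand);
        out_rs.push_back(ws + res[1]);
        out_re.push_back(ws + res[2]);
        out_ed.push_back(res[0]);
        done.insert(cd.taxid);
      }
    }
  }

  return List::create(
      _["read"] = IntegerVector(out_read.begin(), out_read.end()),
      _["member"] = IntegerVector(out_member.begin(), out_member.end()),
      _["strand"] = IntegerVector(out_strand.begin(), out_strand.end()),
      _["ref_start"] = IntegerVector(out_rs.begin(), out_rs.end()),
      _["ref_end"] = IntegerVector(out_re.begin(), out_re.end()),
      _["edit_distance"] = IntegerVector(out_ed.begin(), out_ed.end()),
      _["align_calls"] = align_calls);
}
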