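#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <array>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Affine-gap Smith-Waterman of one short query against one target, with the
// running match count and alignment start carried along the optimal path so
// identity (matches / query length) is available without a traceback.
// Positions are 0-based half-open on the target. Columns whose index falls in
// [mask_s, mask_e) are excluded (used for the second-best non-overlapping hit).
struct SWHit {
  int score;
  int matches;
  int tstart; // 0-based inclusive
  int tend;   // 0-based exclusive
};

static SWHit sw_one(const char *q, int m, const char *t, int n,
                    int match, int mismatch, int gap_open, int gap_extend,
                    int mask_s, int mask_e) {
  // DP over query rows (m small), target columns (n large).
  std::vector<int> H(n + 1, 0), E(n + 1, 0), F(n + 1, 0);
  std::vector<int> HM(n + 1, 0), EM(n + 1, 0), FM(n + 1, 0); // match counts
  std::vector<int> HS(n + 1, 0), ES(n + 1, 0), FS(n + 1, 0); // alignment start
  SWHit best = {0, 0, 0, 0};
  for (int j = 0; j <= n; ++j) { HS[j] = j; ES[j] = j; FS[j] = j; }
  for (int i = 1; i <= m; ++i) {
    int diagH = H[0], diagM = HM[0], diagS = HS[0];
    H[0] = 0; HM[0] = 0; HS[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int curH = H[j], curM = HM[j], curS = HS[j];
      if (j - 1 >= mask_s && j - 1 < mask_e) {
        // masked column: nothing may align to this target base
        H[j] = 0; HM[j] = 0; HS[j] = j;
        E[j] = 0; EM[j] = 0; ES[j] = j;
        F[j] = 0; FM[j] = 0; FS[j] = j;
        diagH = curH; diagM = curM; diagS = curS;
        continue;
      }
      char tc = t[j - 1], qc = q[i - 1];
      bool is_match = (tc == qc) && tc != 'N';
      int sub = is_match ? match : mismatch;
      // E: gap in query (skip target base), horizontal within the row
      int e_open = H[j - 1] - gap_open, e_ext = E[j - 1] - gap_extend;
      if (e_open >= e_ext) { E[j] = e_open; EM[j] = HM[j - 1]; ES[j] = HS[j - 1]; }
      else                 { E[j] = e_ext;  EM[j] = EM[j - 1]; ES[j] = ES[j - 1]; }
      // F: gap in target (skip query base), vertical from the previous row
      int f_open = curH - gap_open, f_ext = F[j] - gap_extend;
      if (f_open >= f_ext) { F[j] = f_open; FM[j] = curM; FS[j] = curS; }
      else                 { F[j] = f_ext; /* FM[j], FS[j] carried */ }
      // H
      int d = diagH + sub;
      int h = d, hm = diagM + (is_match ? 1 : 0), hs = diagS;
      if (E[j] > h) { h = E[j]; hm = EM[j]; hs = ES[j]; }
      if (F[j] > h) { h = F[j]; hm = FM[j]; hs = FS[j]; }
      if (h <= 0)   { h = 0;    hm = 0;     hs = j;     }
      H[j] = h; HM[j] = hm; HS[j] = hs;
      if (h > best.score || (h == best.score && hm > best.matches)) {
        best.score = h; best.matches = hm; best.tstart = hs; best.tend = j;
      }
      diagH = curH; diagM = curM; diagS = curS;
    }
  }
  return best;
}

// Lean score-only scan: best local alignment score and end column. The
// rich bookkeeping (start, match count) is recovered afterwards by
// re-running the full DP on a short window ending at the best end.
struct LeanHit { int score; int tend; };

// colmax (optional, length n + 1): best local alignment score ending at
// each target column, used to find non-overlapping secondary hits
// without a second full scan
static LeanHit sw_lean(const char *q, int m, const char *t, int n,
                       int match, int mismatch, int gap_open,
                       int gap_extend, int mask_s, int mask_e,
                       int *colmax = nullptr) {
  // target encoded once; per-row score profile removes the per-cell
  // character comparison; E (horizontal gap) lives in a register
  std::vector<unsigned char> tc(n);
  for (int j = 0; j < n; ++j) {
    switch (t[j]) {
      case 'A': tc[j] = 0; break; case 'C': tc[j] = 1; break;
      case 'G': tc[j] = 2; break; case 'T': tc[j] = 3; break;
      default: tc[j] = 4; break;
    }
  }
  if (mask_s >= 0)
    for (int j = std::max(0, mask_s); j < std::min(n, mask_e); ++j)
      tc[j] = 5; // masked columns scored as hard mismatch + forced zero
  std::vector<int> H(n + 1, 0), F(n + 1, 0);
  LeanHit best = {0, 0};
  int prof[6];
  for (int i = 1; i <= m; ++i) {
    const char qc = q[i - 1];
    prof[0] = (qc == 'A') ? match : mismatch;
    prof[1] = (qc == 'C') ? match : mismatch;
    prof[2] = (qc == 'G') ? match : mismatch;
    prof[3] = (qc == 'T') ? match : mismatch;
    prof[4] = mismatch;
    prof[5] = mismatch;
    int diag = H[0];
    int e = 0, hleft = 0;
    int bscore = best.score, bend = best.tend;
    for (int j = 1; j <= n; ++j) {
      const int cur = H[j];
      const unsigned char c = tc[j - 1];
      e = std::max(hleft - gap_open, e - gap_extend);
      const int f = std::max(cur - gap_open, F[j] - gap_extend);
      int h = diag + prof[c];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0 || c == 5) h = 0;
      if (c == 5) e = 0;
      F[j] = (c == 5) ? 0 : f;
      H[j] = h;
      hleft = h;
      if (h > bscore) { bscore = h; bend = j; }
      if (colmax && h > colmax[j]) colmax[j] = h;
      diag = cur;
    }
    best.score = bscore; best.tend = bend;
  }
  return best;
}

// recover start/matches of the best alignment ending at `tend` by rich
// DP on a window; window is generous (4 m + 16) so the start is inside
static SWHit refine_hit(const char *q, int m, const char *t, int n,
                        int match, int mismatch, int gap_open,
                        int gap_extend, int tend, int mask_s, int mask_e) {
  int w0 = std::max(0, tend - (4 * m + 16));
  int ms = (mask_s >= 0) ? std::max(-1, mask_s - w0) : -1;
  int me = (mask_e >= 0) ? std::max(-1, mask_e - w0) : -1;
  SWHit h = sw_one(q, m, t + w0, tend - w0, match, mismatch,
                   gap_open, gap_extend, ms, me);
  h.tstart += w0;
  h.tend += w0;
  return h;
}

// --- exact k-mer seeding (k = 11) --------------------------------------
// Sorted (kmer, position) index of a target; lookups drive both the
// strand pre-filter and the windowed DP around candidate diagonals, so
// full-read DP is only a fallback for seedless queries.
static const int SEED_K = 11;

static inline bool pack_kmer(const char *s, uint32_t &out) {
  uint32_t v = 0;
  for (int i = 0; i < SEED_K; ++i) {
    uint32_t c;
    switch (s[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: return false;
    }
    v = (v << 2) | c;
  }
  out = v;
  return true;
}

static void kmer_index(const std::string &t,
                       std::vector<std::pair<uint32_t, int>> &idx) {
  idx.clear();
  int n = (int)t.size();
  for (int p = 0; p + SEED_K <= n; ++p) {
    uint32_t v;
    if (pack_kmer(t.c_str() + p, v)) idx.push_back({v, p});
  }
  std::sort(idx.begin(), idx.end());
}

// all target positions of exact seed matches of query q
static void seed_positions(const std::vector<std::pair<uint32_t, int>> &idx,
                           const std::string &q, std::vector<int> &diags) {
  diags.clear();
  int m = (int)q.size();
  for (int qo = 0; qo + SEED_K <= m; ++qo) {
    uint32_t v;
    if (!pack_kmer(q.c_str() + qo, v)) continue;
    auto lo = std::lower_bound(idx.begin(), idx.end(),
                               std::make_pair(v, -1));
    for (auto it = lo; it != idx.end() && it->first == v; ++it)
      diags.push_back(it->second - qo);
  }
  std::sort(diags.begin(), diags.end());
}

//' @noRd
// [[Rcpp::export(name = ".sw_scan")]]
List sw_scan(CharacterVector targets, CharacterVector queries,
             int match = 2, int mismatch = -2,
             int gap_open = 3, int gap_extend = 1,
             double min_identity = 0.75, double score_margin = 0.9,
             Nullable<IntegerVector> query_strand = R_NilValue) {
  int R = targets.size(), Q = queries.size();
  IntegerMatrix score(R, Q), matches(R, Q), tstart(R, Q), tend(R, Q);
  IntegerMatrix score2(R, Q), matches2(R, Q);
  std::vector<std::string> qs(Q);
  for (int k = 0; k < Q; ++k) qs[k] = as<std::string>(queries[k]);
  // optional strand pre-filter: when every query of one strand group has
  // an exact seed and the other group has none, only that group is
  // scanned (reads are one strand; spurious other-strand hits are noise)
  std::vector<int> qstr(Q, 0);
  bool use_filter = false;
  if (query_strand.isNotNull()) {
    IntegerVector qsv(query_strand);
    if (qsv.size() == Q) {
      use_filter = true;
      for (int k = 0; k < Q; ++k) qstr[k] = qsv[k];
    }
  }
  std::vector<int> colmax;
  std::vector<std::pair<uint32_t, int>> kidx;
  std::vector<int> diags;
  for (int r = 0; r < R; ++r) {
    std::string tg = as<std::string>(targets[r]);
    const char *t = tg.c_str();
    int n = (int)tg.size();
    kmer_index(tg, kidx);
    bool scan_strand[2] = {true, true};
    if (use_filter && n > 0) {
      bool found[2] = {false, false};
      for (int k = 0; k < Q; ++k) {
        if (found[qstr[k]]) continue;
        seed_positions(kidx, qs[k], diags);
        if (!diags.empty()) found[qstr[k]] = true;
      }
      if (found[0] != found[1]) {
        scan_strand[0] = found[0];
        scan_strand[1] = found[1];
      }
    }
    for (int k = 0; k < Q; ++k) {
      int m = (int)qs[k].size();
      if (m == 0 || n == 0 || !scan_strand[qstr[k]]) continue;
      const char *q = qs[k].c_str();
      // seeded path: windowed DP around clustered seed diagonals
      bool seeded_ok = false;
      if (m >= SEED_K) {
        seed_positions(kidx, qs[k], diags);
        if (!diags.empty()) {
          std::vector<SWHit> hits;
          bool cluster_skipped = false;
          size_t i0 = 0;
          while (i0 < diags.size()) {
            size_t i1 = i0;
            while (i1 + 1 < diags.size() &&
                   diags[i1 + 1] - diags[i1] <= 16) ++i1;
            // symmetric slack so results mirror exactly under reverse
            // complement of the read
            int w0 = std::max(0, diags[i0] - 16);
            int w1 = std::min(n, diags[i1] + m + 16);
            if (w1 - w0 <= 6 * m + 64) {
              SWHit h = sw_one(q, m, t + w0, w1 - w0, match, mismatch,
                               gap_open, gap_extend, -1, -1);
              h.tstart += w0; h.tend += w0;
              if (h.score > 0) hits.push_back(h);
            } else cluster_skipped = true; // repetitive: use the full scan
            i0 = i1 + 1;
          }
          if (!hits.empty() && !cluster_skipped) {
            size_t bi = 0;
            for (size_t h = 1; h < hits.size(); ++h)
              if (hits[h].score > hits[bi].score ||
                  (hits[h].score == hits[bi].score &&
                   hits[h].matches > hits[bi].matches)) bi = h;
            SWHit b = hits[bi];
            if ((double)b.matches / m >= min_identity) {
              seeded_ok = true;
              score(r, k) = b.score; matches(r, k) = b.matches;
              tstart(r, k) = b.tstart; tend(r, k) = b.tend;
              // secondary: best disjoint cluster hit at the margin
              int need = (int)std::ceil(score_margin * b.score);
              int s2 = 0, m2 = 0;
              for (size_t h = 0; h < hits.size(); ++h) {
                if (h == bi) continue;
                const SWHit &x = hits[h];
                bool disjoint = x.tend <= b.tstart || x.tstart >= b.tend;
                if (disjoint && x.score >= need && x.score > s2) {
                  s2 = x.score; m2 = x.matches;
                }
              }
              score2(r, k) = s2; matches2(r, k) = m2;
            }
          }
        }
      }
      if (seeded_ok) continue;
      // fallback: full lean scan with column-max secondary tracking
      colmax.assign(n + 1, 0);
      LeanHit lb = sw_lean(q, m, t, n, match, mismatch,
                           gap_open, gap_extend, -1, -1, colmax.data());
      if (lb.score <= 0) continue;
      SWHit b = refine_hit(q, m, t, n, match, mismatch,
                           gap_open, gap_extend, lb.tend, -1, -1);
      score(r, k) = b.score; matches(r, k) = b.matches;
      tstart(r, k) = b.tstart; tend(r, k) = b.tend;
      // secondary non-overlapping hit (ambiguity check): only candidates
      // whose column-max score could reach the ambiguity margin, ending
      // clearly outside the best interval, are refined
      if ((double)b.matches / m >= min_identity && b.tend > b.tstart) {
        int need = (int)std::ceil(score_margin * b.score);
        int right0 = b.tend + (3 * m) / 4;
        int cand = -1, cand_score = 0;
        for (int j = 1; j <= std::min(b.tstart, n); ++j)
          if (colmax[j] >= need && colmax[j] > cand_score) {
            cand_score = colmax[j]; cand = j;
          }
        for (int j = right0 + 1; j <= n; ++j)
          if (colmax[j] >= need && colmax[j] > cand_score) {
            cand_score = colmax[j]; cand = j;
          }
        if (cand > 0) {
          SWHit s = refine_hit(q, m, t, n, match, mismatch,
                               gap_open, gap_extend, cand,
                               b.tstart, b.tend);
          score2(r, k) = s.score; matches2(r, k) = s.matches;
        }
      }
    }
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["start"] = tstart, _["end"] = tend,
                      _["score2"] = score2, _["matches2"] = matches2);
}

// Banded Levenshtein distance with early exit once the running band minimum
// exceeds k; returns k + 1 when the true distance exceeds k.
static int banded_lev(const std::string &a, const std::string &b, int k) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > k) return k + 1;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - k), hi = std::min(m, i + k);
    cur[lo - 1] = (lo - 1 == 0) ? i : k + 1;
    int rowmin = cur[lo - 1];
    for (int j = lo; j <= hi; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = (j <= i + k - 1) ? prev[j] + 1 : k + 1;
      int left = (j >= lo + 1 || lo - 1 == 0) ? cur[j - 1] + 1 : k + 1;
      int v = std::min(d, std::min(up, left));
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  int res = prev[m];
  return res > k ? k + 1 : res;
}

static void char_counts(const std::string &s, int *c) {
  std::memset(c, 0, 5 * sizeof(int));
  for (char ch : s) {
    switch (ch) {
      case 'A': c[0]++; break; case 'C': c[1]++; break;
      case 'G': c[2]++; break; case 'T': c[3]++; break;
      default: c[4]++; break;
    }
  }
}

static inline bool counts_compatible(const int *x, const int *y, int k) {
  // sum of positive differences is a lower bound on edit distance
  int pos = 0, neg = 0;
  for (int i = 0; i < 5; ++i) {
    int d = x[i] - y[i];
    if (d > 0) pos += d; else neg -= d;
  }
  return std::max(pos, neg) <= k;
}

//' @noRd
// [[Rcpp::export(name = ".close_pairs")]]
DataFrame close_pairs(CharacterVector x, int maxdist) {
  int n = x.size();
  std::vector<std::string> s(n);
  std::vector<std::array<int, 5>> cc(n);
  bool equal_len = true;
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(x[i]);
    char_counts(s[i], cc[i].data());
    if (s[i].size() != s[0].size()) equal_len = false;
  }
  std::vector<int> ii, jj, dd;
  int len = n ? (int)s[0].size() : 0;
  int k = maxdist;
  int cl = (k >= 0) ? len / (k + 1) : 0;
  if (n >= 3000 && equal_len && k >= 1 && cl >= 4) {
    // pigeonhole bucketing: with <= k edits, at least one of the k+1
    // chunks of one string appears exactly in the other, shifted by at
    // most k; candidates from shared (chunk, sequence) keys, verified
    // with the banded DP
    std::unordered_map<std::string, std::vector<int>> base;
    base.reserve(n * (k + 1) * 2);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c <= k; ++c) {
        std::string key(1, (char)('0' + c));
        key += s[i].substr(c * cl, cl);
        base[key].push_back(i);
      }
    std::vector<long long> cand;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c <= k; ++c) {
        for (int sh = -k; sh <= k; ++sh) {
          int pos = c * cl + sh;
          if (pos < 0 || pos + cl > len) continue;
          std::string key(1, (char)('0' + c));
          key += s[i].substr(pos, cl);
          auto it = base.find(key);
          if (it == base.end()) continue;
          for (int j : it->second)
            if (j != i) {
              int a = std::min(i, j), b = std::max(i, j);
              cand.push_back((long long)a * n + b);
            }
        }
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (long long p : cand) {
      int i = (int)(p / n), j = (int)(p % n);
      if (!counts_compatible(cc[i].data(), cc[j].data(), maxdist)) continue;
      int d = banded_lev(s[i], s[j], maxdist);
      if (d <= maxdist) {
        ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d);
      }
    }
  } else {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (!counts_compatible(cc[i].data(), cc[j].data(), maxdist)) continue;
        int d = banded_lev(s[i], s[j], maxdist);
        if (d <= maxdist) {
          ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d);
        }
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

//' @noRd
// [[Rcpp::export(name = ".has_close_in")]]
LogicalVector has_close_in(CharacterVector x, CharacterVector ref, int maxdist) {
  int n = x.size(), m = ref.size();
  std::vector<std::string> rs(m);
  std::vector<std::array<int, 5>> rc(m);
  for (int j = 0; j < m; ++j) {
    rs[j] = as<std::string>(ref[j]);
    char_counts(rs[j], rc[j].data());
  }
  LogicalVector out(n, false);
  for (int i = 0; i < n; ++i) {
    std::string si = as<std::string>(x[i]);
    int ci[5]; char_counts(si, ci);
    for (int j = 0; j < m; ++j) {
      if (!counts_compatible(ci, rc[j].data(), maxdist)) continue;
      if (banded_lev(si, rs[j], maxdist) <= maxdist) { out[i] = true; break; }
    }
  }
  return out;
}
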