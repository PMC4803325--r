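#include <Rcpp.h>
#include <cstring>
#include <limits>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Affine-gap pairwise alignment and support routines.
//
// Conventions shared by every function here:
//  * sequences arrive as std::string over {A,C,G,T,N} (uppercase);
//  * a gap run of length L costs gap_open + L * gap_extend (both <= 0);
//  * 'N' never scores as a match;
//  * all reported coordinates are 0-based half-open.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

// Banded Gotoh alignment, pinned at (0,0).
//
// The band is centred on the interpolated diagonal j ~ i*n/m so that
// length-mismatched pairs stay inside it.  With free_end = true the
// alignment may end on the last row or last column wherever the score is
// maximal (trailing gaps in either sequence are free); otherwise it ends
// at (m, n).  Returns aligned strings for the aligned region, the end
// coordinates, and whether the optimal path touched the band boundary
// (the R wrapper reacts by doubling the band).
//
// Layer codes: 0 = M (diagonal), 1 = X (gap in b, consumes a),
// 2 = Y (gap in a, consumes b).
// [[Rcpp::export]]
List cpp_align_pinned(std::string a, std::string b,
                      int match, int mismatch,
                      int gap_open, int gap_extend,
                      int band, bool free_end) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0)
    stop("cpp_align_pinned: empty sequence");
  if (band < 1) stop("cpp_align_pinned: band must be >= 1");

  const int w = 2 * band + 1;
  // Column range for row i.  End-anchored (global) alignments band around
  // the corner-to-corner diagonal; free-end alignments are pinned only at
  // the start, so the path tracks the main diagonal j = i and the band
  // must follow it.
  std::vector<int> lo(m + 1), hi(m + 1);
  for (int i = 0; i <= m; ++i) {
    int center = free_end ? std::min(i, n) : (int)((long long)i * n / m);
    lo[i] = std::max(0, center - band);
    hi[i] = std::min(n, center + band);
  }

  // Rolling score rows per layer; full (banded) traceback pointers.
  std::vector<int> Mprev(w, NEG_INF), Xprev(w, NEG_INF), Yprev(w, NEG_INF);
  std::vector<int> Mcur(w, NEG_INF), Xcur(w, NEG_INF), Ycur(w, NEG_INF);
  // ptr[layer][i*w + off]: predecessor layer, or -1 when unset.
  std::vector<signed char> ptrM((size_t)(m + 1) * w, -1);
  std::vector<signed char> ptrX((size_t)(m + 1) * w, -1);
  std::vector<signed char> ptrY((size_t)(m + 1) * w, -1);

  auto off = [&](int i, int j) { return j - lo[i]; };

  // Row 0: leading gaps in a (layer Y) are charged.
  for (int j = lo[0]; j <= hi[0]; ++j) {
    int o = off(0, j);
    if (j == 0) {
      Mprev[o] = 0;
    } else {
      Yprev[o] = gap_open + gap_extend * j;
      ptrY[o] = (j == 1) ? 0 : 2;
    }
  }

  int best_score = NEG_INF, best_i = -1, best_j = -1, best_layer = 0;

  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    const char ai = a[i - 1];
    for (int j = lo[i]; j <= hi[i]; ++j) {
      const int o = off(i, j);
      // X: vertical, from row i-1 same j.
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        const int po = j - lo[i - 1];
        int sM = Mprev[po] + gap_open + gap_extend;
        int sX = Xprev[po] + gap_extend;
        int sY = Yprev[po] + gap_open + gap_extend;
        int best = sM; signed char pl = 0;
        if (sX > best) { best = sX; pl = 1; }
        if (sY > best) { best = sY; pl = 2; }
        if (best > NEG_INF / 2) { Xcur[o] = best; ptrX[(size_t)i * w + o] = pl; }
      }
      // M: diagonal, from (i-1, j-1).
      if (j >= 1 && (j - 1) >= lo[i - 1] && (j - 1) <= hi[i - 1]) {
        const int po = (j - 1) - lo[i - 1];
        int s = subst(ai, b[j - 1], match, mismatch);
        int best = Mprev[po]; signed char pl = 0;
        if (Xprev[po] > best) { best = Xprev[po]; pl = 1; }
        if (Yprev[po] > best) { best = Yprev[po]; pl = 2; }
        if (best > NEG_INF / 2) { Mcur[o] = best + s; ptrM[(size_t)i * w + o] = pl; }
      }
      // Y: horizontal, from (i, j-1).
      if (j - 1 >= lo[i]) {
        const int po = o - 1;
        int sM = Mcur[po] + gap_open + gap_extend;
        int sX = Xcur[po] + gap_open + gap_extend;
        int sY = Ycur[po] + gap_extend;
        int best = sM; signed char pl = 0;
        if (sX > best) { best = sX; pl = 1; }
        if (sY > best) { best = sY; pl = 2; }
        if (best > NEG_INF / 2) { Ycur[o] = best; ptrY[(size_t)i * w + o] = pl; }
      }
      // Candidate endpoints.
      bool endpoint = free_end ? (i == m || j == n) : (i == m && j == n);
      if (endpoint) {
        int sc = Mcur[o]; int ly = 0;
        if (Xcur[o] > sc) { sc = Xcur[o]; ly = 1; }
        if (Ycur[o] > sc) { sc = Ycur[o]; ly = 2; }
        if (sc > best_score) {
          best_score = sc; best_i = i; best_j = j; best_layer = ly;
        }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best_i < 0 || best_score <= NEG_INF / 2)
    stop("cpp_align_pinned: no endpoint reachable inside band");

  // Traceback.
  std::string aa, ab;
  aa.reserve(m + n); ab.reserve(m + n);
  int i = best_i, j = best_j, layer = best_layer;
  bool band_hit = false;
  while (i > 0 || j > 0) {
    if ((j == lo[i] && lo[i] > 0) || (j == hi[i] && hi[i] < n)) band_hit = true;
    signed char pl;
    if (layer == 0) {
      pl = ptrM[(size_t)i * w + off(i, j)];
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]);
      --i; --j;
    } else if (layer == 1) {
      pl = ptrX[(size_t)i * w + off(i, j)];
      aa.push_back(a[i - 1]); ab.push_back('-');
      --i;
    } else {
      pl = ptrY[(size_t)i * w + off(i, j)];
      aa.push_back('-'); ab.push_back(b[j - 1]);
      --j;
    }
    if (pl < 0) {
      if (i == 0 && j == 0) break;
      stop("cpp_align_pinned: traceback lost (internal error)");
    }
    layer = pl;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());

  return List::create(
    _["aligned_a"] = aa, _["aligned_b"] = ab,
    _["score"] = best_score,
    _["a_end"] = best_i, _["b_end"] = best_j,
    _["band_hit"] = band_hit);
}

// Smith-Waterman local alignment with affine gaps, full matrix over
// query x target window.  Returns the single best hit with match/column
// counts from the traceback.
// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string t,
                     int match, int mismatch,
                     int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)t.size();
  if (m == 0 || n == 0)
    return List::create(_["found"] = false);

  const size_t sz = (size_t)(m + 1) * (n + 1);
  // rolling score rows; full byte traceback matrices
  std::vector<int> Mp(n + 1, 0), Xp(n + 1, NEG_INF), Yp(n + 1, NEG_INF);
  std::vector<int> Mc(n + 1, 0), Xc(n + 1, NEG_INF), Yc(n + 1, NEG_INF);
  // ptr codes: 0 stop, 1 diag(M), 2 up(X), 3 left(Y); per layer.
  std::vector<signed char> pM(sz, 0), pX(sz, 0), pY(sz, 0);
  auto idx = [&](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    Mc[0] = 0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    const char qi = q[i - 1];
    const size_t rowoff = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      const size_t c = rowoff + j;
      int vUp = Mp[j] + gap_open + gap_extend;
      int sX = std::max(vUp, Xp[j] + gap_extend);
      Xc[j] = sX;
      if (sX > NEG_INF / 2) pX[c] = (vUp >= Xp[j] + gap_extend) ? 1 : 2;
      int vLf = Mc[j - 1] + gap_open + gap_extend;
      int sY = std::max(vLf, Yc[j - 1] + gap_extend);
      Yc[j] = sY;
      if (sY > NEG_INF / 2) pY[c] = (vLf >= Yc[j - 1] + gap_extend) ? 1 : 3;
      int s = subst(qi, t[j - 1], match, mismatch);
      int dbest = Mp[j - 1]; signed char dl = 1;
      if (Xp[j - 1] > dbest) { dbest = Xp[j - 1]; dl = 2; }
      if (Yp[j - 1] > dbest) { dbest = Yp[j - 1]; dl = 3; }
      int sM = dbest + s;
      if (sM < 0) { Mc[j] = 0; pM[c] = 0; }
      else { Mc[j] = sM; pM[c] = dl; }
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (best <= 0)
    return List::create(_["found"] = false);

  // Traceback from (bi, bj) in layer M.
  int i = bi, j = bj, layer = 1; // 1=M, 2=X, 3=Y
  int matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    const size_t c = idx(i, j);
    signed char p;
    if (layer == 1) {
      p = pM[c];
      if (p == 0) break;
      ++columns;
      if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (layer == 2) {
      p = pX[c]; ++columns; --i;
    } else {
      p = pY[c]; ++columns; --j;
    }
    layer = p;
    if (layer == 0) break;
  }
  return List::create(
    _["found"] = true,
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,
    _["t_start"] = j, _["t_end"] = bj,
    _["matches"] = matches, _["columns"] = columns);
}

// Exact k-mer seed matches between query and target (forward strands of
// both).  2-bit encoding; k-mers containing N are skipped.  Returns an
// integer matrix with columns (q_pos, t_pos), 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_hits(std::string q, std::string t, int k) {
  if (k < 4 || k > 31) stop("cpp_seed_hits: k must be in [4, 31]");
  const int m = (int)q.size(), n = (int)t.size();
  std::vector<std::pair<int, int> > out;
  if (m < k || n < k) return IntegerMatrix(0, 2);

  auto code = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return -1;
    }
  };
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_multimap<uint64_t, int> qmap;
  qmap.reserve(m);
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < m; ++i) {
      int c = code(q[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) qmap.emplace(h, i - k + 1);
    }
  }
  {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int c = code(t[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto rng = qmap.equal_range(h);
        for (auto it = rng.first; it != rng.second; ++it)
          out.emplace_back(it->second, j - k + 1);
      }
    }
  }
  IntegerMatrix res((int)out.size(), 2);
  for (int r = 0; r < (int)out.size(); ++r) {
    res(r, 0) = out[r].first;
    res(r, 1) = out[r].second;
  }
  return res;
}

// Unit-cost edit distance with adaptive band doubling (Ukkonen): a path
// of cost <= k never strays more than k off the main diagonal, so the
// band |i - j| <= k is exact once the returned distance is <= k.
// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0) return n;
  if (n == 0) return m;

  int k = std::max(64, std::abs(m - n) + 1);
  for (;;) {
    const int w = 2 * k + 1;
    const int BIG = NEG_INF * -1; // large positive
    std::vector<int> prev(w, BIG), cur(w, BIG);
    // row i covers j in [i-k, i+k]; offset o = j - (i - k).
    for (int j = 0; j <= std::min(n, k); ++j) prev[j + k] = j;
    for (int i = 1; i <= m; ++i) {
      std::fill(cur.begin(), cur.end(), BIG);
      int jlo = std::max(0, i - k), jhi = std::min(n, i + k);
      for (int j = jlo; j <= jhi; ++j) {
        int o = j - (i - k);
        int v = BIG;
        if (j == 0) v = i;
        else {
          int dg = prev[o]; // (i-1, j-1): offset in prev row = j-1 - (i-1-k) = o
          if (dg < BIG) v = dg + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (o + 1 < w && prev[o + 1] < BIG) v = std::min(v, prev[o + 1] + 1); // del a[i-1]
          if (o - 1 >= 0 && cur[o - 1] < BIG) v = std::min(v, cur[o - 1] + 1);  // ins b[j-1]
        }
        cur[o] = v;
      }
      std::swap(prev, cur);
    }
    int o = n - (m - k);
    int d = (o >= 0 && o < w) ? prev[o] : BIG;
    if (d <= k) return d;
    if (k >= std::max(m, n)) return d; // cannot shrink further
    k *= 2;
  }
}

// Window dot plot: (i, j) reported when a[i, i+window) and b[j, j+window)
// agree at >= min_matches positions.  Brute force by definition.
// [[Rcpp::export]]
IntegerMatrix cpp_dotplot(std::string a, std::string b,
                          int window, int min_matches) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<std::pair<int, int> > out;
  for (int i = 0; i + window <= m; ++i) {
    for (int j = 0; j + window <= n; ++j) {
      int mm = 0;
      for (int u = 0; u < window; ++u)
        if (a[i + u] == b[j + u] && a[i + u] != 'N') ++mm;
      if (mm >= min_matches) out.emplace_back(i, j);
    }
  }
  IntegerMatrix res((int)out.size(), 2);
  for (int r = 0; r < (int)out.size(); ++r) {
    res(r, 0) = out[r].first;
    res(r, 1) = out[r].second;
  }
  return res;
}
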