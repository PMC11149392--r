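// Affine-gap global alignment (Gotoh) for the built-in HSP engine.
// Scoring: match/mismatch over {A,C,G,T}, N scored neutrally (0 against
// anything), a gap of length L costs open + ext * L, end gaps penalized.
//
// The DP is banded on the diagonal offset i - j with iterative band
// doubling. A banded result is accepted only when it is provably optimal:
// any path leaving the band must spend at least |n-m| + 2(w+1) gap
// characters, so its score is at most
//   2 * min(n, m) - open - ext * (|n-m| + 2w + 2);
// once the banded score reaches that bound, no out-of-band path can beat
// it. Otherwise the band is doubled, up to the full matrix, so results are
// always exact.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -1e30;

static inline int encode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N or anything else: neutral
  }
}

struct AlnStats {
  double score;
  int nident, length, gaps;
};

// Traceback codes packed per cell: 2 bits each for M, X, Y predecessors.
static inline uint8_t pack_tb(int m, int x, int y) {
  return (uint8_t)(m | (x << 2) | (y << 4));
}

// Banded Gotoh. Band: i - j in [lo, hi] (must contain 0 and n - m).
// Returns false if the (finite) end cell is unreachable within the band.
static bool gotoh_banded(const std::vector<int>& ea, const std::vector<int>& eb,
                         double match, double mismatch, double open, double ext,
                         int lo, int hi, AlnStats* out) {
  const int n = (int)ea.size(), m = (int)eb.size();
  const int B = hi - lo + 1;  // band width in diagonals
  // row i stores j in [max(0, i - hi), min(m, i - lo)]; index by d = i - j,
  // column slot = hi - d in [0, B)
  std::vector<double> M((size_t)(n + 1) * B, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * B, NEG_INF);
  std::vector<double> Y((size_t)(n + 1) * B, NEG_INF);
  std::vector<uint8_t> TB((size_t)(n + 1) * B, 0);

  auto slot = [&](int i, int j) -> size_t {
    return (size_t)i * B + (hi - (i - j));
  };

  M[slot(0, 0)] = 0.0;
  for (int j = 1; j <= m && -j >= lo; ++j) Y[slot(0, j)] = -open - ext * j;
  for (int i = 1; i <= n && i <= hi; ++i) X[slot(i, 0)] = -open - ext * i;

  for (int i = 1; i <= n; ++i) {
    int jmin = i - hi; if (jmin < 1) jmin = 1;
    int jmax = i - lo; if (jmax > m) jmax = m;
    const size_t ro = (size_t)i * B, rp = (size_t)(i - 1) * B;
    for (int j = jmin; j <= jmax; ++j) {
      const int col = hi - (i - j);       // this cell in row i
      // (i-1, j-1) is the same diagonal: same col in row i-1
      // (i-1, j)   is diagonal d+... i-1-j = d-1 -> col+1
      // (i,   j-1) is d+1 -> col-1
      double s = (ea[i - 1] == 4 || eb[j - 1] == 4) ? 0.0
                 : (ea[i - 1] == eb[j - 1] ? match : mismatch);
      int tm = 0, tx = 0, ty = 0;

      double diagM = M[rp + col], diagX = X[rp + col], diagY = Y[rp + col];
      double bestd = diagM;
      if (diagX > bestd) { bestd = diagX; tm = 1; }
      if (diagY > bestd) { bestd = diagY; tm = 2; }
      double Mv = (bestd <= NEG_INF / 2) ? NEG_INF : bestd + s;

      double Xv = NEG_INF;
      if (col + 1 < B) {  // (i-1, j) inside band
        double xo = M[rp + col + 1] - open - ext, xe = X[rp + col + 1] - ext;
        if (xo >= xe) { Xv = xo; tx = 0; } else { Xv = xe; tx = 1; }
      }
      double Yv = NEG_INF;
      if (col - 1 >= 0) {  // (i, j-1) inside band
        double yo = M[ro + col - 1] - open - ext, ye = Y[ro + col - 1] - ext;
        if (yo >= ye) { Yv = yo; ty = 0; } else { Yv = ye; ty = 2; }
      }
      M[ro + col] = Mv;
      X[ro + col] = Xv;
      Y[ro + col] = Yv;
      TB[ro + col] = pack_tb(tm, tx, ty);
    }
  }

  const size_t end = slot(n, m);
  int cur = 0;
  double sc = M[end];
  if (X[end] > sc) { sc = X[end]; cur = 1; }
  if (Y[end] > sc) { sc = Y[end]; cur = 2; }
  if (sc <= NEG_INF / 2) return false;

  AlnStats st; st.score = sc; st.nident = 0; st.length = 0; st.gaps = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    st.length++;
    if (i == 0) { st.gaps++; --j; continue; }   // leading gap row
    if (j == 0) { st.gaps++; --i; continue; }
    uint8_t tb = TB[slot(i, j)];
    if (cur == 0) {
      if (ea[i - 1] == eb[j - 1]) st.nident++;
      cur = tb & 3;
      --i; --j;
    } else if (cur == 1) {
      st.gaps++;
      cur = (tb >> 2) & 3;
      --i;
    } else {
      st.gaps++;
      cur = (tb >> 4) & 3;
      --j;
    }
  }
  *out = st;
  return true;
}

static AlnStats align_pair(const std::string& a, const std::string& b,
                           double match, double mismatch,
                           double open, double ext) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) ea[i] = encode(a[i]);
  for (int j = 0; j < m; ++j) eb[j] = encode(b[j]);
  const int d = n - m;
  const int minlen = n < m ? n : m;
  const int absd = d < 0 ? -d : d;
  int w = 16;
  AlnStats st;
  for (;;) {
    int lo = (d < 0 ? d : 0) - w;
    int hi = (d > 0 ? d : 0) + w;
    // once a band pass costs about as much as the full matrix, just do it
    bool full = 2 * (hi - lo + 1) >= (n + m + 1);
    if (full) { lo = -m; hi = n; }
    bool ok = gotoh_banded(ea, eb, match, mismatch, open, ext, lo, hi, &st);
    if (full) break;
    if (ok) {
      // an out-of-band path aligns at most min(n, m) pairs (gain <= match
      // each) and pays for at least |n-m| + 2(w+1) gap characters
      double bound = match * minlen - open - ext * (absd + 2.0 * (w + 1));
      if (st.score >= bound) break;
    }
    w *= 4;
  }
  return st;
}

// [[Rcpp::export(name = ".gotoh_align_stats")]]
DataFrame gotoh_align_stats(CharacterVector query, CharacterVector subject,
                            double match = 2.0, double mismatch = -3.0,
                            double gap_open = 5.0, double gap_ext = 2.0) {
  const int k = query.size();
  if (subject.size() != k) stop("query and subject must have equal length");
  IntegerVector nident(k), length(k), gaps(k);
  NumericVector score(k);
  for (int r = 0; r < k; ++r) {
    AlnStats st = align_pair(as<std::string>(query[r]),
                             as<std::string>(subject[r]),
                             match, mismatch, gap_open, gap_ext);
    nident[r] = st.nident; length[r] = st.length;
    gaps[r] = st.gaps; score[r] = st.score;
    if (r % 64 == 0) checkUserInterrupt();
  }
  return DataFrame::create(_["nident"] = nident, _["length"] = length,
                           _["gaps"] = gaps, _["score"] = score);
}
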