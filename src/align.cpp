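#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap dynamic programming (Gotoh). A gap of length L costs
// gap_open + gap_ext * L.  States: 0 = M (diagonal), 1 = X (gap in b,
// consumes a residue of `a`; "up"), 2 = Y (gap in a; "left").
// Ties are resolved M > X > Y (diagonal > up > left), giving a
// deterministic traceback.

static const double NEG = -1e30;

struct TB {
  // one byte per cell per state
  std::vector<uint8_t> m, x, y;
  size_t cols;
  TB(size_t n, size_t mm) : m((n + 1) * (mm + 1)), x((n + 1) * (mm + 1)),
                            y((n + 1) * (mm + 1)), cols(mm + 1) {}
  inline size_t at(size_t i, size_t j) const { return i * cols + j; }
};

// Shared DP over a per-cell substitution score functor.
template <typename Score>
static List gotoh(int n, int m, Score sub, double gap_open, double gap_ext,
                  bool local) {
  const double go = gap_open + gap_ext;  // cost of the first gap residue
  TB tb(n, m);
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  Mprev[0] = 0.0;
  Xprev[0] = NEG;
  Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    if (local) {
      Yprev[j] = NEG;
    } else {
      Yprev[j] = -(go + gap_ext * (j - 1));
      tb.y[tb.at(0, j)] = (j == 1) ? 0 : 1;
    }
  }

  double best_loc = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    if (local) {
      Xcur[0] = NEG;
    } else {
      Xcur[0] = -(go + gap_ext * (i - 1));
      tb.x[tb.at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      const double sc = sub(i - 1, j - 1);
      // M state: best predecessor on the diagonal
      double best = Mprev[j - 1];
      uint8_t from = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; from = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; from = 2; }
      if (local && best <= 0.0) { best = 0.0; from = 3; }  // fresh start
      double mval = best + sc;
      if (local && mval < 0.0) mval = NEG;  // dead end, never on a path
      Mcur[j] = mval;
      tb.m[tb.at(i, j)] = from;
      // X state (gap in b)
      double xm = Mprev[j] - go, xx = Xprev[j] - gap_ext;
      if (xm >= xx) { Xcur[j] = xm; tb.x[tb.at(i, j)] = 0; }
      else          { Xcur[j] = xx; tb.x[tb.at(i, j)] = 1; }
      // Y state (gap in a)
      double ym = Mcur[j - 1] - go, yy = Ycur[j - 1] - gap_ext;
      if (ym >= yy) { Ycur[j] = ym; tb.y[tb.at(i, j)] = 0; }
      else          { Ycur[j] = yy; tb.y[tb.at(i, j)] = 1; }
      if (local && Mcur[j] > best_loc) {
        best_loc = Mcur[j];
        best_i = i;
        best_j = j;
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
    if (local) {
      // keep last full rows? not needed: traceback uses tb only
    }
  }
  // after the swap, Mprev holds row n
  double score;
  int state;  // 0 M, 1 X, 2 Y
  int ti, tj;
  if (local) {
    score = best_loc;
    state = 0;
    ti = best_i;
    tj = best_j;
  } else {
    score = Mprev[m];
    state = 0;
    if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
    if (Yprev[m] > score) { score = Yprev[m]; state = 2; }
    ti = n;
    tj = m;
  }

  std::vector<int> ai, bi;  // 1-based positions, 0 = gap
  if (local && best_loc <= 0.0) {
    ti = 0; tj = 0;  // empty local alignment
  }
  while (ti > 0 || tj > 0) {
    if (!local && ti == 0) state = 2;
    if (!local && tj == 0) state = 1;
    if (state == 0) {
      ai.push_back(ti);
      bi.push_back(tj);
      uint8_t from = tb.m[tb.at(ti, tj)];
      --ti; --tj;
      if (from == 3) break;      // start of local alignment
      state = from;
    } else if (state == 1) {
      ai.push_back(ti);
      bi.push_back(0);
      uint8_t from = tb.x[tb.at(ti, tj)];
      --ti;
      state = (from == 0) ? 0 : 1;
    } else {
      ai.push_back(0);
      bi.push_back(tj);
      uint8_t from = tb.y[tb.at(ti, tj)];
      --tj;
      state = (from == 0) ? 0 : 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_ext, bool local) {
  const int *pa = INTEGER(a), *pb = INTEGER(b);
  const double *ps = REAL(S);
  const int ns = S.nrow();
  auto sub = [&](int i, int j) {
    return ps[(pa[i] - 1) + ns * (pb[j] - 1)];
  };
  return gotoh(a.size(), b.size(), sub, gap_open, gap_ext, local);
}

// Profile-profile alignment: pa, pb are 20 x L frequency matrices
// (columns sum to <= 1; gap mass contributes nothing). Score of a column
// pair is the frequency-weighted average substitution score fA' S fB.
// [[Rcpp::export]]
List align_profile_cpp(NumericMatrix pa, NumericMatrix pb, NumericMatrix S,
                       double gap_open, double gap_ext) {
  const int K = S.nrow();
  const int la = pa.ncol(), lb = pb.ncol();
  // precompute SB = S %*% pb  (K x lb)
  std::vector<double> SB((size_t)K * lb);
  for (int j = 0; j < lb; ++j)
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int l = 0; l < K; ++l) acc += S(k, l) * pb(l, j);
      SB[(size_t)j * K + k] = acc;
    }
  const double *ppa = REAL(pa);
  auto sub = [&](int i, int j) {
    const double *ca = ppa + (size_t)i * K;
    const double *cb = &SB[(size_t)j * K];
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += ca[k] * cb[k];
    return acc;
  };
  return gotoh(la, lb, sub, gap_open, gap_ext, false);
}

// Column frequency profile of an alignment given as an integer matrix
// (rows = sequences). Codes 1..nstates are residues; anything else
// (gap = NA or 0, ambiguity > nstates) contributes no mass.
// [[Rcpp::export]]
NumericMatrix profile_from_codes_cpp(IntegerMatrix aln, int nstates) {
  const int nr = aln.nrow(), nc = aln.ncol();
  NumericMatrix out(nstates, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int c = aln(i, j);
      if (c != NA_INTEGER && c >= 1 && c <= nstates) out(c - 1, j) += 1.0;
    }
    for (int k = 0; k < nstates; ++k) out(k, j) /= nr;
  }
  return out;
}
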