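#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise and profile-profile alignment with affine gaps (Gotoh
// three-state DP, explicit backpointers).  A gap of length k costs
// gap_open + (k-1) * gap_extend (both negative).  Traceback tie-break:
// match/mismatch > gap-in-b > gap-in-a.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// backpointer codes: which predecessor state (0=M, 1=X, 2=Y)
struct Gotoh {
  int n, m;
  std::vector<double> M, X, Y;
  std::vector<signed char> bM, bX, bY;
  Gotoh(int n_, int m_) : n(n_), m(m_),
    M((n_ + 1) * (m_ + 1), NEG_INF), X(M), Y(M),
    bM((n_ + 1) * (m_ + 1), -1), bX(bM), bY(bM) {}
  inline int at(int i, int j) const { return i * (m + 1) + j; }

  // fill using a column-score callback
  template <typename F>
  void fill(double go, double ge, F score) {
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
      X[at(i, 0)] = go + (i - 1) * ge;
      bX[at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[at(0, j)] = go + (j - 1) * ge;
      bY[at(0, j)] = (j == 1) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double s = score(i - 1, j - 1);
        int d = at(i - 1, j - 1);
        // M: tie-break M > X > Y
        double best = M[d]; signed char arg = 0;
        if (X[d] > best) { best = X[d]; arg = 1; }
        if (Y[d] > best) { best = Y[d]; arg = 2; }
        M[at(i, j)] = best + s; bM[at(i, j)] = arg;
        // X: consume from a (gap in b)
        int u = at(i - 1, j);
        best = M[u] + go; arg = 0;
        if (X[u] + ge > best) { best = X[u] + ge; arg = 1; }
        if (Y[u] + go > best) { best = Y[u] + go; arg = 2; }
        X[at(i, j)] = best; bX[at(i, j)] = arg;
        // Y: consume from b (gap in a)
        int l = at(i, j - 1);
        best = M[l] + go; arg = 0;
        if (X[l] + go > best) { best = X[l] + go; arg = 1; }
        if (Y[l] + ge > best) { best = Y[l] + ge; arg = 2; }
        Y[at(i, j)] = best; bY[at(i, j)] = arg;
      }
    }
  }

  // traceback into per-column source indices (1-based; 0 = gap)
  void traceback(std::vector<int>& mapa, std::vector<int>& mapb,
                 double& score) const {
    int e = at(n, m);
    int state = 0;
    score = M[e];
    if (X[e] > score) { score = X[e]; state = 1; }
    if (Y[e] > score) { score = Y[e]; state = 2; }
    if (n == 0 && m == 0) { score = 0.0; return; }
    if (n == 0) { score = Y[e]; state = 2; }
    if (m == 0) { score = X[e]; state = 1; }
    int i = n, j = m;
    while (i > 0 || j > 0) {
      if (state == 0) {
        mapa.push_back(i); mapb.push_back(j);
        state = bM[at(i, j)];
        --i; --j;
      } else if (state == 1) {
        mapa.push_back(i); mapb.push_back(0);
        state = bX[at(i, j)];
        --i;
      } else {
        mapa.push_back(0); mapb.push_back(j);
        state = bY[at(i, j)];
        --j;
      }
    }
    std::reverse(mapa.begin(), mapa.end());
    std::reverse(mapb.begin(), mapb.end());
  }
};

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  std::string alphabet, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  int idx[256];
  for (int c = 0; c < 256; ++c) idx[c] = -1;
  for (size_t k = 0; k < alphabet.size(); ++k)
    idx[(unsigned char)alphabet[k]] = (int)k;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in alphabet", std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in alphabet", std::string(1, b[j]));
  }
  Gotoh g(n, m);
  g.fill(gap_open, gap_extend,
         [&](int i, int j) { return submat(ai[i], bi[j]); });
  std::vector<int> mapa, mapb;
  double score;
  g.traceback(mapa, mapb, score);
  std::string ra, rb;
  ra.reserve(mapa.size()); rb.reserve(mapa.size());
  for (size_t t = 0; t < mapa.size(); ++t) {
    ra.push_back(mapa[t] > 0 ? a[mapa[t] - 1] : '-');
    rb.push_back(mapb[t] > 0 ? b[mapb[t] - 1] : '-');
  }
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// Profile-profile alignment; column score is the occupancy-weighted
// expected substitution score between frequency vectors fa (La x A) and
// fb (Lb x A).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix fa, NumericMatrix fb, NumericMatrix submat,
                       double gap_open, double gap_extend) {
  const int n = fa.nrow(), m = fb.nrow(), A = fa.ncol();
  NumericMatrix sb(m, A);  // sb(j, a) = sum_b fb(j,b) * S(a,b)
  for (int j = 0; j < m; ++j)
    for (int aa = 0; aa < A; ++aa) {
      double acc = 0.0;
      for (int bb = 0; bb < A; ++bb) acc += fb(j, bb) * submat(aa, bb);
      sb(j, aa) = acc;
    }
  Gotoh g(n, m);
  g.fill(gap_open, gap_extend, [&](int i, int j) {
    double s = 0.0;
    for (int aa = 0; aa < A; ++aa) s += fa(i, aa) * sb(j, aa);
    return s;
  });
  std::vector<int> mapa, mapb;
  double score;
  g.traceback(mapa, mapb, score);
  return List::create(_["map_a"] = wrap(mapa), _["map_b"] = wrap(mapb),
                      _["score"] = score);
}
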