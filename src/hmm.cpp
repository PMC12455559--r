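#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Profile HMM forward and Viterbi in log-odds space (natural log internally,
// bits on return).  Node k = 0..L, node 0 is Begin (an M state emitting
// nothing).  Transition layout (vectors of length L+1):
//   mm[k] = P(M_k -> M_{k+1}); mm[L] = P(M_L -> End)
//   mi[k] = P(M_k -> I_k)
//   md[k] = P(M_k -> D_{k+1}); md[L] = 0
//   im[k] = P(I_k -> M_{k+1}); im[L] = P(I_L -> End)
//   ii[k] = P(I_k -> I_k)
//   dm[k] = P(D_k -> M_{k+1}); dm[L] = P(D_L -> End)
//   dd[k] = P(D_k -> D_{k+1}); dd[L] = 0
// Match emissions: A x L; insert emissions and background: length A.
// Residue indices are 0-based into the alphabet; -1 denotes 'X', which emits
// with background probability (log-odds contribution zero) in M and I states.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logsum2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double logsum3(double a, double b, double c) {
  return logsum2(logsum2(a, b), c);
}
static inline double lg(double x) { return x > 0 ? std::log(x) : NEG_INF; }

struct HmmPar {
  int L, A;
  std::vector<double> lme;  // log-odds match emissions, A x L (col-major)
  std::vector<double> lie;  // log-odds insert emissions
  std::vector<double> mm, mi, md, im, ii, dm, dd;  // log transitions
  HmmPar(List hmm) {
    NumericMatrix me = as<NumericMatrix>(hmm["match_emissions"]);
    NumericVector ie = as<NumericVector>(hmm["insert_emissions"]);
    NumericVector bg = as<NumericVector>(hmm["background"]);
    L = me.ncol();
    A = me.nrow();
    lme.resize(A * L);
    for (int k = 0; k < L; ++k)
      for (int x = 0; x < A; ++x)
        lme[k * A + x] = lg(me(x, k)) - lg(bg[x]);
    lie.resize(A);
    for (int x = 0; x < A; ++x) lie[x] = lg(ie[x]) - lg(bg[x]);
    auto grab = [&](const char* nm, std::vector<double>& v) {
      NumericVector t = as<NumericVector>(hmm[nm]);
      v.resize(t.size());
      for (int i = 0; i < t.size(); ++i) v[i] = lg(t[i]);
    };
    grab("mm", mm); grab("mi", mi); grab("md", md);
    grab("im", im); grab("ii", ii); grab("dm", dm); grab("dd", dd);
  }
  inline double em(int k, int x) const {  // k 1-based; x < 0 is 'X'
    return x < 0 ? 0.0 : lme[(k - 1) * A + x];
  }
  inline double ei(int x) const { return x < 0 ? 0.0 : lie[x]; }
};

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(List hmm, IntegerVector seq, std::string mode) {
  HmmPar p(hmm);
  const int L = p.L, n = seq.size();
  bool local = (mode == "unilocal");
  // DP over nodes x positions; fM[k][i]: paths ending with M_k having
  // emitted i residues (M_k emitted residue i).
  std::vector<std::vector<double>> fM(L + 1, std::vector<double>(n + 1, NEG_INF)),
      fI(L + 1, std::vector<double>(n + 1, NEG_INF)),
      fD(L + 1, std::vector<double>(n + 1, NEG_INF));
  // in uni-local mode all entry goes through the uniform match-state entry,
  // so Begin-anchored (global) paths are disabled
  fM[0][0] = local ? NEG_INF : 0.0;
  double lent = local ? -std::log((double)L) : NEG_INF;
  // I_0 and D_1 only in global mode paths from Begin
  for (int i = 1; i <= n; ++i)
    fI[0][i] = p.ei(seq[i - 1]) +
               logsum2(fM[0][i - 1] + p.mi[0], fI[0][i - 1] + p.ii[0]);
  for (int k = 1; k <= L; ++k) {
    fD[k][0] = (k == 1) ? fM[0][0] + p.md[0]
                        : logsum2(fM[k - 1][0] + p.md[k - 1],
                                  fD[k - 1][0] + p.dd[k - 1]);
    for (int i = 1; i <= n; ++i) {
      double entry = local ? lent : NEG_INF;  // N -> M_k, prefix at background
      fM[k][i] = p.em(k, seq[i - 1]) +
                 logsum2(logsum3(fM[k - 1][i - 1] + p.mm[k - 1],
                                 fI[k - 1][i - 1] + p.im[k - 1],
                                 fD[k - 1][i - 1] + p.dm[k - 1]),
                         entry);
      fI[k][i] = p.ei(seq[i - 1]) + logsum2(fM[k][i - 1] + p.mi[k],
                                            fI[k][i - 1] + p.ii[k]);
      fD[k][i] = logsum2(fM[k - 1][i] + p.md[k - 1],
                         fD[k - 1][i] + p.dd[k - 1]);
    }
  }
  double total = NEG_INF;
  if (!local) {
    total = logsum3(fM[L][n] + p.mm[L], fI[L][n] + p.im[L],
                    fD[L][n] + p.dm[L]);
  } else {
    // exit from any match state at any position; suffix emitted at background
    for (int k = 1; k <= L; ++k)
      for (int i = 1; i <= n; ++i) total = logsum2(total, fM[k][i]);
    // the empty-alignment path is not allowed (must pass >=1 match state)
  }
  return total / std::log(2.0);
}

// Viterbi: returns bit score, per-residue match-column assignment (0 = not a
// match emission), and matched span (first/last residue index, 1-based).
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(List hmm, IntegerVector seq, std::string mode) {
  HmmPar p(hmm);
  const int L = p.L, n = seq.size();
  bool local = (mode == "unilocal");
  std::vector<std::vector<double>> vM(L + 1, std::vector<double>(n + 1, NEG_INF)),
      vI(L + 1, std::vector<double>(n + 1, NEG_INF)),
      vD(L + 1, std::vector<double>(n + 1, NEG_INF));
  // back-pointers: 0 = from M, 1 = from I, 2 = from D, 3 = entry
  std::vector<std::vector<signed char>> bM(L + 1, std::vector<signed char>(n + 1, -1)),
      bI(L + 1, std::vector<signed char>(n + 1, -1)),
      bD(L + 1, std::vector<signed char>(n + 1, -1));
  vM[0][0] = local ? NEG_INF : 0.0;
  double lent = local ? -std::log((double)L) : NEG_INF;
  for (int i = 1; i <= n; ++i) {
    double a = vM[0][i - 1] + p.mi[0], b = vI[0][i - 1] + p.ii[0];
    vI[0][i] = p.ei(seq[i - 1]) + std::max(a, b);
    bI[0][i] = (a >= b) ? 0 : 1;
  }
  for (int k = 1; k <= L; ++k) {
    if (k == 1) {
      vD[1][0] = vM[0][0] + p.md[0];
      bD[1][0] = 0;
    } else {
      double a = vM[k - 1][0] + p.md[k - 1],
             b = vD[k - 1][0] + p.dd[k - 1];
      vD[k][0] = std::max(a, b);
      bD[k][0] = (a >= b) ? 0 : 2;
    }
    for (int i = 1; i <= n; ++i) {
      double fm = vM[k - 1][i - 1] + p.mm[k - 1];
      double fd = vD[k - 1][i - 1] + p.dm[k - 1];
      double fi = vI[k - 1][i - 1] + p.im[k - 1];
      // tie-break preference: M > D > I
      double best = fm;
      signed char arg = 0;
      if (fd > best) { best = fd; arg = 2; }
      if (fi > best) { best = fi; arg = 1; }
      if (local && lent > best) { best = lent; arg = 3; }
      vM[k][i] = p.em(k, seq[i - 1]) + best;
      bM[k][i] = arg;
      double a = vM[k][i - 1] + p.mi[k], b = vI[k][i - 1] + p.ii[k];
      vI[k][i] = p.ei(seq[i - 1]) + std::max(a, b);
      bI[k][i] = (a >= b) ? 0 : 1;
      a = vM[k - 1][i] + p.md[k - 1];
      b = vD[k - 1][i] + p.dd[k - 1];
      vD[k][i] = std::max(a, b);
      bD[k][i] = (a >= b) ? 0 : 2;
    }
  }
  double best = NEG_INF;
  int endk = -1, endi = -1, endstate = 0;
  if (!local) {
    double m = vM[L][n] + p.mm[L], ii_ = vI[L][n] + p.im[L],
           d = vD[L][n] + p.dm[L];
    best = m; endstate = 0;
    if (d > best) { best = d; endstate = 2; }
    if (ii_ > best) { best = ii_; endstate = 1; }
    endk = L; endi = n;
  } else {
    for (int k = 1; k <= L; ++k)
      for (int i = 1; i <= n; ++i)
        if (vM[k][i] > best) { best = vM[k][i]; endk = k; endi = i; }
    endstate = 0;
  }
  IntegerVector colmap(n, 0);
  int first = 0, last = 0;
  if (best > NEG_INF && endk >= 0) {
    int k = endk, i = endi, st = endstate;
    last = local ? endi : 0;
    while (true) {
      if (st == 0) {  // M_k emitted residue i
        if (k == 0) break;  // Begin
        colmap[i - 1] = k;
        if (last == 0) last = i;
        first = i;
        signed char bp = bM[k][i];
        --i; --k;
        if (bp == 3) break;  // local entry
        st = bp;
      } else if (st == 1) {
        signed char bp = bI[k][i];
        --i;
        st = bp;
      } else {
        signed char bp = bD[k][i];
        --k;
        st = bp;
      }
    }
  }
  return List::create(_["bits"] = best / std::log(2.0), _["colmap"] = colmap,
                      _["span"] = IntegerVector::create(first, last));
}
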