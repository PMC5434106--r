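#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Global (end-gap-penalized) affine-gap pairwise alignment restricted to a
// diagonal band, with traceback, returning the alignment identity used for
// OTU clustering: matching columns / alignment columns excluding
// terminal-gap columns. Scoring: match +1, mismatch -1, gap open -2 plus
// -1 per gap position (a length-L gap costs 2 + L). All scores are small
// integers, so traceback comparisons are exact.
//
// The band allows j - i (j along `y`, i along `x`) to range over
// [min(0, m-n) - band, max(0, m-n) + band], which always contains the
// corner-to-corner path; a band of max(n, m) or more is a full alignment.
//
// Banded addressing: cell (i, j) lives at row i, column c = j - i - minoff;
// its diagonal neighbour (i-1, j-1) has the same c, the left neighbour
// (i, j-1) has c-1, and the upper neighbour (i-1, j) has c+1.

static const int NEG = INT_MIN / 4;

struct AlnResult {
  long matches;
  long core_cols;
  int score;
};

static AlnResult banded_align(const std::string &x, const std::string &y,
                              int band) {
  const int n = (int)x.size();
  const int m = (int)y.size();
  const int minoff = std::min(0, m - n) - band;
  const int maxoff = std::max(0, m - n) + band;
  const int W = maxoff - minoff + 1;

  std::vector<int> H((size_t)(n + 1) * W, NEG);
  std::vector<int> E((size_t)(n + 1) * W, NEG);
  std::vector<int> F((size_t)(n + 1) * W, NEG);

  // row 0: j from 0 while in band (c = j - minoff)
  {
    int c0 = -minoff;                       // column of j = 0
    if (c0 >= 0 && c0 < W) H[c0] = 0;
    for (int j = 1; j <= m; ++j) {
      int c = j - minoff;
      if (c >= W) break;
      if (c >= 0) E[c] = -2 - j;            // leading gap in x
    }
  }
  for (int i = 1; i <= n; ++i) {
    int *Hr = &H[(size_t)i * W];
    int *Er = &E[(size_t)i * W];
    int *Fr = &F[(size_t)i * W];
    const int *Hp = Hr - W;
    const int *Ep = Er - W;
    const int *Fp = Fr - W;
    const char xi = x[i - 1];
    {
      int c = -i - minoff;                  // column of j = 0
      if (c >= 0 && c < W) Fr[c] = -2 - i;  // leading gap in y
    }
    int jlo = std::max(1, i + minoff);
    int jhi = std::min(m, i + maxoff);
    for (int j = jlo; j <= jhi; ++j) {
      const int c = j - i - minoff;
      // diagonal (i-1, j-1): previous row, same c (always a valid index)
      {
        int best = Hp[c];
        if (Ep[c] > best) best = Ep[c];
        if (Fp[c] > best) best = Fp[c];
        Hr[c] = (best <= NEG / 2) ? NEG : best + (xi == y[j - 1] ? 1 : -1);
      }
      // left (i, j-1): same row, c-1
      if (c - 1 >= 0) {
        int open = (Hr[c - 1] > Fr[c - 1] ? Hr[c - 1] : Fr[c - 1]) - 3;
        int ext = Er[c - 1] - 1;
        int v = open > ext ? open : ext;
        Er[c] = (v <= NEG / 2) ? NEG : v;
      }
      // up (i-1, j): previous row, c+1
      if (c + 1 < W) {
        int open = (Hp[c + 1] > Ep[c + 1] ? Hp[c + 1] : Ep[c + 1]) - 3;
        int ext = Fp[c + 1] - 1;
        int v = open > ext ? open : ext;
        Fr[c] = (v <= NEG / 2) ? NEG : v;
      }
    }
  }

  // traceback from the best end state; ops: 0 = diagonal, 1 = gap in x
  // (consume y), 2 = gap in y (consume x); ties prefer H, then E, then F
  auto at = [&](const std::vector<int> &M, int i, int j) -> int {
    int c = j - i - minoff;
    if (j < 0 || c < 0 || c >= W) return NEG;
    return M[(size_t)i * W + c];
  };
  int i = n, j = m;
  int hv = at(H, i, j), ev = at(E, i, j), fv = at(F, i, j);
  int state = (hv >= ev && hv >= fv) ? 0 : (ev >= fv ? 1 : 2);
  const int final_score = std::max(hv, std::max(ev, fv));

  std::vector<char> ops;
  ops.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      int target = at(H, i, j) - (x[i - 1] == y[j - 1] ? 1 : -1);
      if (i - 1 == 0 && j - 1 == 0) state = 0;
      else if (at(H, i - 1, j - 1) == target) state = 0;
      else if (at(E, i - 1, j - 1) == target) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      int target = at(E, i, j);
      if (j - 1 == 0 && i == 0) state = 0;
      else if (at(H, i, j - 1) - 3 == target) state = 0;
      else if (at(E, i, j - 1) - 1 == target) state = 1;
      else state = 2;
      --j;
    } else {
      ops.push_back(2);
      int target = at(F, i, j);
      if (i - 1 == 0 && j == 0) state = 0;
      else if (at(H, i - 1, j) - 3 == target) state = 0;
      else if (at(F, i - 1, j) - 1 == target) state = 2;
      else state = 1;
      --i;
    }
  }

  // ops run from the last alignment column to the first; terminal-gap
  // columns are the runs of gap ops before the first and after the last
  // diagonal op
  long first = -1, last = -1;
  for (long k = 0; k < (long)ops.size(); ++k)
    if (ops[k] == 0) { if (first < 0) first = k; last = k; }

  AlnResult res;
  res.score = final_score;
  if (first < 0) { res.matches = 0; res.core_cols = 0; return res; }
  long matches = 0, core = 0;
  long xi = n, yj = m;
  for (long k = 0; k < (long)ops.size(); ++k) {
    if (ops[k] == 0) {
      if (k >= first && k <= last && x[xi - 1] == y[yj - 1]) ++matches;
      --xi; --yj;
    } else if (ops[k] == 1) {
      --yj;
    } else {
      --xi;
    }
    if (k >= first && k <= last) ++core;
  }
  res.matches = matches;
  res.core_cols = core;
  return res;
}

// [[Rcpp::export(name = ".banded_identity")]]
NumericVector banded_identity_cpp(CharacterVector a, std::string b,
                                  int band) {
  const int nseq = a.size();
  NumericVector out(nseq);
  for (int s = 0; s < nseq; ++s) {
    std::string x = as<std::string>(a[s]);
    if (x.empty() || b.empty()) stop("sequences must be non-empty");
    if (x == b) { out[s] = 1.0; continue; }
    AlnResult r = banded_align(x, b, band);
    out[s] = r.core_cols > 0 ? (double)r.matches / r.core_cols : 0.0;
  }
  return out;
}

// Identity, optimal score, match and core-column counts for one pair;
// the score lets tests verify optimality against an independent aligner
// even when co-optimal paths differ in identity.
// [[Rcpp::export(name = ".align_stats")]]
List align_stats_cpp(std::string a, std::string b, int band) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  AlnResult r = banded_align(a, b, band);
  return List::create(
    _["identity"] = r.core_cols > 0 ? (double)r.matches / r.core_cols : 0.0,
    _["score"] = (double)r.score,
    _["matches"] = (double)r.matches,
    _["core_cols"] = (double)r.core_cols);
}
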