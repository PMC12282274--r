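#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment.
// Gap cost convention: a gap run of length L costs gap_open + (L-1)*gap_extend
// (both negative). Three-state DP with deterministic traceback preferring
// match/mismatch over a gap in `a` over a gap in `b`.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(const std::string& a, const std::string& b,
                  NumericMatrix sub, const std::string& alphabet,
                  double gap_open, double gap_extend, bool traceback) {
  const int n = a.size(), m = b.size();

  // residue -> substitution matrix index
  std::vector<int> idx(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k) {
    idx[(unsigned char)alphabet[k]] = (int)k;
  }
  for (int i = 0; i < n; ++i) {
    if (idx[(unsigned char)a[i]] < 0) stop("residue outside alphabet in sequence a");
  }
  for (int j = 0; j < m; ++j) {
    if (idx[(unsigned char)b[j]] < 0) stop("residue outside alphabet in sequence b");
  }

  // state 0 = M (a[i] vs b[j]), 1 = Y (gap in a, consumes b), 2 = X (gap in b, consumes a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  // traceback: which predecessor state fed each cell's state
  std::vector<signed char> tbM, tbY, tbX;
  if (traceback) {
    tbM.assign((n + 1) * (m + 1), -1);
    tbY.assign((n + 1) * (m + 1), -1);
    tbX.assign((n + 1) * (m + 1), -1);
  }
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    if (traceback) tbY[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    if (traceback) tbX[at(i, 0)] = (i == 1) ? 0 : 2;
  }

  // pick best predecessor with preference order M > Y > X
  auto best3 = [](double vm, double vy, double vx, signed char& which) {
    double best = vm; which = 0;
    if (vy > best) { best = vy; which = 1; }
    if (vx > best) { best = vx; which = 2; }
    return best;
  };

  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int bj = idx[(unsigned char)b[j - 1]];
      signed char w;
      // M: diagonal move
      double s = sub(ai, bj);
      double v = best3(M[at(i - 1, j - 1)], Y[at(i - 1, j - 1)], X[at(i - 1, j - 1)], w);
      if (v > NEG_INF) {
        M[at(i, j)] = v + s;
        if (traceback) tbM[at(i, j)] = w;
      }
      // Y: gap in a, consume b[j]
      {
        double vm = M[at(i, j - 1)] + gap_open;
        double vy = Y[at(i, j - 1)] + gap_extend;
        double vx = X[at(i, j - 1)] + gap_open;
        double vv = best3(vm, vy, vx, w);
        if (vv > NEG_INF) {
          Y[at(i, j)] = vv;
          if (traceback) tbY[at(i, j)] = w;
        }
      }
      // X: gap in b, consume a[i]
      {
        double vm = M[at(i - 1, j)] + gap_open;
        double vy = Y[at(i - 1, j)] + gap_open;
        double vx = X[at(i - 1, j)] + gap_extend;
        double vv = best3(vm, vy, vx, w);
        if (vv > NEG_INF) {
          X[at(i, j)] = vv;
          if (traceback) tbX[at(i, j)] = w;
        }
      }
    }
  }

  signed char state;
  double score = best3(M[at(n, m)], Y[at(n, m)], X[at(n, m)], state);

  std::string ga, gb;
  int matches = 0, aligned_cols = 0;
  if (traceback) {
    int i = n, j = m;
    std::string ra, rb;
    while (i > 0 || j > 0) {
      if (state == 0) {
        signed char prev = tbM[at(i, j)];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        if (a[i - 1] == b[j - 1] && a[i - 1] != 'X') ++matches;
        ++aligned_cols;
        --i; --j;
        state = prev;
      } else if (state == 1) {
        signed char prev = tbY[at(i, j)];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        state = prev;
      } else {
        signed char prev = tbX[at(i, j)];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        state = prev;
      }
    }
    ga.assign(ra.rbegin(), ra.rend());
    gb.assign(rb.rbegin(), rb.rend());
  }

  return List::create(
    _["score"] = score,
    _["aligned_a"] = ga,
    _["aligned_b"] = gb,
    _["matches"] = matches,
    _["aligned_columns"] = aligned_cols
  );
}

// Score-and-stats only, vectorized over many partners of one sequence;
// avoids per-pair R call overhead in the all-against-all matrix build.
// [[Rcpp::export(name = ".nw_align_many_cpp")]]
DataFrame nw_align_many_cpp(const std::string& x, CharacterVector ys,
                            NumericMatrix sub, const std::string& alphabet,
                            double gap_open, double gap_extend) {
  const int k = ys.size();
  NumericVector identity(k), coverage(k), score(k);
  for (int t = 0; t < k; ++t) {
    std::string y = as<std::string>(ys[t]);
    // canonical orientation keeps traceback statistics swap-invariant
    List r = (x <= y)
      ? nw_align_cpp(x, y, sub, alphabet, gap_open, gap_extend, true)
      : nw_align_cpp(y, x, sub, alphabet, gap_open, gap_extend, true);
    int matches = r["matches"];
    int cols = r["aligned_columns"];
    identity[t] = cols == 0 ? 0.0 : 100.0 * matches / cols;
    double cov_x = 100.0 * cols / std::max<int>(x.size(), 1);
    double cov_y = 100.0 * cols / std::max<int>(y.size(), 1);
    coverage[t] = std::min(cov_x, cov_y);
    score[t] = as<double>(r["score"]);
  }
  return DataFrame::create(
    _["identity_pct"] = identity,
    _["coverage_pct"] = coverage,
    _["score"] = score,
    _["stringsAsFactors"] = false
  );
}
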