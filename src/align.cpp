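#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) over a 21-letter protein alphabet.
// Gap run of length L costs open + (L - 1) * ext, i.e. the first gap column
// pays the full opening penalty. Traceback tie-break order: diagonal, then
// gap-in-target (consume query), then gap-in-query.

static const double NEG_INF = -1e18;

static inline int idx_of(char c, const std::string &alphabet) {
  size_t p = alphabet.find(c);
  if (p == std::string::npos) return -1;
  return (int)p;
}

static std::vector<int> encode(const std::string &s, const std::string &alphabet) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int k = idx_of(s[i], alphabet);
    if (k < 0) stop("invalid character '%s' in sequence", std::string(1, s[i]).c_str());
    v[i] = k;
  }
  return v;
}

// states: 0 = M (diagonal), 1 = X (gap in target, consumes query), 2 = Y (gap in query)
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                    std::string alphabet, double open, double ext, bool local) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);

  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG_INF)),
      X(n + 1, std::vector<double>(m + 1, NEG_INF)),
      Y(n + 1, std::vector<double>(m + 1, NEG_INF));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = local ? NEG_INF : -(open + (i - 1) * ext);
  for (int j = 1; j <= m; ++j) Y[0][j] = local ? NEG_INF : -(open + (j - 1) * ext);

  double best = 0.0; int bi = 0, bj = 0, bstate = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ea[i - 1], eb[j - 1]);
      double dM = M[i - 1][j - 1], dX = X[i - 1][j - 1], dY = Y[i - 1][j - 1];
      double dbest = std::max(dM, std::max(dX, dY));
      double mv = (dbest <= NEG_INF / 2) ? NEG_INF : dbest + s;
      if (local) mv = std::max(mv, s); // fresh local start
      M[i][j] = mv;

      double xo = (M[i - 1][j] <= NEG_INF / 2) ? NEG_INF : M[i - 1][j] - open;
      double xe = (X[i - 1][j] <= NEG_INF / 2) ? NEG_INF : X[i - 1][j] - ext;
      double xy = (Y[i - 1][j] <= NEG_INF / 2) ? NEG_INF : Y[i - 1][j] - open;
      X[i][j] = std::max(xo, std::max(xe, xy));

      double yo = (M[i][j - 1] <= NEG_INF / 2) ? NEG_INF : M[i][j - 1] - open;
      double yx = (X[i][j - 1] <= NEG_INF / 2) ? NEG_INF : X[i][j - 1] - open;
      double ye = (Y[i][j - 1] <= NEG_INF / 2) ? NEG_INF : Y[i][j - 1] - ext;
      Y[i][j] = std::max(yo, std::max(yx, ye));

      if (local && M[i][j] > best) { best = M[i][j]; bi = i; bj = j; bstate = 0; }
    }
  }

  std::string qa, qb;
  int qs = 0, qe = 0, ts = 0, te = 0;
  double score;

  if (local) {
    score = best;
    if (best <= 0.0) { // empty alignment
      return List::create(_["score"] = 0.0, _["aligned_a"] = "", _["aligned_b"] = "",
                          _["a_span"] = IntegerVector::create(NA_INTEGER, NA_INTEGER),
                          _["b_span"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
    }
    int i = bi, j = bj, state = bstate;
    qe = bi; te = bj;
    const double tol = 1e-9;
    while (true) {
      if (state == 0) {
        double s = sub(ea[i - 1], eb[j - 1]);
        qa.push_back(a[i - 1]); qb.push_back(b[j - 1]);
        double v = M[i][j];
        // ended here? a fresh local start terminates traceback
        if (std::abs(v - s) < tol &&
            !(i > 1 && j > 1 &&
              (std::abs(M[i-1][j-1] + s - v) < tol ||
               std::abs(X[i-1][j-1] + s - v) < tol ||
               std::abs(Y[i-1][j-1] + s - v) < tol))) {
          i--; j--; break;
        }
        if (std::abs(M[i-1][j-1] + s - v) < tol) state = 0;
        else if (std::abs(X[i-1][j-1] + s - v) < tol) state = 1;
        else state = 2;
        i--; j--;
        if (i == 0 || j == 0) break;
      } else if (state == 1) {
        qa.push_back(a[i - 1]); qb.push_back('-');
        double v = X[i][j];
        if (std::abs(M[i-1][j] - open - v) < 1e-9) state = 0;
        else if (std::abs(X[i-1][j] - ext - v) < 1e-9) state = 1;
        else state = 2;
        i--;
      } else {
        qa.push_back('-'); qb.push_back(b[j - 1]);
        double v = Y[i][j];
        if (std::abs(M[i][j-1] - open - v) < 1e-9) state = 0;
        else if (std::abs(X[i][j-1] - open - v) < 1e-9) state = 1;
        else state = 2;
        j--;
      }
    }
    qs = i + 1; ts = j + 1;
  } else {
    double gM = M[n][m], gX = X[n][m], gY = Y[n][m];
    score = std::max(gM, std::max(gX, gY));
    int state = (gM >= gX && gM >= gY) ? 0 : (gX >= gY ? 1 : 2);
    int i = n, j = m;
    const double tol = 1e-9;
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 && state == 0) {
        double s = sub(ea[i - 1], eb[j - 1]);
        qa.push_back(a[i - 1]); qb.push_back(b[j - 1]);
        double v = M[i][j];
        if (i > 1 || j > 1) {
          if (std::abs(M[i-1][j-1] + s - v) < tol) state = 0;
          else if (std::abs(X[i-1][j-1] + s - v) < tol) state = 1;
          else state = 2;
        }
        i--; j--;
      } else if (i > 0 && (state == 1 || j == 0)) {
        qa.push_back(a[i - 1]); qb.push_back('-');
        double v = X[i][j];
        if (j > 0) {
          if (std::abs(M[i-1][j] - open - v) < tol) state = 0;
          else if (std::abs(X[i-1][j] - ext - v) < tol) state = 1;
          else state = 2;
        }
        i--;
      } else {
        qa.push_back('-'); qb.push_back(b[j - 1]);
        double v = Y[i][j];
        if (i > 0) {
          if (std::abs(M[i][j-1] - open - v) < tol) state = 0;
          else if (std::abs(X[i][j-1] - open - v) < tol) state = 1;
          else state = 2;
        }
        j--;
      }
    }
    qs = 1; qe = n; ts = 1; te = m;
  }

  std::reverse(qa.begin(), qa.end());
  std::reverse(qb.begin(), qb.end());
  return List::create(_["score"] = score, _["aligned_a"] = qa, _["aligned_b"] = qb,
                      _["a_span"] = IntegerVector::create(qs, qe),
                      _["b_span"] = IntegerVector::create(ts, te));
}

// Brute-force oracle: recursion over all monotone edit paths, scoring affine
// gaps by tracking the previous move. No memoization; independent of the DP.
static double enum_rec(const std::vector<int> &a, const std::vector<int> &b,
                       int i, int j, int last, const NumericMatrix &sub,
                       double open, double ext) {
  const int n = (int)a.size(), m = (int)b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double v = sub(a[i], b[j]) + enum_rec(a, b, i + 1, j + 1, 0, sub, open, ext);
    best = std::max(best, v);
  }
  if (i < n) {
    double c = (last == 1) ? ext : open;
    best = std::max(best, -c + enum_rec(a, b, i + 1, j, 1, sub, open, ext));
  }
  if (j < m) {
    double c = (last == 2) ? ext : open;
    best = std::max(best, -c + enum_rec(a, b, i, j + 1, 2, sub, open, ext));
  }
  return best;
}

// [[Rcpp::export(name = ".enum_global_score_cpp")]]
double enum_global_score_cpp(std::string a, std::string b, NumericMatrix sub,
                             std::string alphabet, double open, double ext) {
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  return enum_rec(ea, eb, 0, 0, -1, sub, open, ext);
}

// Local oracle: best global enumeration score over every substring pair,
// floored at 0 (the empty alignment).
// [[Rcpp::export(name = ".enum_local_score_cpp")]]
double enum_local_score_cpp(std::string a, std::string b, NumericMatrix sub,
                            std::string alphabet, double open, double ext) {
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  const int n = (int)ea.size(), m = (int)eb.size();
  double best = 0.0;
  for (int i1 = 0; i1 < n; ++i1) for (int i2 = i1 + 1; i2 <= n; ++i2)
    for (int j1 = 0; j1 < m; ++j1) for (int j2 = j1 + 1; j2 <= m; ++j2) {
      std::vector<int> sa(ea.begin() + i1, ea.begin() + i2);
      std::vector<int> sb(eb.begin() + j1, eb.begin() + j2);
      best = std::max(best, enum_rec(sa, sb, 0, 0, -1, sub, open, ext));
    }
  return best;
}
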