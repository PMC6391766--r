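#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment with deterministic traceback.
// A gap run of length L costs gap_open + L * gap_extend (scores, so both
// are typically negative). Traceback prefers diagonal, then up (gap in b),
// then left (gap in a) on ties.

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // state matrices: M diag, X gap in b (consumes a, "up"), Y gap in a ("left")
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + j * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      if (prev > NEG) M(i, j) = prev + sub;
      double xo = M(i - 1, j) + gap_open + gap_extend;
      double xx = X(i - 1, j) + gap_extend;
      double xy = Y(i - 1, j) + gap_open + gap_extend;
      X(i, j) = std::max(xo, std::max(xx, xy));
      double yo = M(i, j - 1) + gap_open + gap_extend;
      double yy = Y(i, j - 1) + gap_extend;
      double yx = X(i, j - 1) + gap_open + gap_extend;
      Y(i, j) = std::max(yo, std::max(yy, yx));
    }
  }

  const double tol = 1e-9;
  int i = n, j = m;
  // state: 0 = M, 1 = X (up), 2 = Y (left); preference M > X > Y on ties
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  int state;
  if (M(n, m) >= best - tol) state = 0;
  else if (X(n, m) >= best - tol) state = 1;
  else state = 2;
  double score = best;

  std::string ra, rb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double target = M(i, j) - sub;
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M(i, j) >= target - tol) state = 0;
      else if (X(i, j) >= target - tol) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      double cur = X(i, j);
      --i;
      if (M(i, j) + gap_open + gap_extend >= cur - tol) state = 0;
      else if (X(i, j) + gap_extend >= cur - tol) state = 1;
      else state = 2;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      double cur = Y(i, j);
      --j;
      if (M(i, j) + gap_open + gap_extend >= cur - tol) state = 0;
      else if (Y(i, j) + gap_extend >= cur - tol) state = 2;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
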