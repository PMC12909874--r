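#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Gap convention: a run of g gap positions costs gap_open + (g-1) * gap_ext,
// i.e. the first gapped residue carries the opening penalty. gap_open and
// gap_ext are the (non-positive) score increments themselves, not magnitudes.
//
// States: M = a[i] aligned to b[j]; X = a[i] against a gap ("up");
//         Y = b[j] against a gap ("left").
// Traceback ties are resolved M > X > Y (diagonal > up > left) so aligned
// strings are reproducible; tie choice never affects the score.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct DPResult {
  double score;
  int matches;
  int columns;
  std::string aligned_a;
  std::string aligned_b;
};

static inline int best_state(double m, double x, double y) {
  // priority M > X > Y under exact float equality of the running maxima;
  // all inputs are sums of identical term multisets when tied in exact
  // arithmetic, and scheme values are small decimals, so compare with a
  // tolerance to be safe.
  const double eps = 1e-9;
  double mx = std::max(m, std::max(x, y));
  if (m >= mx - eps) return 0;
  if (x >= mx - eps) return 1;
  return 2;
}

static DPResult gotoh_global(const std::string &a, const std::string &b,
                             double match, double mismatch,
                             double gap_open, double gap_ext,
                             bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = gap_open + (i - 1) * gap_ext;
  for (int j = 1; j <= m; ++j) Y[j] = gap_open + (j - 1) * gap_ext;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      M[c] = std::max(M[d], std::max(X[d], Y[d])) + s;
      X[c] = std::max(M[u] + gap_open,
                      std::max(X[u] + gap_ext, Y[u] + gap_open));
      Y[c] = std::max(M[l] + gap_open,
                      std::max(X[l] + gap_open, Y[l] + gap_ext));
    }
  }
  DPResult res;
  const size_t end = (size_t)n * W + m;
  int state = best_state(M[end], X[end], Y[end]);
  res.score = std::max(M[end], std::max(X[end], Y[end]));
  res.matches = 0;
  res.columns = 0;
  if (!traceback) return res;

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) res.matches++;
      const size_t d = (size_t)(i - 1) * W + (j - 1);
      state = best_state(M[d], X[d], Y[d]);
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      const size_t u = (size_t)(i - 1) * W + j;
      // predecessor achieving X[i][j]; opening from M or Y, extension from X
      state = best_state(M[u] + gap_open, X[u] + gap_ext, Y[u] + gap_open) ;
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      const size_t l = (size_t)i * W + (j - 1);
      state = best_state(M[l] + gap_open, X[l] + gap_open, Y[l] + gap_ext);
      --j;
    }
    res.columns++;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.aligned_a = ra;
  res.aligned_b = rb;
  return res;
}

static DPResult gotoh_local(const std::string &a, const std::string &b,
                            double match, double mismatch,
                            double gap_open, double gap_ext,
                            bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t W = (size_t)m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  for (int i = 0; i <= n; ++i) M[i * W] = 0.0;
  for (int j = 0; j <= m; ++j) M[j] = 0.0;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double prev = std::max(0.0, std::max(M[d], std::max(X[d], Y[d])));
      M[c] = prev + s;
      X[c] = std::max(M[u] + gap_open,
                      std::max(X[u] + gap_ext, Y[u] + gap_open));
      Y[c] = std::max(M[l] + gap_open,
                      std::max(X[l] + gap_open, Y[l] + gap_ext));
      // first strictly-best cell in row-major order wins (deterministic)
      if (M[c] > best + 1e-9) { best = M[c]; bi = i; bj = j; }
    }
  }
  DPResult res;
  res.score = best;
  res.matches = 0;
  res.columns = 0;
  if (!traceback || best <= 0.0) return res;

  std::string ra, rb;
  int i = bi, j = bj, state = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) res.matches++;
      res.columns++;
      const size_t d = (size_t)(i - 1) * W + (j - 1);
      double pm = M[d], px = X[d], py = Y[d];
      double pbest = std::max(pm, std::max(px, py));
      --i; --j;
      if (pbest <= eps) break;  // alignment started here
      state = best_state(pm, px, py);
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      res.columns++;
      const size_t u = (size_t)(i - 1) * W + j;
      state = best_state(M[u] + gap_open, X[u] + gap_ext, Y[u] + gap_open);
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      res.columns++;
      const size_t l = (size_t)i * W + (j - 1);
      state = best_state(M[l] + gap_open, X[l] + gap_open, Y[l] + gap_ext);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.aligned_a = ra;
  res.aligned_b = rb;
  return res;
}

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b, double match,
                     double mismatch, double gap_open, double gap_ext,
                     bool local, bool traceback) {
  DPResult r = local
    ? gotoh_local(a, b, match, mismatch, gap_open, gap_ext, traceback)
    : gotoh_global(a, b, match, mismatch, gap_open, gap_ext, traceback);
  return List::create(
      _["score"] = r.score,
      _["matches"] = traceback ? IntegerVector::create(r.matches)
                               : IntegerVector::create(NA_INTEGER),
      _["columns"] = traceback ? IntegerVector::create(r.columns)
                               : IntegerVector::create(NA_INTEGER),
      _["aligned_a"] = r.aligned_a,
      _["aligned_b"] = r.aligned_b);
}

// Batch score of one query against many references; used by the composite
// alignment score where only scores are needed.
// [[Rcpp::export(name = ".gotoh_scores_cpp")]]
NumericVector gotoh_scores_cpp(std::string a, CharacterVector refs,
                               double match, double mismatch,
                               double gap_open, double gap_ext, bool local) {
  const int nr = refs.size();
  NumericVector out(nr);
  for (int k = 0; k < nr; ++k) {
    std::string b = as<std::string>(refs[k]);
    DPResult r = local
      ? gotoh_local(a, b, match, mismatch, gap_open, gap_ext, false)
      : gotoh_global(a, b, match, mismatch, gap_open, gap_ext, false);
    out[k] = r.score;
  }
  return out;
}

// Batch global identity (matches / alignment columns) of one query against
// many references; drives MaxID computation.
// [[Rcpp::export(name = ".gotoh_identities_cpp")]]
List gotoh_identities_cpp(std::string a, CharacterVector refs, double match,
                          double mismatch, double gap_open, double gap_ext) {
  const int nr = refs.size();
  NumericVector ident(nr);
  IntegerVector matches(nr), columns(nr);
  for (int k = 0; k < nr; ++k) {
    std::string b = as<std::string>(refs[k]);
    DPResult r = gotoh_global(a, b, match, mismatch, gap_open, gap_ext, true);
    matches[k] = r.matches;
    columns[k] = r.columns;
    ident[k] = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
  }
  return List::create(_["identity"] = ident, _["matches"] = matches,
                      _["columns"] = columns);
}
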