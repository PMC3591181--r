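#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All chain dynamic programs run in log space; logsumexp guards against
// underflow on long sentences.
static inline double logsumexp(const double* v, int n) {
  double m = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Log-partition of a single sentence by the forward recursion.
// S: T x L matrix of per-position state scores; trans: L x L (from, to).
// [[Rcpp::export]]
double crf_logZ_cpp(const NumericMatrix& S, const NumericMatrix& trans) {
  const int T = S.nrow(), L = S.ncol();
  std::vector<double> alpha(L), prev(L), tmp(L);
  for (int l = 0; l < L; ++l) alpha[l] = S(0, l);
  for (int t = 1; t < T; ++t) {
    prev = alpha;
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = prev[i] + trans(i, j);
      alpha[j] = logsumexp(tmp.data(), L) + S(t, j);
    }
  }
  return logsumexp(alpha.data(), L);
}

// Per-position posterior marginals P(y_t = l | x) by forward-backward.
// [[Rcpp::export]]
NumericMatrix crf_marginals_cpp(const NumericMatrix& S, const NumericMatrix& trans) {
  const int T = S.nrow(), L = S.ncol();
  NumericMatrix alpha(T, L), beta(T, L), post(T, L);
  std::vector<double> tmp(L);
  for (int l = 0; l < L; ++l) alpha(0, l) = S(0, l);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha(t - 1, i) + trans(i, j);
      alpha(t, j) = logsumexp(tmp.data(), L) + S(t, j);
    }
  for (int l = 0; l < L; ++l) { tmp[l] = alpha(T - 1, l); beta(T - 1, l) = 0.0; }
  const double logZ = logsumexp(tmp.data(), L);
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < L; ++i) {
      for (int j = 0; j < L; ++j)
        tmp[j] = trans(i, j) + S(t + 1, j) + beta(t + 1, j);
      beta(t, i) = logsumexp(tmp.data(), L);
    }
  for (int t = 0; t < T; ++t)
    for (int l = 0; l < L; ++l)
      post(t, l) = std::exp(alpha(t, l) + beta(t, l) - logZ);
  return post;
}

// Batched negative log-likelihood pieces over a stacked corpus.
// S stacks the state-score rows of all sentences; start (0-based) and len
// delimit sentences; y holds 0-based observed labels per row.
// Returns total (logZ - gold score), per-row posteriors, and expected
// transition counts summed over all sentences and positions.
// [[Rcpp::export]]
List crf_batch_infer_cpp(const NumericMatrix& S, const NumericMatrix& trans,
                         const IntegerVector& start, const IntegerVector& len,
                         const IntegerVector& y) {
  const int L = S.ncol();
  const int n_sent = start.size();
  NumericMatrix post(S.nrow(), L);
  NumericMatrix transE(L, L);
  double nll = 0.0;
  std::vector<double> tmp(L);
  for (int s = 0; s < n_sent; ++s) {
    const int r0 = start[s], T = len[s];
    NumericMatrix alpha(T, L), beta(T, L);
    for (int l = 0; l < L; ++l) alpha(0, l) = S(r0, l);
    for (int t = 1; t < T; ++t)
      for (int j = 0; j < L; ++j) {
        for (int i = 0; i < L; ++i) tmp[i] = alpha(t - 1, i) + trans(i, j);
        alpha(t, j) = logsumexp(tmp.data(), L) + S(r0 + t, j);
      }
    for (int l = 0; l < L; ++l) { tmp[l] = alpha(T - 1, l); beta(T - 1, l) = 0.0; }
    const double logZ = logsumexp(tmp.data(), L);
    for (int t = T - 2; t >= 0; --t)
      for (int i = 0; i < L; ++i) {
        for (int j = 0; j < L; ++j)
          tmp[j] = trans(i, j) + S(r0 + t + 1, j) + beta(t + 1, j);
        beta(t, i) = logsumexp(tmp.data(), L);
      }
    for (int t = 0; t < T; ++t)
      for (int l = 0; l < L; ++l)
        post(r0 + t, l) = std::exp(alpha(t, l) + beta(t, l) - logZ);
    for (int t = 1; t < T; ++t)
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j)
          transE(i, j) += std::exp(alpha(t - 1, i) + trans(i, j) +
                                   S(r0 + t, j) + beta(t, j) - logZ);
    double sc = 0.0;
    for (int t = 0; t < T; ++t) sc += S(r0 + t, y[r0 + t]);
    for (int t = 1; t < T; ++t) sc += trans(y[r0 + t - 1], y[r0 + t]);
    nll += logZ - sc;
  }
  return List::create(_["nll"] = nll, _["post"] = post,
                      _["trans_expected"] = transE);
}

// Max-score path; ties broken toward the lowest label index by the strict
// comparisons in both the transition argmax and the final argmax.
// [[Rcpp::export]]
List crf_viterbi_cpp(const NumericMatrix& S, const NumericMatrix& trans) {
  const int T = S.nrow(), L = S.ncol();
  NumericMatrix delta(T, L);
  IntegerMatrix bp(T, L);
  for (int l = 0; l < L; ++l) delta(0, l) = S(0, l);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < L; ++j) {
      int arg = 0;
      double best = delta(t - 1, 0) + trans(0, j);
      for (int i = 1; i < L; ++i) {
        const double v = delta(t - 1, i) + trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + S(t, j);
      bp(t, j) = arg;
    }
  int argl = 0;
  double best = delta(T - 1, 0);
  for (int l = 1; l < L; ++l)
    if (delta(T - 1, l) > best) { best = delta(T - 1, l); argl = l; }
  IntegerVector path(T);
  path[T - 1] = argl;
  for (int t = T - 1; t > 0; --t) path[t - 1] = bp(t, path[t]);
  return List::create(_["path"] = path, _["score"] = best);
}
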