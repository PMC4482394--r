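#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward over independent per-chromosome chains.
// logE: N x S log emission densities; A: S x S transition matrix;
// chain_starts: 1-based first row of each chain. Each chain restarts with
// the uniform initial distribution. Returns posteriors gamma (rows sum to 1)
// and the total log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logE, NumericMatrix A, IntegerVector chain_starts) {
  const int N = logE.nrow(), S = logE.ncol();
  NumericMatrix gamma(N, S);
  double loglik = 0.0;

  std::vector<double> e(N * S);       // row-rescaled emissions
  std::vector<double> rowmax(N);
  for (int i = 0; i < N; ++i) {
    double m = R_NegInf;
    for (int s = 0; s < S; ++s) m = std::max(m, logE(i, s));
    if (!std::isfinite(m))
      stop("all emission densities are zero at probe row %d", i + 1);
    rowmax[i] = m;
    for (int s = 0; s < S; ++s) e[i * S + s] = std::exp(logE(i, s) - m);
  }

  std::vector<double> alpha(N * S), beta(N * S), c(N);
  const int nc = chain_starts.size();
  for (int ci = 0; ci < nc; ++ci) {
    const int i0 = chain_starts[ci] - 1;
    const int i1 = (ci + 1 < nc) ? chain_starts[ci + 1] - 1 : N;

    // forward
    double csum = 0.0;
    for (int s = 0; s < S; ++s) {
      alpha[i0 * S + s] = e[i0 * S + s] / S;
      csum += alpha[i0 * S + s];
    }
    c[i0] = csum;
    for (int s = 0; s < S; ++s) alpha[i0 * S + s] /= csum;
    loglik += std::log(csum) + rowmax[i0];

    for (int i = i0 + 1; i < i1; ++i) {
      csum = 0.0;
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int k = 0; k < S; ++k) acc += alpha[(i - 1) * S + k] * A(k, s);
        double v = acc * e[i * S + s];
        alpha[i * S + s] = v;
        csum += v;
      }
      if (csum <= 0.0)
        stop("forward pass underflow at probe row %d", i + 1);
      c[i] = csum;
      for (int s = 0; s < S; ++s) alpha[i * S + s] /= csum;
      loglik += std::log(csum) + rowmax[i];
    }

    // backward (scaled by the forward constants)
    for (int s = 0; s < S; ++s) beta[(i1 - 1) * S + s] = 1.0;
    for (int i = i1 - 2; i >= i0; --i) {
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int k = 0; k < S; ++k)
          acc += A(s, k) * e[(i + 1) * S + k] * beta[(i + 1) * S + k];
        beta[i * S + s] = acc / c[i + 1];
      }
    }

    for (int i = i0; i < i1; ++i) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        double g = alpha[i * S + s] * beta[i * S + s];
        gamma(i, s) = g;
        tot += g;
      }
      for (int s = 0; s < S; ++s) gamma(i, s) /= tot;
    }
  }

  return List::create(Named("gamma") = gamma, Named("loglik") = loglik);
}

// Viterbi decoding over independent chains (uniform initial distribution).
// [[Rcpp::export(name = ".viterbi_core")]]
IntegerVector viterbi_core(NumericMatrix logE, NumericMatrix A,
                           IntegerVector chain_starts) {
  const int N = logE.nrow(), S = logE.ncol();
  NumericMatrix logA(S, S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      logA(i, j) = std::log(A(i, j));

  IntegerVector path(N);
  std::vector<double> d(N * S);
  std::vector<int> bp(N * S);
  const int nc = chain_starts.size();
  for (int ci = 0; ci < nc; ++ci) {
    const int i0 = chain_starts[ci] - 1;
    const int i1 = (ci + 1 < nc) ? chain_starts[ci + 1] - 1 : N;
    for (int s = 0; s < S; ++s) d[i0 * S + s] = logE(i0, s) - std::log((double)S);
    for (int i = i0 + 1; i < i1; ++i) {
      for (int s = 0; s < S; ++s) {
        double best = R_NegInf; int arg = 0;
        for (int k = 0; k < S; ++k) {
          double v = d[(i - 1) * S + k] + logA(k, s);
          if (v > best) { best = v; arg = k; }
        }
        d[i * S + s] = best + logE(i, s);
        bp[i * S + s] = arg;
      }
    }
    double best = R_NegInf; int arg = 0;
    for (int s = 0; s < S; ++s)
      if (d[(i1 - 1) * S + s] > best) { best = d[(i1 - 1) * S + s]; arg = s; }
    path[i1 - 1] = arg + 1;
    for (int i = i1 - 1; i > i0; --i) {
      arg = bp[i * S + arg];
      path[i - 1] = arg + 1;
    }
  }
  return path;
}
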