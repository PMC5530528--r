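// Chain computations for the structured variational copy-number model:
// dense emission matrices and scaled forward-backward with pairwise
// marginal reductions. States are passed as an integer matrix with one row
// per state and interleaved (major, minor) columns per clone.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double nb_lpmf(double x, double mu, double size) {
  if (mu <= 0.0) return x == 0.0 ? 0.0 : R_NegInf;
  return R::dnbinom_mu(x, size, mu, 1);
}

static inline double pois_lpmf(double x, double mu) {
  if (mu <= 0.0) return x == 0.0 ? 0.0 : R_NegInf;
  return R::dpois(x, mu, 1);
}

static inline double bb_lpmf(double x, double n, double p, double rho,
                             double lchoose_nx) {
  if (p <= 0.0) return x == 0.0 ? 0.0 : R_NegInf;
  if (p >= 1.0) return x == n ? 0.0 : R_NegInf;
  if (rho <= 0.0) return lchoose_nx + x * std::log(p) + (n - x) * std::log1p(-p);
  double s = (1.0 - rho) / rho;
  double a = p * s, b = (1.0 - p) * s;
  return lchoose_nx + R::lbeta(x + a, n - x + b) - R::lbeta(a, b);
}

// Negative binomial log-pmf with the x-dependent lgamma terms hoisted:
// cnst = lgamma(x + r) - lgamma(r) - lgamma(x + 1).
static inline double nb_lpmf_fast(double x, double mu, double size,
                                  double cnst) {
  if (mu <= 0.0) return x == 0.0 ? 0.0 : R_NegInf;
  return cnst + size * std::log(size / (size + mu)) +
         x * std::log(mu / (size + mu));
}

// Emission log-likelihood matrix (segments x states).
// family: 0 = poisson, 1 = negbin, 2 = negbin mixture.
// The allele term is a symmetric phase mixture over the two assignments of
// state alleles to data alleles. outlierLogDens is per segment; the outlier
// component (weight wOut) is mixed into the combined emission.
// [[Rcpp::export]]
NumericMatrix cpp_emission_matrix(NumericVector x, NumericVector xa,
                                  NumericVector xb, NumericVector leff,
                                  IntegerMatrix states, NumericVector h,
                                  int family, NumericVector nbSize,
                                  double nbMixWeight, double alleleRho,
                                  double wOut, NumericVector outlierLogDens) {
  int N = x.size(), S = states.nrow(), M = states.ncol() / 2;
  if ((int)h.size() != M) stop("h length must match clone count");
  std::vector<double> hc(S), pa(S);
  for (int s = 0; s < S; ++s) {
    double num = 0.0, den = 0.0;
    for (int m = 0; m < M; ++m) {
      double a = states(s, 2 * m), b = states(s, 2 * m + 1);
      num += h[m] * a;
      den += h[m] * (a + b);
    }
    hc[s] = den;
    pa[s] = den > 0.0 ? num / den : 0.5;
  }
  double lw1 = 0.0, lw2 = R_NegInf;
  double r1 = nbSize.size() > 0 ? nbSize[0] : 1.0;
  double r2 = nbSize.size() > 1 ? nbSize[1] : r1;
  if (family == 2) {
    lw1 = std::log(1.0 - nbMixWeight);
    lw2 = nbMixWeight > 0.0 ? std::log(nbMixWeight) : R_NegInf;
  }
  double lkeep = wOut > 0.0 ? std::log(1.0 - wOut) : 0.0;
  double lout = wOut > 0.0 ? std::log(wOut) : R_NegInf;

  // beta-binomial per-state shape parameters and their lbeta normaliser
  double sBB = alleleRho > 0.0 ? (1.0 - alleleRho) / alleleRho : 0.0;
  std::vector<double> aBB(S), bBB(S), lbAB(S);
  bool binom = alleleRho <= 0.0;
  for (int s = 0; s < S; ++s) {
    double p = pa[s];
    if (!binom && p > 0.0 && p < 1.0) {
      aBB[s] = p * sBB;
      bBB[s] = (1.0 - p) * sBB;
      lbAB[s] = R::lbeta(aBB[s], bBB[s]);
    } else {
      aBB[s] = bBB[s] = lbAB[s] = 0.0;
    }
  }

  NumericMatrix out(N, S);
  double* o = REAL(out);
  double lgr1 = std::lgamma(r1), lgr2 = std::lgamma(r2);
  for (int n = 0; n < N; ++n) {
    double xn = x[n], xan = xa[n], xbn = xb[n];
    double nab = xan + xbn;
    double lch = nab > 0.0 ? R::lchoose(nab, xan) : 0.0;
    double ln = leff[n];
    double lgx1 = std::lgamma(xn + 1.0);
    double c1 = std::lgamma(xn + r1) - lgr1 - lgx1;
    double c2 = std::lgamma(xn + r2) - lgr2 - lgx1;
    double odn = outlierLogDens[n];
    for (int s = 0; s < S; ++s) {
      double mu = ln * hc[s];
      double tot;
      if (family == 0) tot = pois_lpmf(xn, mu);
      else if (family == 1) tot = nb_lpmf_fast(xn, mu, r1, c1);
      else tot = lse2(lw1 + nb_lpmf_fast(xn, mu, r1, c1),
                      lw2 + nb_lpmf_fast(xn, mu, r2, c2));
      double al = 0.0;
      if (nab > 0.0) {
        double p = pa[s];
        double l1, l2;
        if (binom || p <= 0.0 || p >= 1.0) {
          l1 = bb_lpmf(xan, nab, p, alleleRho, lch);
          l2 = bb_lpmf(xan, nab, 1.0 - p, alleleRho, lch);
        } else {
          double lgden = std::lgamma(nab + aBB[s] + bBB[s]);
          l1 = lch + std::lgamma(xan + aBB[s]) + std::lgamma(xbn + bBB[s]) -
               lgden - lbAB[s];
          l2 = lch + std::lgamma(xan + bBB[s]) + std::lgamma(xbn + aBB[s]) -
               lgden - lbAB[s];
        }
        al = lse2(l1, l2) - M_LN2;
      }
      double core = tot + al;
      o[n + (size_t)s * N] =
          wOut > 0.0 ? lse2(lkeep + core, lout + odn) : core;
    }
  }
  return out;
}

// Expected total-count log-likelihood under collapsed state weights:
// sum_n sum_j W[n,j] * log p(x_n | mu = leff_n * hc_j). Cells with
// negligible weight are skipped; the caller guards exactness separately.
// [[Rcpp::export]]
double cpp_weighted_total_loglik(NumericVector x, NumericVector leff,
                                 NumericVector hc, NumericMatrix W,
                                 int family, NumericVector nbSize,
                                 double nbMixWeight, double wOut,
                                 NumericVector outlierLogDens,
                                 double minWeight) {
  int N = x.size(), J = hc.size();
  if (W.nrow() != N || W.ncol() != J) stop("weight matrix shape mismatch");
  double r1 = nbSize.size() > 0 ? nbSize[0] : 1.0;
  double r2 = nbSize.size() > 1 ? nbSize[1] : r1;
  double lw1 = 0.0, lw2 = R_NegInf;
  if (family == 2) {
    lw1 = std::log(1.0 - nbMixWeight);
    lw2 = nbMixWeight > 0.0 ? std::log(nbMixWeight) : R_NegInf;
  }
  double lkeep = wOut > 0.0 ? std::log(1.0 - wOut) : 0.0;
  double lout = wOut > 0.0 ? std::log(wOut) : R_NegInf;
  double lgr1 = std::lgamma(r1), lgr2 = std::lgamma(r2);
  std::vector<double> c1(N), c2(N), lgx1(N);
  for (int n = 0; n < N; ++n) {
    lgx1[n] = std::lgamma(x[n] + 1.0);
    c1[n] = std::lgamma(x[n] + r1) - lgr1 - lgx1[n];
    c2[n] = std::lgamma(x[n] + r2) - lgr2 - lgx1[n];
  }
  const double* w = REAL(W);
  double acc = 0.0;
  for (int j = 0; j < J; ++j) {
    const double* wc = w + (size_t)j * N;
    for (int n = 0; n < N; ++n) {
      double wnj = wc[n];
      if (wnj < minWeight) continue;
      double mu = leff[n] * hc[j];
      double tot;
      if (family == 0) tot = pois_lpmf(x[n], mu);
      else if (family == 1) tot = nb_lpmf_fast(x[n], mu, r1, c1[n]);
      else tot = lse2(lw1 + nb_lpmf_fast(x[n], mu, r1, c1[n]),
                      lw2 + nb_lpmf_fast(x[n], mu, r2, c2[n]));
      double v = wOut > 0.0 ? lse2(lkeep + tot, lout + outlierLogDens[n]) : tot;
      acc += wnj * v;
    }
  }
  return acc;
}

// Scaled forward-backward on one chain.
//
// logEmit: N x S emission log-likelihoods.
// transMats / logTransMats: list of S x S transition factor matrices
//   (linear and log scale); transIdx (length N-1, 1-based) selects the
//   matrix of each boundary.
// pairBoundaries: 1-based boundary indices for which the full pairwise
//   marginal is returned.
//
// Returns gamma (N x S single marginals), logZ, eTrans = sum over all
// boundaries of E[log f] under the pairwise marginals, and the requested
// pairwise marginal matrices.
// [[Rcpp::export]]
List cpp_chain_fb(NumericMatrix logEmit, List transMats, List logTransMats,
                  IntegerVector transIdx, IntegerVector pairBoundaries) {
  int N = logEmit.nrow(), S = logEmit.ncol();
  if (N > 1 && transIdx.size() != N - 1) stop("need N-1 boundary transition indices");
  const double* le = REAL(logEmit);

  std::vector<double> emis((size_t)N * S), rowMax(N);
  for (int n = 0; n < N; ++n) {
    double m = R_NegInf;
    for (int s = 0; s < S; ++s) m = std::max(m, le[n + (size_t)s * N]);
    if (m == R_NegInf) stop("segment with no feasible state");
    rowMax[n] = m;
    for (int s = 0; s < S; ++s)
      emis[(size_t)n * S + s] = std::exp(le[n + (size_t)s * N] - m);
  }

  std::vector<double> alpha((size_t)N * S);
  double logZ = 0.0;
  {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) { alpha[s] = emis[s]; tot += alpha[s]; }
    if (tot <= 0.0) stop("forward pass underflow");
    for (int s = 0; s < S; ++s) alpha[s] /= tot;
    logZ += std::log(tot) + rowMax[0];
  }
  for (int n = 1; n < N; ++n) {
    const double* M = REAL((SEXP)transMats[transIdx[n - 1] - 1]);
    const double* ap = &alpha[(size_t)(n - 1) * S];
    double* an = &alpha[(size_t)n * S];
    const double* en = &emis[(size_t)n * S];
    double tot = 0.0;
    for (int j = 0; j < S; ++j) {
      const double* Mc = M + (size_t)j * S;
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += ap[i] * Mc[i];
      double v = acc * en[j];
      an[j] = v;
      tot += v;
    }
    if (tot <= 0.0) stop("forward pass underflow");
    for (int j = 0; j < S; ++j) an[j] /= tot;
    logZ += std::log(tot) + rowMax[n];
  }

  std::vector<int> pairPos(std::max(N - 1, 0), -1);
  for (int k = 0; k < pairBoundaries.size(); ++k) {
    int b = pairBoundaries[k] - 1;
    if (b < 0 || b >= N - 1) stop("pair boundary index out of range");
    pairPos[b] = k;
  }
  List pairOut(pairBoundaries.size());

  NumericMatrix gamma(N, S);
  double* g = REAL(gamma);
  std::vector<double> beta(S, 1.0), tmp(S), betaNew(S);
  double eTrans = 0.0;
  {
    const double* aN = &alpha[(size_t)(N - 1) * S];
    double tot = 0.0;
    for (int s = 0; s < S; ++s) tot += aN[s];
    for (int s = 0; s < S; ++s) g[(N - 1) + (size_t)s * N] = aN[s] / tot;
  }
  for (int n = N - 2; n >= 0; --n) {
    const double* M = REAL((SEXP)transMats[transIdx[n] - 1]);
    const double* LM = REAL((SEXP)logTransMats[transIdx[n] - 1]);
    const double* an = &alpha[(size_t)n * S];
    const double* en1 = &emis[(size_t)(n + 1) * S];
    for (int j = 0; j < S; ++j) tmp[j] = en1[j] * beta[j];
    bool keep = pairPos[n] >= 0;
    NumericMatrix P;
    double* Pp = nullptr;
    if (keep) { P = NumericMatrix(S, S); Pp = REAL(P); }
    double psum = 0.0, eAcc = 0.0;
    std::fill(betaNew.begin(), betaNew.end(), 0.0);
    for (int j = 0; j < S; ++j) {
      const double* Mc = M + (size_t)j * S;
      const double* Lc = LM + (size_t)j * S;
      double tj = tmp[j];
      double* Pc = keep ? Pp + (size_t)j * S : nullptr;
      for (int i = 0; i < S; ++i) {
        double mij = Mc[i];
        double v = an[i] * mij * tj;
        psum += v;
        eAcc += v * Lc[i];
        betaNew[i] += mij * tj;
        if (keep) Pc[i] = v;
      }
    }
    if (psum <= 0.0) stop("backward pass underflow");
    eTrans += eAcc / psum;
    if (keep) {
      for (size_t q = 0; q < (size_t)S * S; ++q) Pp[q] /= psum;
      pairOut[pairPos[n]] = P;
    }
    double btot = 0.0;
    for (int i = 0; i < S; ++i) btot += betaNew[i];
    if (btot <= 0.0) stop("backward pass underflow");
    double gtot = 0.0;
    for (int i = 0; i < S; ++i) {
      beta[i] = betaNew[i] / btot;
      gtot += an[i] * beta[i];
    }
    for (int i = 0; i < S; ++i) g[n + (size_t)i * N] = an[i] * beta[i] / gtot;
  }

  return List::create(_["gamma"] = gamma, _["logZ"] = logZ,
                      _["eTrans"] = eTrans, _["pairs"] = pairOut);
}
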