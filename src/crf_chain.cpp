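#include <Rcpp.h>
using namespace Rcpp;

// Linear-chain forward-backward in log space.
//
// logphi: L x D per-position emission log-potentials
// logpsi: D x D adjacent-pair log-potentials (position independent)
//
// Returns the log partition function, the log forward/backward tables,
// per-position posterior marginals and pairwise marginals summed over the
// L-1 adjacent pairs (the sufficient statistic for the transition gradient).
// All sums stay in log space so chains of thousands of residues with large
// potentials do not overflow.
// [[Rcpp::export(name = ".crfChain")]]
List crfChain(NumericMatrix logphi, NumericMatrix logpsi) {
  const int L = logphi.nrow(), D = logphi.ncol();
  if (logpsi.nrow() != D || logpsi.ncol() != D)
    stop("transition potential must be %d x %d", D, D);
  NumericMatrix la(L, D), lb(L, D), marg(L, D);
  NumericMatrix pair(D, D);

  for (int a = 0; a < D; ++a) la(0, a) = logphi(0, a);
  for (int i = 1; i < L; ++i) {
    for (int b = 0; b < D; ++b) {
      double m = R_NegInf;
      for (int a = 0; a < D; ++a) {
        double v = la(i - 1, a) + logpsi(a, b);
        if (v > m) m = v;
      }
      double s = 0.0;
      for (int a = 0; a < D; ++a)
        s += std::exp(la(i - 1, a) + logpsi(a, b) - m);
      la(i, b) = logphi(i, b) + m + std::log(s);
    }
  }

  double m = R_NegInf;
  for (int a = 0; a < D; ++a) if (la(L - 1, a) > m) m = la(L - 1, a);
  double s = 0.0;
  for (int a = 0; a < D; ++a) s += std::exp(la(L - 1, a) - m);
  const double logZ = m + std::log(s);
  if (!R_finite(logZ))
    stop("non-finite partition function on the chain");

  for (int a = 0; a < D; ++a) lb(L - 1, a) = 0.0;
  for (int i = L - 2; i >= 0; --i) {
    for (int a = 0; a < D; ++a) {
      double mm = R_NegInf;
      for (int b = 0; b < D; ++b) {
        double v = logpsi(a, b) + logphi(i + 1, b) + lb(i + 1, b);
        if (v > mm) mm = v;
      }
      double ss = 0.0;
      for (int b = 0; b < D; ++b)
        ss += std::exp(logpsi(a, b) + logphi(i + 1, b) + lb(i + 1, b) - mm);
      lb(i, a) = mm + std::log(ss);
    }
  }

  for (int i = 0; i < L; ++i)
    for (int a = 0; a < D; ++a) {
      marg(i, a) = std::exp(la(i, a) + lb(i, a) - logZ);
      if (!R_finite(marg(i, a)))
        stop("non-finite posterior marginal at position %d", i + 1);
    }

  for (int i = 0; i + 1 < L; ++i)
    for (int a = 0; a < D; ++a)
      for (int b = 0; b < D; ++b)
        pair(a, b) += std::exp(la(i, a) + logpsi(a, b) + logphi(i + 1, b) +
                               lb(i + 1, b) - logZ);

  return List::create(_["logZ"] = logZ,
                      _["logAlpha"] = la,
                      _["logBeta"] = lb,
                      _["nodeMarginals"] = marg,
                      _["pairMarginalSums"] = pair);
}
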