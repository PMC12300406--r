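#include <Rcpp.h>
using namespace Rcpp;

// Collapsed-state Gibbs sampler for the admixture model with independent
// Dirichlet(lambda) allele frequencies per cluster and Dirichlet(alpha)
// admixture proportions per individual.
//
// a1, a2: n x L integer matrices of allele *indices* (1..nAll[l]); 0 = missing
// (both copies missing together).  Missing copies are skipped everywhere.
//
// Sweep: (i) sample each observed allele copy's cluster of origin z given
// Q and P; (ii) sample P per cluster/locus from Dirichlet(lambda + counts);
// (iii) sample each Q row from Dirichlet(alpha + origin counts).  The data
// log-likelihood log prod_{ilc} sum_k Q[i,k] P[k,l,a] is recorded every
// sweep.  Q and P posterior means accumulate after burn-in.  All
// randomness comes from R's RNG, so set.seed() makes runs reproducible.

static inline double rgamma1(double shape) {
  double g = R::rgamma(shape, 1.0);
  return (g > 0.0) ? g : 1e-300;
}

// [[Rcpp::export(name = ".gibbs_admixture")]]
List gibbs_admixture(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector nAll, int K,
                     int burnin, int mcmc,
                     double alpha, double lambda) {
  const int n = a1.nrow(), L = a1.ncol();
  const int sweeps = burnin + mcmc;
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of accessions");

  // allele frequency blocks, one K x nAll[l] matrix per locus
  std::vector<NumericMatrix> P(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, nAll[l]);
    std::fill(P[l].begin(), P[l].end(), 1.0 / nAll[l]);
  }
  NumericMatrix Q(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);

  IntegerMatrix z1(n, L), z2(n, L);
  std::vector<NumericMatrix> Pcnt(L);
  for (int l = 0; l < L; ++l) Pcnt[l] = NumericMatrix(K, nAll[l]);
  NumericMatrix Qcnt(n, K);

  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, nAll[l]);

  NumericVector lnL(sweeps);
  std::vector<double> prob(K);

  for (int s = 0; s < sweeps; ++s) {
    // reset counts
    for (int l = 0; l < L; ++l)
      std::fill(Pcnt[l].begin(), Pcnt[l].end(), 0.0);
    std::fill(Qcnt.begin(), Qcnt.end(), 0.0);

    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = (c == 0) ? a1(i, l) : a2(i, l);
          if (a == 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[l](k, a - 1);
            tot += prob[k];
          }
          ll += std::log(tot);
          double u = unif_rand() * tot, acc = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { zk = k; break; }
          }
          if (c == 0) z1(i, l) = zk; else z2(i, l) = zk;
          Pcnt[l](zk, a - 1) += 1.0;
          Qcnt(i, zk) += 1.0;
        }
      }
    }
    lnL[s] = ll;

    // P | z  ~ Dirichlet(lambda + counts), per cluster and locus
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < K; ++k) {
        double tot = 0.0;
        for (int a = 0; a < nAll[l]; ++a) {
          double g = rgamma1(lambda + Pcnt[l](k, a));
          P[l](k, a) = g;
          tot += g;
        }
        for (int a = 0; a < nAll[l]; ++a) P[l](k, a) /= tot;
      }
    }
    // Q | z ~ Dirichlet(alpha + origin counts), per individual
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = rgamma1(alpha + Qcnt(i, k));
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= tot;
    }

    if (s >= burnin) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int a = 0; a < nAll[l]; ++a) Psum[l](k, a) += P[l](k, a);
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= mcmc;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < nAll[l]; ++a) Psum[l](k, a) /= mcmc;
    Pout[l] = Psum[l];
  }
  return List::create(_["Q"] = Qsum, _["P_hat"] = Pout,
                      _["lnL_trace"] = lnL);
}
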