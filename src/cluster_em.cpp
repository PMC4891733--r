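#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for the haplotype-cluster hidden Markov model.
//
// Hidden state z_l in 1..K per haplotype; initial distribution alpha;
// transition between adjacent loci: stay with probability 1 - rho_l, else
// jump to a cluster drawn from alpha (jumping back to the same cluster is a
// valid jump).  Emission at locus l from cluster k is Bernoulli(theta[l,k]).
//
// Returns the total log-likelihood plus the expected sufficient statistics
// needed by the M-step, and per-locus posterior cluster frequencies pooled
// within each population (for hapFLK).
//
// H:     n x L integer matrix of 0/1 alleles (no missing values)
// theta: L x K allele frequencies per cluster
// alpha: K cluster weights (sums to 1)
// rho:   L-1 jump probabilities per inter-locus interval
// pop:   length-n integer population index, 1-based, in 1..npop
// [[Rcpp::export(name = ".cluster_em_estep")]]
List cluster_em_estep(IntegerMatrix H, NumericMatrix theta,
                      NumericVector alpha, NumericVector rho,
                      IntegerVector pop, int npop) {
  const int n = H.nrow(), L = H.ncol(), K = theta.ncol();
  if (theta.nrow() != L) stop("theta must be L x K");
  if ((int)rho.size() != L - 1) stop("rho must have length L-1");
  if ((int)pop.size() != n) stop("pop must have length n");

  // emission probabilities per locus, layout [l][k] for allele 1 (th) —
  // allele 0 is 1 - th; contiguous in k
  std::vector<double> th((size_t)L * K);
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k) th[(size_t)l * K + k] = theta(l, k);

  // forward variables, layout [l][h][k] (contiguous in k), scaled per row
  std::vector<double> fwd((size_t)L * n * K);
  std::vector<double> scal((size_t)L * n);
  NumericMatrix thnum(L, K), thden(L, K);
  NumericMatrix jump_in(std::max(L - 1, 1), K);
  NumericVector njump(std::max(L - 1, 1));
  NumericVector init_counts(K);
  NumericVector popfreq((size_t)L * K * npop);  // dim (K, npop, L)
  const double *al = alpha.begin();
  double loglik = 0.0;

  // ---- forward pass
  for (int h = 0; h < n; ++h) {
    double *f = &fwd[(size_t)h * K];
    const double *t0 = &th[0];
    const int g = H(h, 0);
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = g ? t0[k] : 1.0 - t0[k];
      f[k] = al[k] * e;
      s += f[k];
    }
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k) f[k] *= inv;
    scal[h] = s;
    loglik += std::log(s);
  }
  for (int l = 1; l < L; ++l) {
    const double r = rho[l - 1], stay = 1.0 - r;
    const double *tl = &th[(size_t)l * K];
    for (int h = 0; h < n; ++h) {
      const double *fp = &fwd[((size_t)(l - 1) * n + h) * K];
      double *f = &fwd[((size_t)l * n + h) * K];
      const int g = H(h, l);
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = g ? tl[k] : 1.0 - tl[k];
        f[k] = (stay * fp[k] + r * al[k]) * e;
        s += f[k];
      }
      const double inv = 1.0 / s;
      for (int k = 0; k < K; ++k) f[k] *= inv;
      scal[(size_t)l * n + h] = s;
      loglik += std::log(s);
    }
  }

  // ---- backward pass with accumulation of posteriors and jump counts
  std::vector<double> bwd((size_t)n * K, 1.0), tmp(K);
  std::vector<int> popn(npop, 0);
  for (int h = 0; h < n; ++h) popn[pop[h] - 1]++;

  // locus L-1 posteriors (bwd = 1)
  {
    const int l = L - 1;
    for (int h = 0; h < n; ++h) {
      const double *f = &fwd[((size_t)l * n + h) * K];
      const int g = H(h, l), p = pop[h] - 1;
      double *pf = &popfreq[((size_t)l * npop + p) * K];
      for (int k = 0; k < K; ++k) {
        thden(l, k) += f[k];
        if (g) thnum(l, k) += f[k];
        pf[k] += f[k];
      }
    }
  }
  for (int l = L - 2; l >= 0; --l) {
    const double r = rho[l], stay = 1.0 - r;
    const double *tl1 = &th[(size_t)(l + 1) * K];
    for (int h = 0; h < n; ++h) {
      double *b = &bwd[(size_t)h * K];
      const int g1 = H(h, l + 1);
      const double invc = 1.0 / scal[(size_t)(l + 1) * n + h];
      double dot = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = g1 ? tl1[k] : 1.0 - tl1[k];
        double t = b[k] * e * invc;
        tmp[k] = t;
        dot += al[k] * t;
      }
      // expected jumps into k over the interval l -> l+1
      for (int k = 0; k < K; ++k) {
        double j = r * al[k] * tmp[k];
        jump_in(l, k) += j;
        njump[l] += j;
        b[k] = stay * tmp[k] + r * dot;
      }
      const double *f = &fwd[((size_t)l * n + h) * K];
      const int g = H(h, l), p = pop[h] - 1;
      double *pf = &popfreq[((size_t)l * npop + p) * K];
      for (int k = 0; k < K; ++k) {
        double gm = f[k] * b[k];
        thden(l, k) += gm;
        if (g) thnum(l, k) += gm;
        pf[k] += gm;
      }
    }
  }
  for (int h = 0; h < n; ++h) {
    const double *f = &fwd[(size_t)h * K];
    const double *b = &bwd[(size_t)h * K];
    for (int k = 0; k < K; ++k) init_counts[k] += f[k] * b[k];
  }

  // normalise population cluster frequencies by population size
  for (int l = 0; l < L; ++l)
    for (int p = 0; p < npop; ++p)
      if (popn[p] > 0) {
        double *pf = &popfreq[((size_t)l * npop + p) * K];
        for (int k = 0; k < K; ++k) pf[k] /= popn[p];
      }

  popfreq.attr("dim") = IntegerVector::create(K, npop, L);
  return List::create(_["loglik"] = loglik, _["thnum"] = thnum,
                      _["thden"] = thden, _["init_counts"] = init_counts,
                      _["jump_in"] = jump_in, _["njump"] = njump,
                      _["popfreq"] = popfreq);
}
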