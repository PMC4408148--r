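// Collapsed-free Gibbs sampler for the admixture model: latent source
// cluster Z per gene copy, cluster allele frequencies P with a
// Dirichlet(lambda) prior, individual ancestry Q with a Dirichlet(alpha)
// prior. Uses R's RNG so results are reproducible from set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static int sample_discrete(const double *w, int K, double tot) {
  double u = unif_rand() * tot;
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u <= c) return k;
  }
  return K - 1;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int n_sweeps, int burn_in,
                         double alpha, double lambda, bool update_alpha) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 * n_loci columns");
  if (K < 1) stop("K must be >= 1");
  if (n_sweeps <= burn_in) stop("n_sweeps must exceed burn_in");

  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int totA = off[L];

  NumericMatrix P(K, totA), Q(n, K);
  NumericMatrix Psum(K, totA), Qsum(n, K);
  NumericMatrix cntP(K, totA), cntQ(n, K);
  for (int l = 0; l < L; ++l)
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a)
        P(k, off[l] + a) = 1.0 / n_alleles[l];
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  const int retained = n_sweeps - burn_in;
  NumericVector trace(retained);
  double alpha_sum = 0.0;
  std::vector<double> w(K);

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    // (i) latent source clusters
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P(k, off[l] + a);
            tot += w[k];
          }
          int z = (tot > 0.0) ? sample_discrete(w.data(), K, tot)
                              : (int)(unif_rand() * K);
          if (z >= K) z = K - 1;
          cntP(z, off[l] + a) += 1.0;
          cntQ(i, z) += 1.0;
        }
      }
    }
    // (ii) cluster allele frequencies
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(lambda + cntP(k, off[l] + a), 1.0);
          P(k, off[l] + a) = g;
          s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P(k, off[l] + a) /= s;
      }
    }
    // (iii) ancestry proportions
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ(i, k), 1.0);
        Q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }
    // (iv) optional Metropolis update of the ancestry hyperparameter:
    // symmetric Dirichlet(alpha) prior on each q_i, uniform prior on
    // alpha over (0, 10), log-normal random-walk proposal.
    if (update_alpha && K > 1) {
      double slq = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
      double prop = alpha * std::exp(0.2 * norm_rand());
      if (prop > 0.0 && prop < 10.0) {
        double ll_cur = n * (R::lgammafn(K * alpha) -
                             K * R::lgammafn(alpha)) + (alpha - 1.0) * slq;
        double ll_prop = n * (R::lgammafn(K * prop) -
                              K * R::lgammafn(prop)) + (prop - 1.0) * slq;
        // include the log-normal proposal asymmetry (Jacobian)
        double lr = ll_prop - ll_cur + std::log(prop) - std::log(alpha);
        if (std::log(unif_rand()) < lr) alpha = prop;
      }
    }
    if (sweep >= burn_in) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            double m = 0.0;
            for (int k = 0; k < K; ++k) m += Q(i, k) * P(k, off[l] + a);
            ll += std::log(m);
          }
        }
      }
      trace[sweep - burn_in] = ll;
      alpha_sum += alpha;
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < totA; ++a) Psum(k, a) += P(k, a);
      }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
    }
  }
  for (int k = 0; k < K; ++k)
    for (int a = 0; a < totA; ++a) Psum(k, a) /= retained;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= retained;
  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["offsets"] = wrap(off), _["loglik"] = trace,
                      _["alpha_mean"] = alpha_sum / retained);
}
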