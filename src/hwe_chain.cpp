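#include <Rcpp.h>
using namespace Rcpp;

// Metropolis chain over heterozygote counts for the biallelic
// Hardy-Weinberg exact test, conditional on allele counts. The state h is
// the number of heterozygotes; proposals move h by +/-2 (the biallelic
// reduction of genotype-table switch moves). Uses R's RNG so set.seed()
// controls the chain. Returns counts of states with conditional
// probability <= / < that of the observed table, plus 100 batch sums of
// the <= indicator for a batch-means standard error.
static inline double log_prob(int h, int nA, int n) {
  // pi(h) proportional to 2^h / (nAA! h! naa!), nAA = (nA - h)/2
  int nAA = (nA - h) / 2;
  int naa = n - nAA - h;
  return h * M_LN2 - lgamma(nAA + 1.0) - lgamma(h + 1.0) - lgamma(naa + 1.0);
}

// [[Rcpp::export(name = ".hwe_chain_cpp")]]
List hwe_chain_cpp(int nAA, int nAa, int naa, double chain_length) {
  int n = nAA + nAa + naa;
  int nA = 2 * nAA + nAa;                       // alt allele count
  int hmax = std::min(nA, 2 * n - nA);
  double lp_obs = log_prob(nAa, nA, n);
  const double tol = 1e-9;

  long steps = (long)chain_length;
  int n_batch = 100;
  long batch_size = steps / n_batch;
  if (batch_size < 1) { batch_size = 1; n_batch = (int)steps; }
  NumericVector batch(n_batch);

  RNGScope scope;
  int h = nAa;
  double lp = lp_obs;
  long n_leq = 0, n_lt = 0;
  long done = 0;
  for (int b = 0; b < n_batch; b++) {
    long this_batch = (b == n_batch - 1) ? (steps - done) : batch_size;
    long leq_b = 0;
    for (long t = 0; t < this_batch; t++) {
      int prop = h + ((unif_rand() < 0.5) ? 2 : -2);
      if (prop >= 0 && prop <= hmax) {
        double lp_new = log_prob(prop, nA, n);
        if (lp_new >= lp || unif_rand() < exp(lp_new - lp)) {
          h = prop;
          lp = lp_new;
        }
      }
      if (lp <= lp_obs + tol) { n_leq++; leq_b++; }
      if (lp <  lp_obs - tol) n_lt++;
    }
    batch[b] = (double)leq_b / (double)this_batch;
    done += this_batch;
  }
  return List::create(_["n_leq"] = (double)n_leq, _["n_lt"] = (double)n_lt,
                      _["steps"] = (double)done, _["batch_means"] = batch);
}
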