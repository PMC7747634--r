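#include <Rcpp.h>
using namespace Rcpp;

// One-birth-one-death (Moran) local community dynamics with immigration.
//
// Each step: a uniformly chosen individual dies; with probability m it is
// replaced by an immigrant drawn from the metacommunity pool, otherwise by
// the offspring of another uniformly chosen local individual. Uses R's RNG
// so results are reproducible under set.seed().
//
// pool: immigrant source probabilities (summing to 1)
// init: starting counts per species (length(pool)), summing to N
// m:    immigration probability per replacement, in (0, 1]
// steps: number of death-birth events
// [[Rcpp::export]]
IntegerVector moran_sim(NumericVector pool, IntegerVector init, double m,
                        double steps) {
  const int S = pool.size();
  if (init.size() != S) stop("init and pool lengths differ");
  long long N = 0;
  for (int s = 0; s < S; ++s) {
    if (init[s] < 0) stop("negative initial count");
    N += init[s];
  }
  if (N < 1) stop("empty community");

  // cumulative immigrant pool for inverse-CDF draws
  std::vector<double> cum(S);
  double tot = 0.0;
  for (int s = 0; s < S; ++s) {
    if (pool[s] < 0) stop("negative pool probability");
    tot += pool[s];
    cum[s] = tot;
  }
  if (tot <= 0) stop("pool sums to zero");
  for (int s = 0; s < S; ++s) cum[s] /= tot;
  cum[S - 1] = 1.0; // guard against round-off

  // explicit individual array: O(1) death and local birth
  std::vector<int> ind(static_cast<size_t>(N));
  size_t k = 0;
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < init[s]; ++c) ind[k++] = s;

  const long long nsteps = static_cast<long long>(steps);
  for (long long t = 0; t < nsteps; ++t) {
    size_t die = static_cast<size_t>(unif_rand() * N);
    if (die >= ind.size()) die = ind.size() - 1;
    int sp;
    if (unif_rand() < m) {
      double u = unif_rand();
      // binary search over cumulative pool
      int lo = 0, hi = S - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      sp = lo;
    } else {
      size_t par = static_cast<size_t>(unif_rand() * N);
      if (par >= ind.size()) par = ind.size() - 1;
      sp = ind[par];
    }
    ind[die] = sp;
  }

  IntegerVector out(S);
  for (size_t i = 0; i < ind.size(); ++i) out[ind[i]] += 1;
  return out;
}
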