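#include <Rcpp.h>
using namespace Rcpp;

// Moran (single death-birth) neutral dynamics for one local community.
//
// Each step removes one uniformly chosen individual; with probability m the
// vacancy is filled by an immigrant drawn from the metacommunity (prob
// proportional to gamma), otherwise by a local birth proportional to the
// post-death local abundances. Uses R's RNG so set.seed() governs the draw.
//
// counts: initial abundances (sum N), gamma: metacommunity relative
// abundances, m: immigration probability, steps: number of death-birth events.
// [[Rcpp::export]]
IntegerVector moran_step_cpp(IntegerVector counts, NumericVector gamma,
                             double m, double steps) {
  int S = counts.size();
  if (gamma.size() != S) stop("counts and gamma lengths differ");
  std::vector<double> cnt(counts.begin(), counts.end());
  double N = 0.0;
  for (int i = 0; i < S; ++i) N += cnt[i];
  if (N < 1) stop("empty community");

  // cumulative gamma for O(log S) immigrant draws
  std::vector<double> cum(S);
  double g = 0.0;
  for (int i = 0; i < S; ++i) { g += gamma[i]; cum[i] = g; }

  long long nsteps = (long long) steps;
  for (long long t = 0; t < nsteps; ++t) {
    // death: individual uniform => taxon proportional to counts
    double u = unif_rand() * N;
    int dead = 0;
    double acc = cnt[0];
    while (u > acc && dead < S - 1) acc += cnt[++dead];
    cnt[dead] -= 1.0;

    int born;
    if (unif_rand() < m) {
      double v = unif_rand() * g;
      born = (int)(std::lower_bound(cum.begin(), cum.end(), v) - cum.begin());
      if (born >= S) born = S - 1;
    } else {
      // local birth from the N-1 survivors
      double w = unif_rand() * (N - 1.0);
      born = 0;
      double acc2 = cnt[0];
      while (w > acc2 && born < S - 1) acc2 += cnt[++born];
    }
    cnt[born] += 1.0;
  }

  IntegerVector out(S);
  for (int i = 0; i < S; ++i) out[i] = (int) cnt[i];
  return out;
}
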