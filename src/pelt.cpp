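#include <Rcpp.h>
using namespace Rcpp;

// Penalised exact changepoint search (PELT) with an L2 segment cost and a
// minimum segment length. Returns 1-based indices of segment end positions
// (the last one is always length(y)). Pruning uses the standard condition
// F(s) + C(s+1..t) <= F(t), valid for additive costs with K = 0.
// [[Rcpp::export(name = ".pelt_l2")]]
IntegerVector pelt_l2(NumericVector y, double penalty, int minseg = 3) {
  const int n = y.size();
  if (n < 2 * minseg) {
    return IntegerVector::create(n);
  }
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + y[i];
    cs2[i + 1] = cs2[i] + y[i] * y[i];
  }
  // F[t]: optimal cost of y[1..t] (+penalty per segment); cp[t]: previous end.
  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> cp(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);
  for (int t = minseg; t <= n; ++t) {
    double best = R_PosInf;
    int best_s = 0;
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      if (t - s < minseg) continue;
      const double len = t - s;
      const double sum = cs[t] - cs[s];
      const double cost = (cs2[t] - cs2[s]) - sum * sum / len;
      const double val = F[s] + cost + penalty;
      if (val < best) { best = val; best_s = s; }
    }
    F[t] = best;
    cp[t] = best_s;
    // prune
    std::vector<int> keep;
    keep.reserve(cand.size() + 1);
    for (size_t k = 0; k < cand.size(); ++k) {
      const int s = cand[k];
      if (t - s < minseg) { keep.push_back(s); continue; }
      const double len = t - s;
      const double sum = cs[t] - cs[s];
      const double cost = (cs2[t] - cs2[s]) - sum * sum / len;
      if (F[s] + cost <= F[t]) keep.push_back(s);
    }
    const int new_cand = t - minseg + 1;
    if (new_cand >= minseg) keep.push_back(new_cand);
    cand.swap(keep);
  }
  std::vector<int> ends;
  int t = n;
  while (t > 0) {
    ends.push_back(t);
    t = cp[t];
  }
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
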