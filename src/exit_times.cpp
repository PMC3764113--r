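#include <Rcpp.h>
using namespace Rcpp;

// First upward crossing times. For each start t (0-based, t = 0..n-2):
//   out[t] = min{ dt >= 1 : x[t + dt] >= x[t] + rho },  NA when censored.
// Downward crossings are obtained by the caller via x -> -x.
//
// Right-to-left scan with a monotone staircase of candidate indices: an index j
// is kept only while no nearer index j' < j has x[j'] >= x[j] (such a j' answers
// every query j would). Values along the stack are therefore strictly
// decreasing towards the nearest index, so each query is a binary search for
// the nearest candidate at or above x[t] + rho. O(n log n) overall.
// [[Rcpp::export(name = ".exit_times_up")]]
IntegerVector exit_times_up(NumericVector x, double rho) {
  const int n = x.size();
  if (n < 2) stop("series must have at least 2 points");
  IntegerVector out(n - 1, NA_INTEGER);
  std::vector<int> si;    // candidate indices; nearest (smallest) at the back
  std::vector<double> sv; // their values; strictly decreasing front -> back
  si.reserve(n);
  sv.reserve(n);
  si.push_back(n - 1);
  sv.push_back(x[n - 1]);
  for (int t = n - 2; t >= 0; --t) {
    const double theta = x[t] + rho;
    if (sv.front() >= theta) {
      // largest position p with sv[p] >= theta == nearest qualifying index
      int lo = 0, hi = (int)sv.size() - 1;
      while (lo < hi) {
        int mid = (lo + hi + 1) / 2;
        if (sv[mid] >= theta) lo = mid; else hi = mid - 1;
      }
      out[t] = si[lo] - t;
    }
    while (!sv.empty() && sv.back() <= x[t]) {
      sv.pop_back();
      si.pop_back();
    }
    si.push_back(t);
    sv.push_back(x[t]);
  }
  return out;
}
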