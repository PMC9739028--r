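// Run-length block filter for binary contact sequences: merge interior
// zero-gaps strictly shorter than max_gap, then drop one-blocks not strictly
// longer than min_block.  Two passes over explicit run-length encodings.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_filter_blocks(Rcpp::IntegerVector x, int max_gap,
                                      int min_block) {
  const int n = x.size();
  Rcpp::IntegerVector y(Rcpp::clone(x));
  if (n == 0) return y;

  // run starts/values of y
  std::vector<int> start, val;
  for (int k = 0; k < n; ++k) {
    if (k == 0 || y[k] != y[k - 1]) {
      start.push_back(k);
      val.push_back(y[k]);
    }
  }
  start.push_back(n);

  // stage 1: interior zero-runs shorter than max_gap flanked by one-runs
  const int nr = (int)val.size();
  for (int r = 1; r + 1 < nr; ++r) {
    if (val[r] == 0 && val[r - 1] == 1 && val[r + 1] == 1 &&
        (start[r + 1] - start[r]) < max_gap) {
      for (int k = start[r]; k < start[r + 1]; ++k) y[k] = 1;
    }
  }

  // stage 2: recompute runs, drop short one-blocks
  start.clear();
  val.clear();
  for (int k = 0; k < n; ++k) {
    if (k == 0 || y[k] != y[k - 1]) {
      start.push_back(k);
      val.push_back(y[k]);
    }
  }
  start.push_back(n);
  for (size_t r = 0; r < val.size(); ++r) {
    if (val[r] == 1 && (start[r + 1] - start[r]) <= min_block) {
      for (int k = start[r]; k < start[r + 1]; ++k) y[k] = 0;
    }
  }
  return y;
}
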