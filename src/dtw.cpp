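#include <Rcpp.h>
using namespace Rcpp;

// Cumulative DTW cost under the standard monotonicity/continuity/boundary
// constraints: W(1,1) = local(1,1);
// W(t,j) = local(t,j) + min(W(t-1,j), W(t,j-1), W(t-1,j-1)).
// [[Rcpp::export]]
NumericMatrix dtw_accumulate_cpp(NumericMatrix local) {
  int n = local.nrow(), m = local.ncol();
  NumericMatrix W(n, m);
  W(0, 0) = local(0, 0);
  for (int j = 1; j < m; ++j) W(0, j) = local(0, j) + W(0, j - 1);
  for (int t = 1; t < n; ++t) {
    W(t, 0) = local(t, 0) + W(t - 1, 0);
    for (int j = 1; j < m; ++j) {
      double best = W(t - 1, j);
      if (W(t, j - 1) < best) best = W(t, j - 1);
      if (W(t - 1, j - 1) < best) best = W(t - 1, j - 1);
      W(t, j) = local(t, j) + best;
    }
  }
  return W;
}

// One new row of the cumulative matrix from the previous row (empty vector
// for the boundary row) and the new row of local costs.
// [[Rcpp::export]]
NumericVector dtw_next_row_cpp(NumericVector prev, NumericVector local) {
  int m = local.size();
  NumericVector row(m);
  if (prev.size() == 0) {
    row[0] = local[0];
    for (int j = 1; j < m; ++j) row[j] = local[j] + row[j - 1];
  } else {
    row[0] = local[0] + prev[0];
    for (int j = 1; j < m; ++j) {
      double best = prev[j];
      if (row[j - 1] < best) best = row[j - 1];
      if (prev[j - 1] < best) best = prev[j - 1];
      row[j] = local[j] + best;
    }
  }
  return row;
}
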