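#include <Rcpp.h>
using namespace Rcpp;

// All routines draw from R's RNG (RNGScope via Rcpp attributes), so set.seed()
// on the R side governs them. Bases are coded 0..3 = A,C,G,T; a length-m
// context is its lexicographic index in 0..4^m-1.

static inline int draw_categorical(const double *cum, int n) {
  double u = unif_rand();
  for (int i = 0; i < n - 1; ++i)
    if (u <= cum[i]) return i;
  return n - 1;
}

// Simulate one sequence of `len` bases from an order-`order` chain.
// init_cum: cumulative probabilities over the 4^order initial contexts;
// trans_cum: 4^order x 4 matrix of cumulative transition probabilities.
// [[Rcpp::export]]
IntegerVector mc_simulate_bases(NumericVector init_cum, NumericMatrix trans_cum,
                                int order, int len) {
  const int nctx = trans_cum.nrow();
  IntegerVector out(len);
  int ctx = 0;
  if (order > 0) {
    ctx = draw_categorical(init_cum.begin(), nctx);
    int c = ctx;
    for (int j = order - 1; j >= 0; --j) {
      if (j < len) out[j] = c % 4;
      c /= 4;
    }
    if (order >= len) return out;
  }
  const int mask = nctx / 4; // 4^(order-1), or 0 when order == 0
  std::vector<double> row(4);
  for (int i = (order > 0 ? order : 0); i < len; ++i) {
    for (int b = 0; b < 4; ++b) row[b] = trans_cum(ctx, b);
    int b = draw_categorical(row.data(), 4);
    out[i] = b;
    if (order > 0) ctx = (ctx % mask) * 4 + b;
  }
  return out;
}

// Simulate `nsim` sequences of length `len` and return the number of
// (overlapping) occurrences of `word` (0..3 coded) in each -- the
// Monte-Carlo oracle for E(N_w) and sigma(N_w).
// [[Rcpp::export]]
IntegerVector mc_simulate_word_counts(NumericVector init_cum,
                                      NumericMatrix trans_cum, int order,
                                      int len, IntegerVector word, int nsim) {
  const int nctx = trans_cum.nrow();
  const int mask = nctx / 4;
  const int k = word.size();
  IntegerVector counts(nsim);
  std::vector<int> seq(len);
  std::vector<double> row(4);
  for (int s = 0; s < nsim; ++s) {
    int ctx = 0;
    int start = 0;
    if (order > 0) {
      ctx = draw_categorical(init_cum.begin(), nctx);
      int c = ctx;
      for (int j = order - 1; j >= 0; --j) { seq[j] = c % 4; c /= 4; }
      start = order;
    }
    for (int i = start; i < len; ++i) {
      for (int b = 0; b < 4; ++b) row[b] = trans_cum(ctx, b);
      int b = draw_categorical(row.data(), 4);
      seq[i] = b;
      if (order > 0) ctx = (ctx % mask) * 4 + b;
    }
    int n = 0;
    for (int i = 0; i + k <= len; ++i) {
      bool hit = true;
      for (int j = 0; j < k; ++j)
        if (seq[i + j] != word[j]) { hit = false; break; }
      if (hit) ++n;
    }
    counts[s] = n;
  }
  return counts;
}
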