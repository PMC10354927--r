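#include <Rcpp.h>
using namespace Rcpp;

// Simulate a DNA sequence from an order-k Markov chain.
//
// cumprob: (4^k) x 4 matrix of cumulative transition probabilities; row r
// is the context whose base-4 encoding (A=0, C=1, G=2, T=3, most significant
// base first) equals r.  Draws use R's RNG so results respect set.seed().
// Returns an integer vector of base codes 0..3 of length n (n >= k; the
// first k bases are drawn uniformly).
// [[Rcpp::export(name = ".markov_sequence")]]
IntegerVector markov_sequence(int n, NumericMatrix cumprob, int k) {
  if (n < k) stop("sequence length must be at least the Markov order");
  int ncontext = cumprob.nrow();
  IntegerVector out(n);
  int ctx = 0;
  for (int i = 0; i < k; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    out[i] = b;
    ctx = (ctx * 4 + b) % ncontext;
  }
  int mask = ncontext / 4;  // drop the most significant base when shifting
  for (int i = k; i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > cumprob(ctx, b)) ++b;
    out[i] = b;
    ctx = (ctx % mask) * 4 + b;
  }
  return out;
}
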