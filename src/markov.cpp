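// First-order Markov sequence generation. Uses R's RNG (unif_rand) so that
// generation stays inside the caller's set.seed() stream and remains
// reproducible together with the R-level sampling around it.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
std::string cpp_markov_seq(int L, NumericMatrix cum, NumericVector cum_init,
                           std::string alphabet) {
  std::string out(L, 'A');
  const int k = cum_init.size();
  double u = unif_rand();
  int cur = 0;
  while (cur < k - 1 && u > cum_init[cur]) ++cur;
  out[0] = alphabet[cur];
  for (int i = 1; i < L; ++i) {
    u = unif_rand();
    int nxt = 0;
    while (nxt < k - 1 && u > cum(cur, nxt)) ++nxt;
    out[i] = alphabet[nxt];
    cur = nxt;
  }
  return out;
}
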