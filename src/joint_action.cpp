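#include <Rcpp.h>
using namespace Rcpp;

// Olmstead cassette-model effects for a block of samples.
//
// conc:     samples x features matrix of nonnegative concentrations
// ec50:     per-feature potency (length = ncol(conc), all > 0)
// power:    per-cassette slope exponent (length = number of cassettes)
// cassette: 1-based cassette label per feature
//
// Per cassette g: S_g = sum_{i in g} c_i / EC50_i, E_g = S_g^P_g / (1 + S_g^P_g)
// (concentration addition within the cassette); across cassettes the
// surviving fractions multiply (response addition): E = 1 - prod_g (1 - E_g).
// [[Rcpp::export]]
NumericVector olmstead_effect_cpp(const NumericMatrix& conc,
                                  const NumericVector& ec50,
                                  const NumericVector& power,
                                  const IntegerVector& cassette) {
  const int n = conc.nrow(), m = conc.ncol(), k = power.size();
  if (ec50.size() != m || cassette.size() != m)
    stop("length mismatch between concentrations, potencies and cassettes");
  NumericVector out(n);
  std::vector<double> S(k);
  for (int s = 0; s < n; ++s) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int j = 0; j < m; ++j)
      S[cassette[j] - 1] += conc(s, j) / ec50[j];
    double surv = 1.0;
    for (int g = 0; g < k; ++g) {
      double e = 0.0;
      if (S[g] > 0.0) {
        double sp = std::pow(S[g], power[g]);
        e = sp / (1.0 + sp);
      }
      surv *= (1.0 - e);
    }
    out[s] = 1.0 - surv;
  }
  return out;
}
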