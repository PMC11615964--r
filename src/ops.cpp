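#include <Rcpp.h>
#include "belief_math.h"

using namespace Rcpp;
using namespace beliefgame;

// Low-level entry points used by the R wrappers. All mass vectors follow the
// bitmask layout described in belief_math.h; validation happens in R.

// [[Rcpp::export]]
double cpp_cosine(NumericVector a, NumericVector b) {
  return cosine_sim(a.begin(), b.begin(), a.size());
}

// [[Rcpp::export]]
double cpp_map_reliability(double r_prime, double r_fair, double r_eta,
                           double r_max) {
  return map_reliability(r_prime, r_fair, r_eta, r_max);
}

// [[Rcpp::export]]
double cpp_combined_coefficient(double w, double r) {
  return combined_coefficient(w, r);
}

// [[Rcpp::export]]
List cpp_wer_step(NumericVector acc_mass, double acc_unassigned,
                  NumericVector src_mass, double src_unassigned) {
  int S = acc_mass.size();
  std::vector<double> a(acc_mass.begin(), acc_mass.end());
  double ua = acc_unassigned;
  bool ok = wer_step(a, ua, src_mass.begin(), src_unassigned, S);
  return List::create(_["mass"] = NumericVector(a.begin(), a.end()),
                      _["unassigned"] = ua, _["ok"] = ok);
}

// Fold the ego belief (undiscounted) with sources discounted by the combined
// coefficients cs, in the given order, then redistribute the residual
// unassigned slot. Returns ok = FALSE on total conflict (ego returned as-is).
// [[Rcpp::export]]
List cpp_social_learn(NumericVector ego, NumericMatrix sources,
                      NumericVector cs) {
  int S = ego.size();
  int K = sources.nrow();
  std::vector<double> a(ego.begin(), ego.end());
  double ua = 0.0;
  std::vector<double> b((size_t)S);
  for (int k = 0; k < K; ++k) {
    double c = cs[k];
    for (int i = 0; i < S; ++i) b[i] = c * sources(k, i);
    double ub = 1.0 - c;
    if (!wer_step(a, ua, b.data(), ub, S)) {
      return List::create(_["mass"] = ego, _["ok"] = false);
    }
  }
  redistribute_unassigned(a, ua);
  return List::create(_["mass"] = NumericVector(a.begin(), a.end()),
                      _["ok"] = true);
}
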