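#ifndef BELIEFGAME_BELIEF_MATH_H
#define BELIEFGAME_BELIEF_MATH_H

#include <vector>
#include <cmath>

// A mass vector has length S = 2^(2n) - 1 for a frame with n verbs (2n
// verb-form elements). Entry s-1 holds the mass of the non-empty subset whose
// bitmask is s (element e in 0..2n-1 is present iff bit e is set). The full
// frame Theta has bitmask S. Element order is R1..Rn, I1..In, so regular
// singletons are bitmasks 1<<0 .. 1<<(n-1) and irregular singletons
// 1<<n .. 1<<(2n-1).

namespace beliefgame {

const double STABLE_TOL = 1e-9;

inline double cosine_sim(const double* a, const double* b, int S) {
  double dot = 0.0, na = 0.0, nb = 0.0;
  for (int i = 0; i < S; ++i) {
    dot += a[i] * b[i];
    na += a[i] * a[i];
    nb += b[i] * b[i];
  }
  if (na <= 0.0 || nb <= 0.0) return 0.0;  // cannot occur for valid beliefs
  double s = dot / (std::sqrt(na) * std::sqrt(nb));
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return s;
}

// Reliability mapping: identity below the threshold r_eta, affine rescale of
// [r_eta, 1] onto [r_fair, r_max] at and above it.
inline double map_reliability(double rp, double r_fair, double r_eta,
                              double r_max) {
  if (rp >= r_eta) return r_fair + (r_max - r_fair) * (rp - r_eta) / (1.0 - r_eta);
  return rp;
}

inline double combined_coefficient(double w, double r) {
  if (w <= 0.0) return 0.0;  // covers the 0/0 corner at w = 0, r = 1
  double c = w / (1.0 + w - r);
  if (c > 1.0) c = 1.0;  // float rounding at r = 1
  if (c < 0.0) c = 0.0;
  return c;
}

// One weighted-evidential-reasoning fold step: combine the accumulator
// (a, ua) with a discounted source (b, ub), where ua/ub are the slots left
// unassigned by discounting. Cross products whose subset intersection is
// empty are dropped by the renormalization. Returns false on total conflict
// (zero normalizer), leaving a/ua untouched.
inline bool wer_step(std::vector<double>& a, double& ua, const double* b,
                     double ub, int S) {
  std::vector<double> out((size_t)S, 0.0);
  for (int B = 1; B <= S; ++B) {
    double aB = a[B - 1];
    if (aB == 0.0) continue;
    for (int C = 1; C <= S; ++C) {
      double bC = b[C - 1];
      if (bC == 0.0) continue;
      int th = B & C;
      if (th) out[th - 1] += aB * bC;
    }
  }
  for (int th = 0; th < S; ++th) out[th] += ub * a[th] + ua * b[th];
  double uP = ua * ub;
  double tot = uP;
  for (int i = 0; i < S; ++i) tot += out[i];
  if (tot <= 0.0) return false;
  for (int i = 0; i < S; ++i) a[i] = out[i] / tot;
  ua = uP / tot;
  return true;
}

// Final redistribution of the residual unassigned slot after the fold.
inline void redistribute_unassigned(std::vector<double>& a, double& ua) {
  if (ua > 0.0 && ua < 1.0) {
    double denom = 1.0 - ua;
    for (size_t i = 0; i < a.size(); ++i) a[i] /= denom;
    ua = 0.0;
  }
}

inline bool is_stable_mass(const double* m, int S) {
  for (int i = 0; i < S; ++i)
    if (m[i] >= 1.0 - STABLE_TOL) return true;
  return false;
}

// Argmax subset bitmask over all non-empty subsets, ties to lowest bitmask.
inline int argmax_subset(const double* m, int S) {
  int best = 1;
  double bm = m[0];
  for (int s = 2; s <= S; ++s)
    if (m[s - 1] > bm) { bm = m[s - 1]; best = s; }
  return best;
}

}  // namespace beliefgame

#endif
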