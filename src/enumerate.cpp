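#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monoisotopic masses; must match ELEMENT_MASSES on the R side.
static const double MC = 12.0;
static const double MH = 1.007825032;
static const double MN = 14.003074005;
static const double MO = 15.994914620;
static const double MS = 31.972071174;
static const double MP = 30.973761998;

// Enumerate CHNOSP formulas whose monoisotopic mass lies within tol_ppm of
// each target neutral mass, subject to element ranges, H/C and O/C ratio
// bounds, and an integer non-negative DBE. Strategy: loop over the
// heteroatom grid (n, s, p, o); the residual mass then pins (c, h) because
// within sub-mDa tolerances each carbon count admits at most one hydrogen
// count. Returns a long table keyed by the 1-based index of the query mass.
// [[Rcpp::export]]
DataFrame cpp_enumerate_formulas(NumericVector masses, double tol_ppm,
                                 int c_min, int c_max, int h_min, int h_max,
                                 int n_max, int o_max, int s_max, int p_max,
                                 double hc_min, double hc_max, double oc_max,
                                 int max_heteroatoms) {
  std::vector<int> q, cs, hs, ns, os, ss, ps;
  std::vector<double> errs;
  for (int i = 0; i < masses.size(); ++i) {
    double M = masses[i];
    double tol = M * tol_ppm * 1e-6;
    for (int n = 0; n <= n_max; ++n) {
      for (int s = 0; s <= s_max; ++s) {
        for (int p = 0; p <= p_max; ++p) {
          if (n + s + p > max_heteroatoms) continue;
          double hetero = n * MN + s * MS + p * MP;
          if (hetero > M + tol) continue;
          int o_hi = o_max;
          double o_cap = (M + tol - hetero - c_min * MC - h_min * MH) / MO;
          if (o_cap < o_hi) o_hi = (int)std::floor(o_cap);
          for (int o = 0; o <= o_hi; ++o) {
            double rem = M - hetero - o * MO;  // = c*MC + h*MH within tol
            if (rem < c_min * MC + h_min * MH - tol) break;
            // carbon band implied by the H/C ratio limits
            int c_lo = (int)std::floor((rem - tol) / (MC + hc_max * MH));
            int c_hi = (int)std::ceil((rem + tol) / (MC + hc_min * MH));
            if (c_lo < c_min) c_lo = c_min;
            if (c_hi > c_max) c_hi = c_max;
            for (int c = c_lo; c <= c_hi; ++c) {
              int h = (int)std::lround((rem - c * MC) / MH);
              if (h < h_min || h > h_max) continue;
              double mass = c * MC + h * MH + hetero + o * MO;
              if (std::fabs(mass - M) > tol) continue;
              double hc = (double)h / c;
              double oc = (double)o / c;
              if (hc < hc_min || hc > hc_max || oc > oc_max) continue;
              int dbe2 = 2 * c - h + n + p + 2;  // twice the DBE
              if (dbe2 % 2 != 0 || dbe2 < 0) continue;
              q.push_back(i + 1);
              cs.push_back(c); hs.push_back(h); ns.push_back(n);
              os.push_back(o); ss.push_back(s); ps.push_back(p);
              errs.push_back((mass - M) / M * 1e6);
            }
          }
        }
      }
    }
  }
  return DataFrame::create(
      _["query"] = q, _["c"] = cs, _["h"] = hs, _["n"] = ns, _["o"] = os,
      _["s"] = ss, _["p"] = ps, _["error_ppm"] = errs);
}
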