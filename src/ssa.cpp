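#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of the two-state
// transcription model, optionally extended with a translation stage:
//   Off -> On          k_on
//   On  -> Off         k_off
//   On  -> On + M      k_m
//   M   -> 0           delta * m
//   M   -> M + P       k_p * m     (if protein stage enabled)
//   P   -> 0           delta_p * p
// Uses R's RNG so results are reproducible under set.seed().
// Returns a matrix with one row per replicate: promoter state (0/1) at t_end,
// mRNA, protein, and the fraction of time spent On.

// [[Rcpp::export]]
NumericMatrix ssa_telegraph_cpp(double k_on, double k_off, double k_m,
                                double delta, double t_end, int n_replicates,
                                bool with_protein, double k_p,
                                double delta_p) {
  if (t_end <= 0) stop("t_end must be positive");
  NumericMatrix out(n_replicates, 4);
  colnames(out) = CharacterVector::create("state", "mrna", "protein", "on_frac");

  for (int r = 0; r < n_replicates; ++r) {
    double t = 0.0, t_on = 0.0;
    int state = 0; // start Off, empty cell
    long m = 0, p = 0;
    while (true) {
      double a1 = state ? k_off : k_on;       // promoter switch
      double a2 = state ? k_m : 0.0;          // transcription
      double a3 = delta * m;                  // mRNA decay
      double a4 = with_protein ? k_p * m : 0; // translation
      double a5 = with_protein ? delta_p * p : 0;
      double a0 = a1 + a2 + a3 + a4 + a5;
      double tau = (a0 > 0) ? R::rexp(1.0 / a0) : R_PosInf;
      if (t + tau >= t_end) {
        if (state) t_on += t_end - t;
        break;
      }
      if (state) t_on += tau;
      t += tau;
      double u = R::runif(0.0, a0);
      if (u < a1) state = 1 - state;
      else if (u < a1 + a2) m++;
      else if (u < a1 + a2 + a3) m--;
      else if (u < a1 + a2 + a3 + a4) p++;
      else p--;
    }
    out(r, 0) = state;
    out(r, 1) = (double)m;
    out(r, 2) = (double)p;
    out(r, 3) = t_on / t_end;
  }
  return out;
}
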