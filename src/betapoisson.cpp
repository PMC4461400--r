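#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stationary log-pmf of the two-state (telegraph) transcription model in
// its beta-Poisson form: n ~ Poisson(lam * x), x ~ Beta(alpha, beta).
//
// Closed form (Peccoud-Ycart):
//   p(n) = lam^n/n! * (alpha)_n/(alpha+beta)_n * 1F1(alpha+n; alpha+beta+n; -lam)
// Kummer's transformation 1F1(a;b;-z) = e^-z 1F1(b-a;b;z) turns the
// alternating series into one with all-positive terms:
//   p(n) = e^-lam * lam^n/n! * (alpha)_n/(alpha+beta)_n
//          * sum_k (beta)_k lam^k / ((alpha+beta+n)_k k!)
// which is evaluated by term recurrence with periodic rescaling; no
// cancellation occurs, so the result is accurate to near machine precision.

static const double RESCALE_AT = 1e280;
static const double LOG_RESCALE = std::log(1e280);

// series part: log 1F1(beta; alpha+beta+n; lam) for a single n, all-positive
// terms t_k with t_0 = 1, t_k = t_{k-1} * (beta+k-1)*lam / ((c+k-1)*k),
// c = alpha+beta+n. Returns log of the sum; -1 on failure (never expected).
static double log_kummer_pos(double beta, double c, double lam, bool *ok) {
  double term = 1.0, sum = 1.0, log_offset = 0.0;
  const int kmax = 1000000;
  for (int k = 1; k <= kmax; ++k) {
    double ratio = (beta + k - 1.0) * lam / ((c + k - 1.0) * k);
    term *= ratio;
    sum += term;
    if (sum > RESCALE_AT) {
      sum /= RESCALE_AT;
      term /= RESCALE_AT;
      log_offset += LOG_RESCALE;
    }
    // past the term peak and negligibly small relative to the sum
    if (ratio < 1.0 && term < sum * 1e-18) {
      *ok = true;
      return std::log(sum) + log_offset;
    }
  }
  *ok = false;
  return R_NegInf;
}

// [[Rcpp::export]]
NumericVector bp_log_pmf_cpp(IntegerVector n, double alpha, double beta,
                             double lam) {
  int m = n.size();
  NumericVector out(m);
  if (alpha < 0 || beta < 0 || lam < 0)
    stop("alpha, beta and lam must be non-negative");

  for (int i = 0; i < m; ++i) {
    int ni = n[i];
    if (ni < 0) stop("counts must be non-negative");
    if (lam == 0.0 || alpha == 0.0) {
      // no transcription (lam = 0) or promoter never On (alpha = 0)
      out[i] = (ni == 0) ? 0.0 : R_NegInf;
      continue;
    }
    if (beta == 0.0) {
      // promoter permanently On: exact Poisson(lam)
      out[i] = R::dpois(ni, lam, 1);
      continue;
    }
    double lpref = -lam + ni * std::log(lam) - std::lgamma(ni + 1.0) +
                   std::lgamma(alpha + ni) - std::lgamma(alpha) -
                   (std::lgamma(alpha + beta + ni) - std::lgamma(alpha + beta));
    bool ok = false;
    double lM = log_kummer_pos(beta, alpha + beta + ni, lam, &ok);
    out[i] = ok ? lpref + lM : NA_REAL; // NA triggers the quadrature fallback
  }
  return out;
}

// Negative log-likelihood over a count vector, exploiting repeated counts.
// [[Rcpp::export]]
double bp_nll_cpp(IntegerVector counts, double alpha, double beta, double lam) {
  // tabulate unique counts
  std::map<int, int> tab;
  for (int i = 0; i < counts.size(); ++i) tab[counts[i]]++;
  IntegerVector uniq(tab.size());
  int j = 0;
  for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it)
    uniq[j++] = it->first;
  NumericVector lp = bp_log_pmf_cpp(uniq, alpha, beta, lam);
  double nll = 0.0;
  j = 0;
  for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it) {
    double l = lp[j++];
    if (!R_finite(l)) return R_PosInf;
    nll -= it->second * l;
  }
  return nll;
}
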