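// Hot path of the promotion-time cure likelihood.  These mirror the R
// reference implementations in R/cure.R and R/gbs.R exactly; tests assert
// the two routes agree to machine precision.
#include <Rcpp.h>
using namespace Rcpp;

// Right-censored promotion-time log likelihood from cached pieces:
// eta = x beta, S = latent GBS survival (all subjects), lf_ev = latent log
// density at the event times, ev = 0-based indices of the event subjects.
// [[Rcpp::export(name = ".cure_parts_cpp")]]
double cure_parts_cpp(NumericVector eta, NumericVector S,
                      NumericVector lf_ev, IntegerVector ev) {
  const int n = eta.size(), m = ev.size();
  double ll = 0.0;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    // log theta under the logit link, stable in both tails
    double lth = (e >= 0.0) ? -log1p(exp(-e)) : e - log1p(exp(e));
    double th = exp(lth);
    double lA = log1p(-(1.0 - th) * S[i]);               // log[1-(1-th)S]
    ll += lth - lA;
    if (k < m && ev[k] == i) {                           // event subject:
      ll += (lth - e) + lf_ev[k] - lA;                   // log(1-th) = lth - eta
      ++k;
    }
  }
  if (!R_finite(ll)) return R_NegInf;
  return ll;
}

// GBS survival for every subject and log density at the event subjects.
// logt = log(time); ev = 0-based event indices.
// [[Rcpp::export(name = ".gbs_pieces_cpp")]]
List gbs_pieces_cpp(NumericVector logt, IntegerVector ev, double alpha,
                    double beta, double nu) {
  const int n = logt.size(), m = ev.size();
  const double lb = log(beta), la = log(alpha), lnu = log(nu);
  NumericVector S(n), lf(m);
  for (int i = 0; i < n; ++i) {
    double r = nu * (logt[i] - lb);
    double z = (exp(r) - exp(-r)) / alpha;
    S[i] = R::pnorm(z, 0.0, 1.0, 0, 0);
  }
  for (int k = 0; k < m; ++k) {
    int i = ev[k];
    double r = nu * (logt[i] - lb);
    double z = (exp(r) - exp(-r)) / alpha;
    double ar = fabs(r);
    double ldz = lnu - la - logt[i] + ar + log1p(exp(-2.0 * ar));
    lf[k] = R::dnorm(z, 0.0, 1.0, 1) + ldz;
  }
  return List::create(_["S"] = S, _["lf_ev"] = lf);
}
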