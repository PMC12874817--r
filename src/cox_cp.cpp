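#include <Rcpp.h>
using namespace Rcpp;

// Counting-process Cox partial likelihood sweep with modality states.
//
// Rows are (start, stop] episodes; a row is at risk at event time t iff
// start < t <= stop. Each row carries fixed covariates X (linear predictor
// contribution precomputed in e0 = exp(X beta)) and a modality state
// s in 1..S (state 1 = reference). The state contributes a main-effect
// coefficient bmod[s-2+1] and, optionally, a state-by-time coefficient
// gmod so that the row's risk at time t is e0 * exp(bmod_s + gmod_s * t).
// Because the time-varying part is common to all rows of a state, risk-set
// sums factor into per-state aggregates W0/W1/W2 maintained incrementally
// over the ascending sweep of event times (Breslow ties).
//
// Returns the log partial likelihood, score, observed information, and the
// per-event-time S0 and ubar = S1/S0 needed for score residuals.
// [[Rcpp::export]]
List cox_cp_sweep(NumericVector tau, NumericVector d,
                  NumericVector start, NumericVector stop,
                  IntegerVector state, int nstate,
                  NumericMatrix X, NumericVector e0,
                  NumericVector bmod, NumericVector gmod,
                  IntegerVector ord_start, IntegerVector ord_stop,
                  NumericVector ev_lp_sum, NumericMatrix u_ev_sum) {
  const int n = start.size(), K = tau.size(), p = X.ncol();
  const int nb = bmod.size();          // nstate - 1
  const int ng = gmod.size();          // nstate - 1 or 0
  const int P = p + nb + ng;

  std::vector<double> W0(nstate, 0.0);
  std::vector<double> W1(nstate * p, 0.0);
  std::vector<double> W2(nstate * p * p, 0.0);

  double ll = 0.0;
  NumericVector grad(P);
  NumericMatrix info(P, P);
  NumericVector S0out(K);
  NumericMatrix ubarout(K, P);

  std::vector<double> phi(nstate), S1(P), ubar(P), S2(P * P);

  int ia = 0, ir = 0;
  for (int k = 0; k < K; ++k) {
    const double t = tau[k];
    while (ia < n && start[ord_start[ia]] < t) {
      const int j = ord_start[ia]; const int s = state[j] - 1;
      const double e = e0[j];
      W0[s] += e;
      for (int a = 0; a < p; ++a) {
        const double xa = X(j, a);
        W1[s * p + a] += e * xa;
        for (int b = 0; b <= a; ++b)
          W2[(s * p + a) * p + b] += e * xa * X(j, b);
      }
      ++ia;
    }
    while (ir < n && stop[ord_stop[ir]] < t) {
      const int j = ord_stop[ir]; const int s = state[j] - 1;
      const double e = e0[j];
      W0[s] -= e;
      for (int a = 0; a < p; ++a) {
        const double xa = X(j, a);
        W1[s * p + a] -= e * xa;
        for (int b = 0; b <= a; ++b)
          W2[(s * p + a) * p + b] -= e * xa * X(j, b);
      }
      ++ir;
    }

    phi[0] = 1.0;
    for (int s = 1; s < nstate; ++s)
      phi[s] = std::exp(bmod[s - 1] + (ng ? gmod[s - 1] * t : 0.0));

    double S0 = 0.0;
    for (int s = 0; s < nstate; ++s) S0 += phi[s] * W0[s];

    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    for (int a = 0; a < p; ++a) {
      double acc = 0.0;
      for (int s = 0; s < nstate; ++s) acc += phi[s] * W1[s * p + a];
      S1[a] = acc;
      for (int b = 0; b <= a; ++b) {
        double acc2 = 0.0;
        for (int s = 0; s < nstate; ++s)
          acc2 += phi[s] * W2[(s * p + a) * p + b];
        S2[a * P + b] = S2[b * P + a] = acc2;
      }
    }
    for (int s = 1; s < nstate; ++s) {
      const double w0s = phi[s] * W0[s];
      const int ib = p + s - 1;
      S1[ib] = w0s;
      S2[ib * P + ib] = w0s;
      for (int a = 0; a < p; ++a) {
        const double w1sa = phi[s] * W1[s * p + a];
        S2[ib * P + a] = S2[a * P + ib] = w1sa;
      }
      if (ng) {
        const int ig = p + nb + s - 1;
        S1[ig] = t * w0s;
        S2[ig * P + ig] = t * t * w0s;
        S2[ig * P + ib] = S2[ib * P + ig] = t * w0s;
        for (int a = 0; a < p; ++a) {
          const double w1sa = phi[s] * W1[s * p + a];
          S2[ig * P + a] = S2[a * P + ig] = t * w1sa;
        }
      }
    }

    ll += ev_lp_sum[k] - d[k] * std::log(S0);
    S0out[k] = S0;
    for (int a = 0; a < P; ++a) {
      ubar[a] = S1[a] / S0;
      ubarout(k, a) = ubar[a];
      grad[a] += u_ev_sum(k, a) - d[k] * ubar[a];
    }
    for (int a = 0; a < P; ++a)
      for (int b = 0; b <= a; ++b) {
        const double v = d[k] * (S2[a * P + b] / S0 - ubar[a] * ubar[b]);
        info(a, b) += v;
        if (a != b) info(b, a) += v;
      }
  }

  return List::create(_["loglik"] = ll, _["grad"] = grad, _["info"] = info,
                      _["S0"] = S0out, _["ubar"] = ubarout);
}
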