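#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-Hastings sampler for a dyad-separable directed ERGM.
//
// State is kept per unordered dyad in {0 null, 1 i->j, 2 j->i, 3 mutual}.
// A proposal picks one allowed dyad and one direction uniformly (i.e. a
// uniform ordered-pair toggle) and flips that single tie; the acceptance
// log-ratio is +/- (eta_d + theta_mut * y_reverse), where eta_d is the
// asymmetric-state linear predictor of the dyad. Model statistics are
// maintained incrementally, so each recorded draw carries its exact
// sufficient-statistic vector.
//
// Uses R's RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List mh_sample_dyads(NumericMatrix A, int mutual_col, NumericVector theta,
                     IntegerVector init_state, double burnin, double thin,
                     int nsim, bool return_states) {
  const int D = A.nrow();
  const int P = A.ncol();
  if (theta.size() != P) stop("theta length does not match design");
  if (init_state.size() != D) stop("init_state length does not match design");
  if (burnin < 0 || thin < 1) stop("burnin must be >= 0 and thin >= 1");

  const double theta_mut = (mutual_col > 0) ? theta[mutual_col - 1] : 0.0;

  // linear predictor of one asymmetric tie per dyad
  std::vector<double> eta(D);
  for (int d = 0; d < D; ++d) {
    double e = 0.0;
    for (int k = 0; k < P; ++k) e += A(d, k) * theta[k];
    eta[d] = e;
  }

  std::vector<int> state(init_state.begin(), init_state.end());
  std::vector<double> stats(P, 0.0);
  for (int d = 0; d < D; ++d) {
    const int s = state[d];
    if (s < 0 || s > 3) stop("init_state values must be in 0..3");
    const double mult = (s == 3) ? 2.0 : (s == 0 ? 0.0 : 1.0);
    if (mult > 0.0)
      for (int k = 0; k < P; ++k) stats[k] += mult * A(d, k);
    if (s == 3 && mutual_col > 0) stats[mutual_col - 1] += 1.0;
  }

  NumericMatrix out_stats(nsim, P);
  List out_states(return_states ? nsim : 0);

  const double total = burnin + thin * (double)nsim;
  double next_record = burnin + thin;
  int recorded = 0;

  for (double it = 1; it <= total; ++it) {
    const int d = (int)(unif_rand() * D);
    const int bit = (unif_rand() < 0.5) ? 1 : 2;  // 1: i->j, 2: j->i
    const int s = state[d];
    const int y_this = (s & bit) ? 1 : 0;
    const int other = (bit == 1) ? 2 : 1;
    const int y_rev = (s & other) ? 1 : 0;
    const double delta = eta[d] + theta_mut * (double)y_rev;
    const double logr = y_this ? -delta : delta;
    if (logr >= 0.0 || log(unif_rand()) < logr) {
      const double sign = y_this ? -1.0 : 1.0;
      state[d] = s ^ bit;
      for (int k = 0; k < P; ++k) stats[k] += sign * A(d, k);
      if (mutual_col > 0 && y_rev)
        stats[mutual_col - 1] += sign;
    }
    if (it >= next_record && recorded < nsim) {
      for (int k = 0; k < P; ++k) out_stats(recorded, k) = stats[k];
      if (return_states) {
        std::vector<int> idx, val;
        for (int dd = 0; dd < D; ++dd)
          if (state[dd]) { idx.push_back(dd + 1); val.push_back(state[dd]); }
        out_states[recorded] = List::create(_["dyad"] = wrap(idx),
                                            _["state"] = wrap(val));
      }
      ++recorded;
      next_record += thin;
    }
  }
  return List::create(_["stats"] = out_stats, _["states"] = out_states);
}
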