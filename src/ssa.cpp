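#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation on a finite state network with
// time-homogeneous rates.  Transitions are given as parallel arrays
// (0-based source/target state, rate, site offset).  The walk stops when
// any of the limits is reached: total event count, simulated time, or
// number of mechanical (offset != 0) events.  Uses R's RNG so set.seed()
// in the caller makes runs reproducible.  With record_all = false only
// mechanical events are stored, which keeps memory flat when chemical
// events outnumber steps by orders of magnitude.
// [[Rcpp::export]]
List ssa_run_cpp(int n_states,
                 IntegerVector tr_from,
                 IntegerVector tr_to,
                 NumericVector tr_rate,
                 IntegerVector tr_offset,
                 int init_state,
                 double max_events,
                 double t_max,
                 double max_mech,
                 bool record_all) {
  int n_tr = tr_from.size();

  // per-state transition index lists
  std::vector< std::vector<int> > by_state(n_states);
  for (int i = 0; i < n_tr; ++i) {
    if (tr_from[i] < 0 || tr_from[i] >= n_states) stop("transition source out of range");
    by_state[tr_from[i]].push_back(i);
  }
  std::vector<double> exit_rate(n_states, 0.0);
  for (int s = 0; s < n_states; ++s)
    for (size_t j = 0; j < by_state[s].size(); ++j)
      exit_rate[s] += tr_rate[by_state[s][j]];

  std::vector<double> ev_time;
  std::vector<int> ev_trans;   // 1-based transition index
  std::vector<int> ev_offset;

  double t = 0.0;
  int state = init_state;
  double n_ev = 0.0, n_mech = 0.0;
  bool absorbed = false;

  while (n_ev < max_events && n_mech < max_mech) {
    double total = exit_rate[state];
    if (total <= 0.0) { absorbed = true; break; }
    double u1 = unif_rand();
    while (u1 <= 0.0) u1 = unif_rand();
    double dt = -std::log(u1) / total;
    if (t + dt > t_max) { t = t_max; break; }
    t += dt;
    double u2 = unif_rand() * total;
    const std::vector<int>& trs = by_state[state];
    int chosen = trs.back();
    double acc = 0.0;
    for (size_t j = 0; j < trs.size(); ++j) {
      acc += tr_rate[trs[j]];
      if (u2 <= acc) { chosen = trs[j]; break; }
    }
    state = tr_to[chosen];
    if (record_all || tr_offset[chosen] != 0) {
      ev_time.push_back(t);
      ev_trans.push_back(chosen + 1);
      ev_offset.push_back(tr_offset[chosen]);
    }
    n_ev += 1.0;
    if (tr_offset[chosen] != 0) n_mech += 1.0;
  }

  return List::create(
    _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["transition"] = IntegerVector(ev_trans.begin(), ev_trans.end()),
    _["offset"] = IntegerVector(ev_offset.begin(), ev_offset.end()),
    _["final_state"] = state + 1,
    _["final_time"] = t,
    _["n_events"] = n_ev,
    _["absorbed"] = absorbed);
}
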