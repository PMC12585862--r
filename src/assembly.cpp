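#include <Rcpp.h>
using namespace Rcpp;

// Embedded jump chain for death-free assembly with saturated dispersal.
// Every event increases N by one and the logistic factor cancels from the
// recruit-identity probability, so sampling the recruit species with
// probability (r_i n_i + c_i) / sum_j (r_j n_j + c_j) at each of the K
// increments reproduces the Gillespie final-composition distribution at a
// cost of O(K) draws per replicate. Uses R's global RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_embedded_ensemble(NumericVector r, NumericVector c,
                                    int K, int n_rep) {
  const int S = r.size();
  IntegerMatrix out(n_rep, S);
  std::vector<double> n(S), w(S);
  const double csum = std::accumulate(c.begin(), c.end(), 0.0);
  if (csum <= 0.0)
    stop("total dispersal rate is zero: assembly cannot start");
  for (int rep = 0; rep < n_rep; ++rep) {
    std::fill(n.begin(), n.end(), 0.0);
    double rn = 0.0;  // sum_i r_i n_i, updated incrementally
    for (int step = 0; step < K; ++step) {
      double tot = rn + csum;
      double u = unif_rand() * tot;
      int pick = S - 1;
      double acc = 0.0;
      for (int i = 0; i < S; ++i) {
        acc += r[i] * n[i] + c[i];
        if (u < acc) { pick = i; break; }
      }
      n[pick] += 1.0;
      rn += r[pick];
    }
    for (int i = 0; i < S; ++i) out(rep, i) = (int) n[i];
  }
  return out;
}

// Full Gillespie simulation of one assembly trajectory.
//
// Events: division of species i at rate r_i (1 - N/K) n_i, dispersal at
// c_i (1 - N/K) (or plain c_i when saturated = false, forced to 0 at
// N = K), death at d_i n_i.
//
// stop_mode 0: stop when N first reaches stop_n (death-free: stop_n = K).
// stop_mode 1: stop at elapsed time stop_time.
// Either way the simulation also stops if every propensity vanishes
// (reported via the returned state; with death the community may sit at
// N = 0 with no dispersal).
// [[Rcpp::export]]
List cpp_gillespie(NumericVector r, NumericVector c, NumericVector d,
                   int K, bool saturated, int stop_mode, int stop_n,
                   double stop_time, bool record) {
  const int S = r.size();
  std::vector<double> n(S, 0.0), prop(3 * S);
  double t = 0.0;
  int N = 0;
  std::vector<double> traj_t;
  std::vector<int> traj_event, traj_species;
  std::vector<int> traj_counts;  // row-major S columns

  for (;;) {
    if (stop_mode == 0 && N >= stop_n) break;
    if (stop_mode == 1 && t >= stop_time) break;
    double sat = 1.0 - (double) N / (double) K;
    double tot = 0.0;
    for (int i = 0; i < S; ++i) {
      prop[i] = r[i] * sat * n[i];                                // division
      prop[S + i] = saturated ? c[i] * sat : (N >= K ? 0.0 : c[i]);  // dispersal
      prop[2 * S + i] = d[i] * n[i];                              // death
      tot += prop[i] + prop[S + i] + prop[2 * S + i];
    }
    if (tot <= 0.0) break;  // absorbed (N = K with no death, or frozen)
    t += exp_rand() / tot;
    if (stop_mode == 1 && t > stop_time) { t = stop_time; break; }
    double u = unif_rand() * tot;
    int ev = 3 * S - 1;
    double acc = 0.0;
    for (int j = 0; j < 3 * S; ++j) {
      acc += prop[j];
      if (u < acc) { ev = j; break; }
    }
    int sp = ev % S;
    int type = ev / S;  // 0 division, 1 dispersal, 2 death
    if (type == 2) { n[sp] -= 1.0; --N; } else { n[sp] += 1.0; ++N; }
    if (record) {
      traj_t.push_back(t);
      traj_event.push_back(type);
      traj_species.push_back(sp);
      for (int i = 0; i < S; ++i) traj_counts.push_back((int) n[i]);
    }
  }

  IntegerVector counts(S);
  for (int i = 0; i < S; ++i) counts[i] = (int) n[i];
  List out = List::create(_["counts"] = counts, _["time"] = t);
  if (record) {
    const int m = traj_t.size();
    IntegerMatrix cm(m, S);
    for (int k = 0; k < m; ++k)
      for (int i = 0; i < S; ++i) cm(k, i) = traj_counts[k * S + i];
    out["trajectory"] = List::create(
      _["time"] = NumericVector(traj_t.begin(), traj_t.end()),
      _["event"] = IntegerVector(traj_event.begin(), traj_event.end()),
      _["species"] = IntegerVector(traj_species.begin(), traj_species.end()),
      _["counts"] = cm);
  }
  return out;
}
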