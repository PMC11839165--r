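#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie direct-method core over a restricted propensity family:
//   a_j(x) = k_j / div_j * F1_j(x) * F2_j(x)
// where each factor F is affine in at most two species,
//   F(x) = c1 * x[i1] + c2 * x[i2] + c0,
// encoded per reaction as a row (i1, c1, i2, c2, c0) with i = -1 for "unused".
// F2 rows with i1 == -2 mean "no second factor" (F2 = 1).
// This family covers every reaction used by the growth models in this
// package: zeroth/first/second-order mass action, pool-scaled bimolecular
// terms (div = c*Vc), and affine size-feedback factors such as (Sa+Sb+1).
//
// A reaction whose firing would drive any species negative is masked
// (propensity forced to 0); for well-formed mass-action networks the mask
// never binds, but it is the engine-level guarantee that states stay in the
// non-negative orthant (needed e.g. for the size-independent disassembly
// variant).

static inline double eval_factor(const double* x, const double* row) {
  int i1 = (int) row[0];
  if (i1 == -2) return 1.0;          // absent factor
  double v = row[4];                 // constant term
  if (i1 >= 0) v += row[1] * x[i1];
  int i2 = (int) row[2];
  if (i2 >= 0) v += row[3] * x[i2];
  return v;
}

// [[Rcpp::export]]
List ssa_core(NumericVector init, IntegerMatrix delta, NumericVector k,
              NumericVector div, NumericMatrix f1, NumericMatrix f2,
              CharacterVector rxn_names, double t_max, NumericVector grid,
              bool every_event, double max_events) {
  const int S = init.size();
  const int R = k.size();

  std::vector<double> x(init.begin(), init.end());
  std::vector<double> a(R);
  // cache factor rows in plain arrays (column-major access is slow in loop)
  std::vector<double> F1(R * 5), F2(R * 5);
  for (int j = 0; j < R; ++j)
    for (int c = 0; c < 5; ++c) {
      F1[j * 5 + c] = f1(j, c);
      F2[j * 5 + c] = f2(j, c);
    }
  std::vector<int> D(R * S);
  for (int j = 0; j < R; ++j)
    for (int s = 0; s < S; ++s) D[j * S + s] = delta(j, s);

  const int G = grid.size();
  NumericMatrix grid_states(G, S);
  std::vector<double> ev_t;
  std::vector<double> ev_x;

  double t = 0.0;
  int gi = 0;
  double n_events = 0.0;
  bool absorbed = false;

  GetRNGstate();
  if (every_event) { ev_t.push_back(t); ev_x.insert(ev_x.end(), x.begin(), x.end()); }

  for (;;) {
    // propensities with non-negativity mask
    double a0 = 0.0;
    for (int j = 0; j < R; ++j) {
      double aj = k[j] / div[j] * eval_factor(x.data(), &F1[j * 5]) *
                  eval_factor(x.data(), &F2[j * 5]);
      if (ISNAN(aj) || aj < 0.0) {
        PutRNGstate();
        stop("propensity of reaction '%s' is %f at t=%f (state out of domain)",
             std::string(rxn_names[j]).c_str(), aj, t);
      }
      // mask reactions that would drive a species negative
      if (aj > 0.0) {
        for (int s = 0; s < S; ++s) {
          int d = D[j * S + s];
          if (d < 0 && x[s] < -d) { aj = 0.0; break; }
        }
      }
      a[j] = aj;
      a0 += aj;
    }

    if (a0 <= 0.0) { absorbed = true; break; }

    double r1 = unif_rand();
    double tau = std::log(1.0 / r1) / a0;
    double t_new = t + tau;
    if (t_new > t_max) { t = t_max; break; }

    // record grid points passed while in the current state
    while (gi < G && grid[gi] < t_new) {
      for (int s = 0; s < S; ++s) grid_states(gi, s) = x[s];
      ++gi;
    }

    // select reaction by cumulative-propensity inversion (half-open interval)
    double r2a0 = unif_rand() * a0;
    double cum = 0.0;
    int j_sel = R - 1;
    for (int j = 0; j < R; ++j) {
      cum += a[j];
      if (r2a0 < cum) { j_sel = j; break; }
    }

    for (int s = 0; s < S; ++s) x[s] += D[j_sel * S + s];
    t = t_new;
    n_events += 1.0;

    if (every_event) { ev_t.push_back(t); ev_x.insert(ev_x.end(), x.begin(), x.end()); }
    if (n_events >= max_events) {
      PutRNGstate();
      stop("event budget exceeded (%.0f events before t_max=%f; reached t=%f)",
           max_events, t_max, t);
    }
  }
  PutRNGstate();

  // fill remaining grid points with the final (held) state
  while (gi < G) {
    for (int s = 0; s < S; ++s) grid_states(gi, s) = x[s];
    ++gi;
  }

  NumericVector final_state(x.begin(), x.end());
  List out = List::create(
      _["grid_states"] = grid_states, _["final_state"] = final_state,
      _["final_time"] = t, _["n_events"] = n_events, _["absorbed"] = absorbed);
  if (every_event) {
    int n = ev_t.size();
    NumericMatrix M(n, S);
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < S; ++s) M(i, s) = ev_x[(size_t) i * S + s];
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_states"] = M;
  }
  return out;
}
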