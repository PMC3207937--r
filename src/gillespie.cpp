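#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie simulation of a mass-action reaction network.
//
// Propensity of reaction j: k[j] * count[r1[j]] * count[r2[j]], with the
// second factor omitted when r2[j] < 0. Statistical (site-counting)
// factors are folded into k by the caller. Uses R's RNG so runs are
// reproducible via set.seed().
//
// Accumulates the time-weighted occupancy of the "active count" m (the
// summed counts of active_species) after burn_in, per-batch time averages
// of m and m^2 for batch-means standard errors, and optionally the first
// max_record post-initial events of the full trajectory.
// [[Rcpp::export]]
List gillespie_core(NumericVector k, IntegerVector r1, IntegerVector r2,
                    IntegerMatrix stoich, IntegerVector init,
                    double t_max, double burn_in,
                    IntegerVector active_species, int m_max,
                    int max_record, int n_batches) {
  const int n_reac = k.size();
  const int n_spec = init.size();
  std::vector<long> x(n_spec);
  for (int i = 0; i < n_spec; ++i) x[i] = init[i];

  long m = 0;
  for (int i = 0; i < active_species.size(); ++i) m += x[active_species[i]];

  NumericVector occupancy(m_max + 1);
  NumericVector batch_w(n_batches), batch_m(n_batches), batch_m2(n_batches);
  const double batch_len = (t_max - burn_in) / n_batches;

  std::vector<double> rec_t;
  std::vector<long> rec_x;
  if (max_record > 0) {
    rec_t.reserve(max_record + 1);
    rec_x.reserve((size_t)(max_record + 1) * n_spec);
    rec_t.push_back(0.0);
    for (int i = 0; i < n_spec; ++i) rec_x.push_back(x[i]);
  }

  std::vector<double> a(n_reac);
  double t = 0.0;
  long n_events = 0;
  GetRNGstate();
  while (t < t_max) {
    double a0 = 0.0;
    for (int j = 0; j < n_reac; ++j) {
      double aj = k[j] * (double)x[r1[j]];
      if (r2[j] >= 0) aj *= (double)x[r2[j]];
      a[j] = aj;
      a0 += aj;
    }
    double t_next;
    int j_fire = -1;
    if (a0 <= 0.0) {
      t_next = t_max; // absorbing state: hold until the end
    } else {
      t_next = t + ::Rf_rexp(1.0 / a0);
      double u = unif_rand() * a0, cum = 0.0;
      for (int j = 0; j < n_reac; ++j) {
        cum += a[j];
        if (u <= cum) { j_fire = j; break; }
      }
      if (j_fire < 0) j_fire = n_reac - 1;
    }
    double t_end = std::min(t_next, t_max);
    // credit the dwell in the current state to occupancy and batches
    double lo = std::max(t, burn_in);
    if (t_end > lo) {
      double w = t_end - lo;
      if (m <= m_max) occupancy[m] += w;
      // split the dwell across batches
      double seg_lo = lo;
      while (seg_lo < t_end) {
        int b = (int)((seg_lo - burn_in) / batch_len);
        if (b >= n_batches) b = n_batches - 1;
        double seg_hi = std::min(t_end, burn_in + (b + 1) * batch_len);
        if (seg_hi <= seg_lo) {  // fp edge: dwell starts exactly on a boundary
          b = std::min(b + 1, n_batches - 1);
          seg_hi = std::min(t_end, burn_in + (b + 1) * batch_len);
          if (seg_hi <= seg_lo) break;
        }
        double sw = seg_hi - seg_lo;
        batch_w[b] += sw;
        batch_m[b] += sw * (double)m;
        batch_m2[b] += sw * (double)m * (double)m;
        seg_lo = seg_hi;
      }
    }
    if (t_next > t_max || j_fire < 0) break;
    // fire reaction
    for (int i = 0; i < n_spec; ++i) x[i] += stoich(i, j_fire);
    m = 0;
    for (int i = 0; i < active_species.size(); ++i) m += x[active_species[i]];
    t = t_next;
    ++n_events;
    if (max_record > 0 && (long)rec_t.size() <= max_record) {
      rec_t.push_back(t);
      for (int i = 0; i < n_spec; ++i) rec_x.push_back(x[i]);
    }
    if (n_events % 4194304 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  IntegerVector final_state(n_spec);
  for (int i = 0; i < n_spec; ++i) final_state[i] = (int)x[i];

  List out = List::create(
    _["occupancy"] = occupancy,
    _["batch_weight"] = batch_w,
    _["batch_mean_m"] = batch_m,
    _["batch_mean_m2"] = batch_m2,
    _["n_events"] = (double)n_events,
    _["final_state"] = final_state);
  if (max_record > 0) {
    int nr = rec_t.size();
    NumericVector times(nr);
    IntegerMatrix states(nr, n_spec);
    for (int r = 0; r < nr; ++r) {
      times[r] = rec_t[r];
      for (int i = 0; i < n_spec; ++i)
        states(r, i) = (int)rec_x[(size_t)r * n_spec + i];
    }
    out["times"] = times;
    out["states"] = states;
  }
  return out;
}
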