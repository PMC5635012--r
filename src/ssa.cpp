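#include <Rcpp.h>
using namespace Rcpp;

// Transition rates out of state (n, s) for the anchor binding chain.
//
// Channels (index into `rates`):
//   0: (n,s)   -> (n+1,s)   at (N-n) k_on          free anchor binds particle
//   1: (n,0)   -> (n+1,1)   at (N-n) k_on_prime    matrix-bound anchor captures particle (s=0 only)
//   2: (n,s)   -> (n-1,s)   at (n-s) k_off         non-crosslinked anchor released
//   3: (n,s)   -> (n-1,s-1) at  s    k_off         crosslinking anchor released from particle
//   4: (n,s)   -> (n,s+1)   at g(s) (n-s) a_on     anchor in complex binds matrix
//   5: (n,s)   -> (n,s-1)   at  s    a_off         anchor-matrix bond breaks
// with g(0) = D_P/D_A (complex must diffuse to the matrix) and g(s>=1) = C
// (intra-complex binding).
static inline void state_rates(int n, int s, int N,
                               double k_on, double k_onp, double k_off,
                               double a_on, double a_off, double C, double g0,
                               double *rates) {
  rates[0] = (N - n) * k_on;
  rates[1] = (s == 0) ? (N - n) * k_onp : 0.0;
  rates[2] = (n - s) * k_off;
  rates[3] = s * k_off;
  rates[4] = ((s == 0) ? g0 : C) * (n - s) * a_on;
  rates[5] = s * a_off;
}

static inline int pick_channel(const double *rates, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (int j = 0; j < 6; ++j) {
    acc += rates[j];
    if (u <= acc) return j;
  }
  return 5;
}

static inline void apply_channel(int j, int *n, int *s) {
  switch (j) {
  case 0: *n += 1; break;
  case 1: *n += 1; *s += 1; break;
  case 2: *n -= 1; break;
  case 3: *n -= 1; *s -= 1; break;
  case 4: *s += 1; break;
  case 5: *s -= 1; break;
  }
}

// Gillespie simulation of the (n, s) chain started from (0, 0).
// Stops after max_transitions steps or once total time exceeds max_time
// (whichever comes first; a non-positive limit disables that rule).
// Returns total time, time spent free (s = 0), per-batch free-time
// fractions (batches split by transition count), and optionally the full
// transition log.
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(int N, double k_on, double k_onp, double k_off,
                   double a_on, double a_off, double C, double g0,
                   double max_transitions, double max_time,
                   int n_batches, bool keep_log) {
  int n = 0, s = 0;
  double t_total = 0.0, t_free = 0.0;
  double rates[6];
  double m = 0.0;

  std::vector<double> batch_time, batch_free;
  batch_time.reserve(n_batches > 0 ? n_batches : 1);
  batch_free.reserve(n_batches > 0 ? n_batches : 1);
  double cur_bt = 0.0, cur_bf = 0.0;
  double batch_size = (n_batches > 0 && max_transitions > 0)
    ? max_transitions / n_batches : R_PosInf;
  double next_batch = batch_size;

  std::vector<double> log_t, log_n, log_s;
  if (keep_log) {
    log_t.push_back(0.0); log_n.push_back(0); log_s.push_back(0);
  }

  bool exhausted = false;
  while (true) {
    if (max_transitions > 0 && m >= max_transitions) break;
    if (max_time > 0 && t_total >= max_time) break;
    state_rates(n, s, N, k_on, k_onp, k_off, a_on, a_off, C, g0, rates);
    double total = 0.0;
    for (int j = 0; j < 6; ++j) total += rates[j];
    if (total <= 0.0) { exhausted = true; break; }

    double dwell = exp_rand() / total;
    bool truncated = (max_time > 0 && t_total + dwell > max_time);
    if (truncated) dwell = max_time - t_total;
    t_total += dwell;
    cur_bt += dwell;
    if (s == 0) { t_free += dwell; cur_bf += dwell; }
    if (truncated) break;  // censored mid-dwell: no transition occurs

    int j = pick_channel(rates, total);
    apply_channel(j, &n, &s);
    m += 1.0;
    if (keep_log) {
      log_t.push_back(t_total); log_n.push_back(n); log_s.push_back(s);
    }
    if (m >= next_batch && cur_bt > 0.0) {
      batch_time.push_back(cur_bt);
      batch_free.push_back(cur_bf);
      cur_bt = 0.0; cur_bf = 0.0;
      next_batch += batch_size;
    }
  }
  if (cur_bt > 0.0) { batch_time.push_back(cur_bt); batch_free.push_back(cur_bf); }

  NumericVector bfrac(batch_time.size());
  for (size_t i = 0; i < batch_time.size(); ++i)
    bfrac[i] = batch_free[i] / batch_time[i];

  List out = List::create(
    _["m"] = m, _["t_total"] = t_total, _["t_free"] = t_free,
    _["batch_fractions"] = bfrac, _["final_n"] = n, _["final_s"] = s,
    _["exhausted"] = exhausted);
  if (keep_log)
    out["log"] = DataFrame::create(_["time"] = wrap(log_t),
                                   _["n"] = wrap(log_n), _["s"] = wrap(log_s));
  return out;
}

// Diffuse a particle for elapsed time `tau` with diffusivity D_P, reflecting
// at x = 0, absorbing at x = L; sub-steps of at most dt_max bound the bias
// from undetected boundary crossings inside a step. Returns time-to-absorb
// within this interval, or -1 if still inside the slab.
static inline double diffuse_interval(double *x, double tau, double D_P,
                                      double L, double dt_max) {
  double t = 0.0;
  while (t < tau) {
    double dt = std::min(dt_max, tau - t);
    *x += std::sqrt(2.0 * D_P * dt) * norm_rand();
    if (*x < 0) *x = -*x;   // reflection
    t += dt;
    if (*x >= L) return t;  // absorbed
  }
  return -1.0;
}

// Spatial switching-diffusion simulation: each particle runs the (n, s)
// chain; Brownian motion along x (diffusivity D_P) occurs only while s = 0.
// Particles start at x = 0 in state (0, 0); reflecting boundary at 0,
// absorbing at L, censored at time T.
// [[Rcpp::export(name = ".spatial_cpp")]]
List spatial_cpp(int N, double k_on, double k_onp, double k_off,
                 double a_on, double a_off, double C, double g0,
                 double D_P, double L, double T, int n_particles,
                 double dt_max) {
  LogicalVector absorbed(n_particles);
  NumericVector fpt(n_particles, NA_REAL);
  double rates[6];

  for (int i = 0; i < n_particles; ++i) {
    int n = 0, s = 0;
    double t = 0.0, x = 0.0;
    bool hit = false;
    while (t < T) {
      state_rates(n, s, N, k_on, k_onp, k_off, a_on, a_off, C, g0, rates);
      double total = 0.0;
      for (int j = 0; j < 6; ++j) total += rates[j];
      double dwell = (total > 0.0) ? exp_rand() / total : (T - t);
      if (t + dwell > T) dwell = T - t;
      if (s == 0 && dwell > 0.0) {
        double hit_t = diffuse_interval(&x, dwell, D_P, L, dt_max);
        if (hit_t >= 0.0) { hit = true; fpt[i] = t + hit_t; break; }
      }
      t += dwell;
      if (total > 0.0 && t < T) {
        int j = pick_channel(rates, total);
        apply_channel(j, &n, &s);
      }
    }
    absorbed[i] = hit;
  }
  return List::create(_["absorbed"] = absorbed, _["first_passage_time"] = fpt);
}

// Synthetic particle-tracking trajectories: 2-D switching diffusion sampled
// at the frame interval dt. Within each frame the chain is simulated
// continuously and the free (s = 0) time accumulated; the frame displacement
// per axis is Gaussian with variance 2 D_P t_free. Localization noise of sd
// `sigma` is added independently per coordinate per frame at read-out.
// Returns an (n_frames x 2 n_tracks) matrix of noisy positions.
// [[Rcpp::export(name = ".tracks_cpp")]]
NumericMatrix tracks_cpp(int N, double k_on, double k_onp, double k_off,
                         double a_on, double a_off, double C, double g0,
                         double D_P, int n_tracks, int n_frames, double dt,
                         double sigma) {
  NumericMatrix pos(n_frames, 2 * n_tracks);
  double rates[6];

  for (int i = 0; i < n_tracks; ++i) {
    int n = 0, s = 0;
    double x = 0.0, y = 0.0;
    double carry = 0.0;  // dwell time carried over into the next frame
    bool carry_free = false;
    pos(0, 2 * i) = x + sigma * norm_rand();
    pos(0, 2 * i + 1) = y + sigma * norm_rand();
    for (int f = 1; f < n_frames; ++f) {
      double t = 0.0, t_free = 0.0;
      while (t < dt) {
        double dwell;
        bool free_now;
        if (carry > 0.0) {
          dwell = carry; free_now = carry_free; carry = 0.0;
        } else {
          state_rates(n, s, N, k_on, k_onp, k_off, a_on, a_off, C, g0, rates);
          double total = 0.0;
          for (int j = 0; j < 6; ++j) total += rates[j];
          free_now = (s == 0);
          if (total > 0.0) {
            dwell = exp_rand() / total;
            int j = pick_channel(rates, total);
            apply_channel(j, &n, &s);
          } else {
            dwell = dt;  // frozen chain: coast
          }
        }
        if (t + dwell > dt) {
          // dwell spills into the next frame; the chain state has already
          // advanced but the carried remainder belongs to the dwell *before*
          // that transition, so remember its mobility flag
          carry = t + dwell - dt;
          carry_free = free_now;
          dwell = dt - t;
        }
        if (free_now) t_free += dwell;
        t += dwell;
      }
      double sd = std::sqrt(2.0 * D_P * t_free);
      x += sd * norm_rand();
      y += sd * norm_rand();
      pos(f, 2 * i) = x + sigma * norm_rand();
      pos(f, 2 * i + 1) = y + sigma * norm_rand();
    }
  }
  return pos;
}
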