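#include <Rcpp.h>
using namespace Rcpp;

// Navarro-Fuss approximation to the Wiener first-passage-time density at the
// LOWER boundary, unit diffusion coefficient. The small-time and large-time
// series are truncated so the approximation error is below eps; whichever
// series needs fewer terms is used.
static double nf_density_lower(double t, double v, double a, double w,
                               double eps) {
  if (!(t > 0.0) || !R_finite(t)) return 0.0;
  double tt = t / (a * a);  // time in boundary-normalised units

  double ks, kl;
  if (2.0 * sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + sqrt(-2.0 * tt * log(2.0 * eps * sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = sqrt(-2.0 * log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) {
    int K = (int)ceil(ks);
    int lo = -(int)floor((K - 1) / 2.0);
    int hi = (int)ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      p += z * exp(-z * z / (2.0 * tt));
    }
    p /= sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * exp(-k * k * M_PI * M_PI * tt / 2.0) * sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  double f = p * exp(-v * a * w - v * v * t / 2.0) / (a * a);
  return f > 0.0 ? f : 0.0;
}

// [[Rcpp::export]]
double wfpt_density_cpp(double t, double v, double a, double w, double eps) {
  return nf_density_lower(t, v, a, w, eps);
}

// Negative log-likelihood of one subject's trials under the hybrid RLDDM.
// chosen: 0/1 stimulus ids; feedback_unit: +-1 (ignored on late trials);
// late trials contribute neither likelihood nor learning. The observed
// response is scored at the boundary the model drifts toward when the chosen
// stimulus has the higher Q (drift kappa * (Q_chosen - Q_unchosen), response
// boundary convention handled by a sign flip).
// [[Rcpp::export]]
double rlddm_negloglik_cpp(NumericVector rt, IntegerVector chosen,
                           NumericVector feedback_unit, LogicalVector late,
                           double kappa, double a, double alpha, double ndt,
                           double eps) {
  int n = rt.size();
  double q[2] = {0.0, 0.0};
  double nll = 0.0;
  const double log_floor = log(1e-300);
  for (int i = 0; i < n; ++i) {
    if (late[i]) continue;
    int c = chosen[i];
    double v = kappa * (q[c] - q[1 - c]);
    double dt_dec = rt[i] - ndt;
    double f = nf_density_lower(dt_dec, -v, a, 0.5, eps);
    nll -= (f > 1e-300) ? log(f) : log_floor;
    q[c] += alpha * (feedback_unit[i] - q[c]);
  }
  return nll;
}

// Batch first-passage simulation of the bounded accumulator (Euler-Maruyama,
// start a/2, absorbing bounds at 0 and a, diffusion coefficient 1).
// Returns boundary (+1 upper, -1 lower, 0 censored at max_time), decision
// time (n_steps * dt) and the rectangle-rule area under the clipped path.
// [[Rcpp::export]]
List ddm_paths_cpp(int n, double v, double a, double dt, double max_time) {
  IntegerVector boundary(n);
  NumericVector dtime(n), area(n);
  int max_steps = (int)ceil(max_time / dt);
  double sddt = sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = a / 2.0;
    double A = 0.0;
    int b = 0;
    int step = 0;
    while (step < max_steps) {
      x += v * dt + sddt * norm_rand();
      ++step;
      if (x >= a) { x = a; b = 1; }
      else if (x <= 0.0) { x = 0.0; b = -1; }
      A += x * dt;
      if (b != 0) break;
    }
    boundary[i] = b;
    dtime[i] = step * dt;
    area[i] = A;
  }
  return List::create(_["boundary"] = boundary, _["decision_time"] = dtime,
                      _["area"] = area);
}

// One path decision: returns +1/-1/0 and the decision time via out params.
static inline int ddm_one(double v, double a, double dt, int max_steps,
                          double sddt, double *dtime) {
  double x = a / 2.0;
  int step = 0;
  while (step < max_steps) {
    x += v * dt + sddt * norm_rand();
    ++step;
    if (x >= a) { *dtime = step * dt; return 1; }
    if (x <= 0.0) { *dtime = step * dt; return -1; }
  }
  *dtime = max_steps * dt;
  return 0;
}

// Simulate one agent on the probabilistic-reversal task. Stimuli are 0 and 1;
// drift is kappa * (Q0 - Q1), upper boundary = choose stimulus 0. A trial not
// absorbed within (deadline - ndt) is late: no choice, no feedback, no
// learning, and the reversal streak resets. After crit_k consecutive choices
// of the high-probability stimulus, a buffer count is drawn uniformly from
// {buf_lo..buf_hi}; the contingency flips after that many further trials.
// [[Rcpp::export]]
List simulate_agent_cpp(int n_trials, double p_high, double p_low, int crit_k,
                        int buf_lo, int buf_hi, double deadline, double kappa,
                        double a, double alpha, double ndt, double dt) {
  IntegerVector high_stim(n_trials), chosen(n_trials), late(n_trials),
      reversal(n_trials);
  NumericVector rt(n_trials), feedback(n_trials), q1tr(n_trials),
      q2tr(n_trials);
  double q[2] = {0.0, 0.0};
  int high = (unif_rand() < 0.5) ? 0 : 1;
  int streak = 0, buffer = -1;  // buffer < 0: no reversal pending
  double max_dt_time = deadline - ndt;
  int max_steps = (int)ceil(max_dt_time / dt);
  double sddt = sqrt(dt);

  for (int t = 0; t < n_trials; ++t) {
    int rev = 0;
    if (buffer == 0) {
      high = 1 - high;
      rev = 1;
      streak = 0;
      buffer = -1;
    }
    reversal[t] = rev;
    high_stim[t] = high;
    q1tr[t] = q[0];
    q2tr[t] = q[1];

    double v = kappa * (q[0] - q[1]);
    double dtime;
    int b = ddm_one(v, a, dt, max_steps, sddt, &dtime);
    if (b == 0) {
      late[t] = 1;
      chosen[t] = NA_INTEGER;
      rt[t] = NA_REAL;
      feedback[t] = NA_REAL;
      streak = 0;
    } else {
      int c = (b == 1) ? 0 : 1;
      chosen[t] = c;
      rt[t] = dtime + ndt;
      double p_pos = (c == high) ? p_high : p_low;
      double r = (unif_rand() < p_pos) ? 1.0 : -1.0;
      feedback[t] = r;
      q[c] += alpha * (r - q[c]);
      if (buffer < 0) {
        streak = (c == high) ? streak + 1 : 0;
        if (streak >= crit_k) {
          buffer = buf_lo + (int)floor(unif_rand() * (buf_hi - buf_lo + 1));
          if (buffer > buf_hi) buffer = buf_hi;  // guard unif_rand() == 1
        }
      }
    }
    if (buffer > 0) --buffer;
  }
  return List::create(
      _["high_prob_stim"] = high_stim, _["chosen_stim"] = chosen,
      _["rt"] = rt, _["feedback_unit"] = feedback, _["late"] = late,
      _["reversal_onset"] = reversal, _["q1"] = q1tr, _["q2"] = q2tr);
}

// Repeated whole-task simulation at fixed parameters, aggregated into the
// per-choice-category summaries used by the generative check: counts and RT
// sums for choices of the currently high- vs low-probability stimulus.
// [[Rcpp::export]]
NumericVector generative_sim_cpp(int n_reps, int n_trials, double p_high,
                                 double p_low, int crit_k, int buf_lo,
                                 int buf_hi, double deadline, double kappa,
                                 double a, double alpha, double ndt,
                                 double dt) {
  double n_hi = 0, n_lo = 0, rt_hi = 0, rt_lo = 0, n_late = 0;
  double max_dt_time = deadline - ndt;
  int max_steps = (int)ceil(max_dt_time / dt);
  double sddt = sqrt(dt);
  for (int rep = 0; rep < n_reps; ++rep) {
    double q[2] = {0.0, 0.0};
    int high = (unif_rand() < 0.5) ? 0 : 1;
    int streak = 0, buffer = -1;
    for (int t = 0; t < n_trials; ++t) {
      if (buffer == 0) {
        high = 1 - high;
        streak = 0;
        buffer = -1;
      }
      double v = kappa * (q[0] - q[1]);
      double dtime;
      int b = ddm_one(v, a, dt, max_steps, sddt, &dtime);
      if (b == 0) {
        n_late += 1;
        streak = 0;
      } else {
        int c = (b == 1) ? 0 : 1;
        double trt = dtime + ndt;
        if (c == high) { n_hi += 1; rt_hi += trt; }
        else           { n_lo += 1; rt_lo += trt; }
        double p_pos = (c == high) ? p_high : p_low;
        double r = (unif_rand() < p_pos) ? 1.0 : -1.0;
        q[c] += alpha * (r - q[c]);
        if (buffer < 0) {
          streak = (c == high) ? streak + 1 : 0;
          if (streak >= crit_k) {
            buffer = buf_lo + (int)floor(unif_rand() * (buf_hi - buf_lo + 1));
            if (buffer > buf_hi) buffer = buf_hi;
          }
        }
      }
      if (buffer > 0) --buffer;
    }
  }
  return NumericVector::create(
      _["n_high"] = n_hi, _["n_low"] = n_lo, _["rt_sum_high"] = rt_hi,
      _["rt_sum_low"] = rt_lo, _["n_late"] = n_late);
}
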