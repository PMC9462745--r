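#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Action row order everywhere: 0 = left, 1 = wait, 2 = right.
// Integer action coding in outputs: -1 = left, 0 = timeout, +1 = right.

static inline void softmax3(const double *s, double *p) {
  double m = std::max(s[0], std::max(s[1], s[2]));
  double e0 = std::exp(s[0] - m), e1 = std::exp(s[1] - m),
         e2 = std::exp(s[2] - m);
  double z = e0 + e1 + e2;
  p[0] = e0 / z; p[1] = e1 / z; p[2] = e2 / z;
}

// Run a batch of episodes under a frozen policy.
// Returns outcomes and, optionally, per-step decision-variable traces
// (columns: dsr, ds_s, ds_c) up to and including the decision step.
// [[Rcpp::export]]
List cpp_run_batch(NumericVector taus, double dt, int n_steps,
                   double sd_sample, double sigma_I,
                   NumericMatrix theta_s, NumericMatrix theta_c,
                   NumericVector b, NumericVector mus, bool want_traces) {
  int n_tau = taus.size(), n_epi = mus.size();
  std::vector<double> decay(n_tau), gain(n_tau);
  for (int j = 0; j < n_tau; ++j) {
    decay[j] = std::exp(-dt / taus[j]);
    gain[j] = 1.0 - decay[j];
  }
  IntegerVector action(n_epi), step(n_epi), reward(n_epi);
  List traces(want_traces ? n_epi : 0);
  std::vector<double> xs(n_tau), xc(n_tau), ys(n_tau), yc(n_tau);
  std::vector<double> buf;
  if (want_traces) buf.reserve(3 * n_steps);

  for (int e = 0; e < n_epi; ++e) {
    double mu = mus[e];
    std::fill(xs.begin(), xs.end(), 0.0);
    std::fill(xc.begin(), xc.end(), 0.0);
    if (want_traces) buf.clear();
    int a_out = 0, k_out = n_steps;
    for (int k = 1; k <= n_steps; ++k) {
      double s = R::rnorm(mu, sd_sample);
      double sums[3] = {b[0], b[1], b[2]};
      for (int j = 0; j < n_tau; ++j) {
        xs[j] = xs[j] * decay[j] + gain[j] * s;
        xc[j] = xc[j] * decay[j] + gain[j];
        ys[j] = sigma_I > 0 ? xs[j] + R::norm_rand() * sigma_I : xs[j];
        yc[j] = sigma_I > 0 ? xc[j] + R::norm_rand() * sigma_I : xc[j];
      }
      double ss[3] = {0, 0, 0}, sc[3] = {0, 0, 0};
      for (int j = 0; j < n_tau; ++j) {
        ss[0] += theta_s(0, j) * ys[j];
        ss[1] += theta_s(1, j) * std::fabs(ys[j]);
        ss[2] += theta_s(2, j) * ys[j];
        sc[0] += theta_c(0, j) * yc[j];
        sc[1] += theta_c(1, j) * yc[j];
        sc[2] += theta_c(2, j) * yc[j];
      }
      for (int a = 0; a < 3; ++a) sums[a] += ss[a] + sc[a];
      if (want_traces) {
        double ds_s = ss[2] - ss[1];
        double ds_c = (sc[1] + b[1]) - (sc[2] + b[2]);
        buf.push_back(sums[2] - sums[1]); // dsr
        buf.push_back(ds_s);
        buf.push_back(ds_c);
      }
      double p[3];
      softmax3(sums, p);
      double u = R::unif_rand();
      int a = u < p[0] ? 0 : (u < p[0] + p[1] ? 1 : 2);
      if (a != 1) { a_out = (a == 0) ? -1 : 1; k_out = k; break; }
    }
    action[e] = a_out;
    step[e] = k_out;
    reward[e] = (a_out != 0 && ((a_out > 0) == (mu > 0)) && mu != 0) ? 1 : 0;
    if (want_traces) {
      int nk = buf.size() / 3;
      NumericMatrix tr(nk, 3);
      for (int k = 0; k < nk; ++k)
        for (int c = 0; c < 3; ++c) tr(k, c) = buf[3 * k + c];
      colnames(tr) = CharacterVector::create("dsr", "ds_s", "ds_c");
      traces[e] = tr;
    }
  }
  List out = List::create(_["action"] = action, _["step"] = step,
                          _["reward"] = reward);
  if (want_traces) out["traces"] = traces;
  return out;
}

// One chunk of online actor-critic TD(lambda) training. Parameters are
// modified in cloned copies and returned together with per-episode outcomes.
// [[Rcpp::export]]
List cpp_train_chunk(NumericVector taus, double dt, int n_steps,
                     double sd_sample, double sigma_I, double sigma_mu,
                     NumericMatrix theta_s_in, NumericMatrix theta_c_in,
                     NumericVector b_in, NumericVector w_s_in,
                     NumericVector w_c_in, double b_v, int n_episodes,
                     double lr_a, double lr_c, double lambda_a,
                     double lambda_c, double gamma, double guard,
                     bool train_clock, bool batched, double delta_clip) {
  int n_tau = taus.size();
  NumericMatrix theta_s = clone(theta_s_in), theta_c = clone(theta_c_in);
  NumericVector b = clone(b_in), w_s = clone(w_s_in), w_c = clone(w_c_in);
  std::vector<double> decay(n_tau), gain(n_tau);
  for (int j = 0; j < n_tau; ++j) {
    decay[j] = std::exp(-dt / taus[j]);
    gain[j] = 1.0 - decay[j];
  }
  NumericVector mu_out(n_episodes);
  IntegerVector action(n_episodes), step(n_episodes), reward(n_episodes);

  std::vector<double> xs(n_tau), xc(n_tau), ys(n_tau), yc(n_tau);
  std::vector<double> ea_s(3 * n_tau), ea_c(3 * n_tau), ea_b(3);
  std::vector<double> ec_s(n_tau), ec_c(n_tau);
  // accumulators for per-episode (batched) application of the updates
  std::vector<double> da_s(3 * n_tau), da_c(3 * n_tau), da_b(3);
  std::vector<double> dc_s(n_tau), dc_c(n_tau);
  double dc_bv = 0.0, ec_bv = 0.0, V_prev = 0.0;

  // one TD(lambda) update, applied online or into the episode accumulator;
  // the TD error is clipped to +/- delta_clip, which bounds the gain of the
  // value->update->value feedback loop without moving its fixed points
  auto apply_updates = [&](double delta) {
    if (delta > delta_clip) delta = delta_clip;
    if (delta < -delta_clip) delta = -delta_clip;
    double ga = lr_a * delta, gc = lr_c * delta;
    for (int aa = 0; aa < 3; ++aa) {
      for (int j = 0; j < n_tau; ++j) {
        if (batched) {
          da_s[aa * n_tau + j] += ga * ea_s[aa * n_tau + j];
          if (train_clock) da_c[aa * n_tau + j] += ga * ea_c[aa * n_tau + j];
        } else {
          theta_s(aa, j) += ga * ea_s[aa * n_tau + j];
          if (train_clock) theta_c(aa, j) += ga * ea_c[aa * n_tau + j];
        }
      }
      if (batched) da_b[aa] += ga * ea_b[aa];
      else b[aa] += ga * ea_b[aa];
    }
    for (int j = 0; j < n_tau; ++j) {
      if (batched) {
        dc_s[j] += gc * ec_s[j];
        dc_c[j] += gc * ec_c[j];
      } else {
        w_s[j] += gc * ec_s[j];
        w_c[j] += gc * ec_c[j];
      }
    }
    if (batched) dc_bv += gc * ec_bv;
    else b_v += gc * ec_bv;
  };

  for (int e = 0; e < n_episodes; ++e) {
    double mu = R::rnorm(0.0, sigma_mu);
    if (batched) {
      std::fill(da_s.begin(), da_s.end(), 0.0);
      std::fill(da_c.begin(), da_c.end(), 0.0);
      std::fill(da_b.begin(), da_b.end(), 0.0);
      std::fill(dc_s.begin(), dc_s.end(), 0.0);
      std::fill(dc_c.begin(), dc_c.end(), 0.0);
      dc_bv = 0.0;
    }
    std::fill(xs.begin(), xs.end(), 0.0);
    std::fill(xc.begin(), xc.end(), 0.0);
    std::fill(ea_s.begin(), ea_s.end(), 0.0);
    std::fill(ea_c.begin(), ea_c.end(), 0.0);
    std::fill(ea_b.begin(), ea_b.end(), 0.0);
    std::fill(ec_s.begin(), ec_s.end(), 0.0);
    std::fill(ec_c.begin(), ec_c.end(), 0.0);
    ec_bv = 0.0;
    V_prev = 0.0;
    int a_out = 0, k_out = n_steps, r = 0;

    for (int k = 1; k <= n_steps; ++k) {
      double s = R::rnorm(mu, sd_sample);
      for (int j = 0; j < n_tau; ++j) {
        xs[j] = xs[j] * decay[j] + gain[j] * s;
        xc[j] = xc[j] * decay[j] + gain[j];
        ys[j] = sigma_I > 0 ? xs[j] + R::norm_rand() * sigma_I : xs[j];
        yc[j] = sigma_I > 0 ? xc[j] + R::norm_rand() * sigma_I : xc[j];
      }
      double V = b_v;
      for (int j = 0; j < n_tau; ++j)
        V += w_s[j] * std::fabs(ys[j]) + w_c[j] * yc[j];

      if (k > 1) // non-terminal transition from step k-1
        apply_updates(gamma * V - V_prev);

      double sums[3] = {b[0], b[1], b[2]};
      for (int j = 0; j < n_tau; ++j) {
        sums[0] += theta_s(0, j) * ys[j] + theta_c(0, j) * yc[j];
        sums[1] += theta_s(1, j) * std::fabs(ys[j]) + theta_c(1, j) * yc[j];
        sums[2] += theta_s(2, j) * ys[j] + theta_c(2, j) * yc[j];
      }
      double p[3];
      softmax3(sums, p);
      double u = R::unif_rand();
      int a = u < p[0] ? 0 : (u < p[0] + p[1] ? 1 : 2);

      // accumulate eligibility traces (decay, then add current gradients)
      double gl = gamma * lambda_a, gcl = gamma * lambda_c;
      for (int aa = 0; aa < 3; ++aa) {
        double coef = ((aa == a) ? 1.0 : 0.0) - p[aa];
        for (int j = 0; j < n_tau; ++j) {
          double feat = (aa == 1) ? std::fabs(ys[j]) : ys[j];
          ea_s[aa * n_tau + j] = gl * ea_s[aa * n_tau + j] + coef * feat;
          ea_c[aa * n_tau + j] = gl * ea_c[aa * n_tau + j] + coef * yc[j];
        }
        ea_b[aa] = gl * ea_b[aa] + coef;
      }
      for (int j = 0; j < n_tau; ++j) {
        ec_s[j] = gcl * ec_s[j] + std::fabs(ys[j]);
        ec_c[j] = gcl * ec_c[j] + yc[j];
      }
      ec_bv = gcl * ec_bv + 1.0;

      bool terminal = (a != 1) || (k == n_steps);
      if (terminal) {
        if (a != 1) { a_out = (a == 0) ? -1 : 1; k_out = k; }
        r = (a_out != 0 && mu != 0 && ((a_out > 0) == (mu > 0))) ? 1 : 0;
        apply_updates((double)r - V);
        break;
      }
      V_prev = V;
    }
    if (batched) { // flush the episode's accumulated updates
      for (int aa = 0; aa < 3; ++aa) {
        for (int j = 0; j < n_tau; ++j) {
          theta_s(aa, j) += da_s[aa * n_tau + j];
          if (train_clock) theta_c(aa, j) += da_c[aa * n_tau + j];
        }
        b[aa] += da_b[aa];
      }
      for (int j = 0; j < n_tau; ++j) {
        w_s[j] += dc_s[j];
        w_c[j] += dc_c[j];
      }
      b_v += dc_bv;
    }
    mu_out[e] = mu;
    action[e] = a_out;
    step[e] = k_out;
    reward[e] = r;

    double mx = 0.0;
    for (int a = 0; a < 3; ++a) {
      mx = std::max(mx, std::fabs(b[a]));
      for (int j = 0; j < n_tau; ++j)
        mx = std::max(mx, std::max(std::fabs(theta_s(a, j)),
                                   std::fabs(theta_c(a, j))));
    }
    if (!std::isfinite(mx) || mx > guard)
      stop("training diverged: max |parameter| = %f after episode %d",
           mx, e + 1);
  }
  return List::create(_["theta_s"] = theta_s, _["theta_c"] = theta_c,
                      _["b"] = b, _["w_s"] = w_s, _["w_c"] = w_c,
                      _["b_v"] = b_v, _["mu"] = mu_out,
                      _["action"] = action, _["step"] = step,
                      _["reward"] = reward);
}

// Accuracy of the single-timescale OU threshold model over a grid of
// candidate thresholds, with common random numbers across candidates.
// Returns counts of correct and decided episodes per threshold.
// [[Rcpp::export]]
List cpp_ou_grid(double tau, double dt, int n_steps, double sd_sample,
                 double sigma_I_eff, NumericVector mus,
                 NumericVector thetas) {
  int n_epi = mus.size(), n_th = thetas.size();
  double decay = std::exp(-dt / tau), gain = 1.0 - decay;
  IntegerVector correct(n_th), decided(n_th);
  std::vector<double> y(n_steps);
  for (int e = 0; e < n_epi; ++e) {
    double mu = mus[e], x = 0.0;
    for (int k = 0; k < n_steps; ++k) {
      double s = R::rnorm(mu, sd_sample);
      x = x * decay + gain * s;
      y[k] = sigma_I_eff > 0 ? x + R::norm_rand() * sigma_I_eff : x;
    }
    for (int t = 0; t < n_th; ++t) {
      double th = thetas[t];
      for (int k = 0; k < n_steps; ++k) {
        if (y[k] >= th || y[k] <= -th) {
          decided[t]++;
          if (mu != 0 && ((y[k] > 0) == (mu > 0))) correct[t]++;
          break;
        }
      }
    }
  }
  return List::create(_["correct"] = correct, _["decided"] = decided,
                      _["n"] = n_epi);
}

// Single-threshold OU decision model; optionally returns the noisy
// integrator trace up to the decision (the model's decision variable).
// [[Rcpp::export]]
List cpp_ou_decide(double tau, double dt, int n_steps, double sd_sample,
                   double sigma_I_eff, double theta, NumericVector mus,
                   bool want_traces) {
  int n_epi = mus.size();
  double decay = std::exp(-dt / tau), gain = 1.0 - decay;
  IntegerVector action(n_epi), step(n_epi), reward(n_epi);
  List traces(want_traces ? n_epi : 0);
  std::vector<double> buf;
  for (int e = 0; e < n_epi; ++e) {
    double mu = mus[e], x = 0.0;
    if (want_traces) buf.clear();
    int a_out = 0, k_out = n_steps;
    for (int k = 1; k <= n_steps; ++k) {
      double s = R::rnorm(mu, sd_sample);
      x = x * decay + gain * s;
      double y = sigma_I_eff > 0 ? x + R::norm_rand() * sigma_I_eff : x;
      if (want_traces) buf.push_back(y);
      if (y >= theta) { a_out = 1; k_out = k; break; }
      if (y <= -theta) { a_out = -1; k_out = k; break; }
    }
    action[e] = a_out;
    step[e] = k_out;
    reward[e] = (a_out != 0 && mu != 0 && ((a_out > 0) == (mu > 0))) ? 1 : 0;
    if (want_traces) traces[e] = NumericVector(buf.begin(), buf.end());
  }
  List out = List::create(_["action"] = action, _["step"] = step,
                          _["reward"] = reward);
  if (want_traces) out["traces"] = traces;
  return out;
}

// First-passage simulation of the pure (leak-free) drift-diffusion model:
// x accumulates s_t * dt with s_t ~ N(mu, sd_sample), absorbing at +/- theta.
// [[Rcpp::export]]
List cpp_ddm_fpt(double mu, double sd_sample, double theta, double dt,
                 int max_steps, int n) {
  IntegerVector steps(n), side(n);
  for (int e = 0; e < n; ++e) {
    double x = 0.0;
    int k_out = NA_INTEGER, s_out = 0;
    for (int k = 1; k <= max_steps; ++k) {
      x += R::rnorm(mu, sd_sample) * dt;
      if (x >= theta) { k_out = k; s_out = 1; break; }
      if (x <= -theta) { k_out = k; s_out = -1; break; }
    }
    steps[e] = k_out;
    side[e] = s_out;
  }
  return List::create(_["steps"] = steps, _["side"] = side);
}
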