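#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gillespie realizations of a continuous-time Markov chain.
// 'rates' is the off-diagonal matrix in ms^-1 (diagonal ignored),
// 'durations' the per-path duration in ms, 'init_probs' the distribution of
// the initial state. Uses R's RNG so results are governed by set.seed().
// Returns one row per constant-state segment.
// [[Rcpp::export]]
DataFrame cpp_ctmc_segments(NumericVector durations, NumericMatrix rates,
                            NumericVector init_probs) {
  const int n_paths = durations.size();
  const int n_states = rates.nrow();
  std::vector<double> exit_rate(n_states, 0.0);
  for (int i = 0; i < n_states; ++i)
    for (int j = 0; j < n_states; ++j)
      if (i != j) exit_rate[i] += rates(i, j);

  std::vector<int> path_id, state;
  std::vector<double> t0, t1;
  path_id.reserve(n_paths * 4);

  for (int p = 0; p < n_paths; ++p) {
    const double T = durations[p];
    // initial state
    double u = unif_rand();
    int s = n_states - 1;
    double acc = 0.0;
    for (int i = 0; i < n_states; ++i) {
      acc += init_probs[i];
      if (u <= acc) { s = i; break; }
    }
    double t = 0.0;
    while (t < T) {
      double dwell = (exit_rate[s] > 0.0)
        ? R::rexp(1.0 / exit_rate[s]) : R_PosInf;
      double tn = std::min(t + dwell, T);
      path_id.push_back(p + 1);
      state.push_back(s + 1);
      t0.push_back(t);
      t1.push_back(tn);
      if (tn >= T) break;
      // next state with probability k[s,j]/exit_rate[s]
      double v = unif_rand() * exit_rate[s];
      double c = 0.0;
      int nxt = s;
      for (int j = 0; j < n_states; ++j) {
        if (j == s) continue;
        c += rates(s, j);
        if (v <= c) { nxt = j; break; }
      }
      s = nxt;
      t = tn;
    }
  }
  return DataFrame::create(_["path"] = path_id, _["state"] = state,
                           _["t0_ms"] = t0, _["t1_ms"] = t1);
}

// Monte-Carlo forward sampler for dynamic PDA. For each requested sample:
// draw one sigma-broadened distance per state, run a CTMC path over the bin,
// form the intensity-weighted mean proximity ratio (corrections and
// backgrounds folded in) and draw the acceptor count from a binomial.
// counts N are supplied (resampled from the measured bin-count library in R).
// Rates in ms^-1, bin in ms, brightness and backgrounds in counts/ms.
// [[Rcpp::export]]
IntegerVector cpp_pda_sample(NumericMatrix rates, NumericVector init_probs,
                             double bin_ms, IntegerVector N,
                             NumericVector distances, double R0,
                             double sigma, double g, double lk, double de,
                             double brightness, double bg_d, double bg_a) {
  const int n_states = rates.nrow();
  const int n = N.size();
  std::vector<double> exit_rate(n_states, 0.0);
  for (int i = 0; i < n_states; ++i)
    for (int j = 0; j < n_states; ++j)
      if (i != j) exit_rate[i] += rates(i, j);

  IntegerVector na(n);
  std::vector<double> E(n_states), dwell(n_states);

  for (int m = 0; m < n; ++m) {
    for (int s = 0; s < n_states; ++s) {
      double R = R::rnorm(distances[s], sigma * distances[s]);
      if (R < 1.0) R = 1.0;
      double r6 = std::pow(R / R0, 6.0);
      E[s] = 1.0 / (1.0 + r6);
      dwell[s] = 0.0;
    }
    // CTMC path over the bin
    double u = unif_rand();
    int s = n_states - 1;
    double acc = 0.0;
    for (int i = 0; i < n_states; ++i) {
      acc += init_probs[i];
      if (u <= acc) { s = i; break; }
    }
    double t = 0.0;
    while (t < bin_ms) {
      double dw = (exit_rate[s] > 0.0)
        ? R::rexp(1.0 / exit_rate[s]) : R_PosInf;
      double tn = std::min(t + dw, bin_ms);
      dwell[s] += tn - t;
      if (tn >= bin_ms) break;
      double v = unif_rand() * exit_rate[s];
      double c = 0.0;
      int nxt = s;
      for (int j = 0; j < n_states; ++j) {
        if (j == s) continue;
        c += rates(s, j);
        if (v <= c) { nxt = j; break; }
      }
      s = nxt;
      t = tn;
    }
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n_states; ++k) {
      double rda = brightness * (g * E[k] + lk * (1.0 - E[k]) + de * g) + bg_a;
      double rdd = brightness * (1.0 - E[k]) + bg_d;
      num += dwell[k] * rda;
      den += dwell[k] * (rda + rdd);
    }
    double p = (den > 0.0) ? num / den : 0.0;
    na[m] = (int) R::rbinom((double) N[m], p);
  }
  return na;
}

// Rao-Blackwellized PDA forward histogram: as cpp_pda_sample, but instead of
// drawing one acceptor count per sample, the exact Binomial(N, p) mass is
// accumulated onto the PR grid. Removes the shot-noise sampling variance
// from the Monte-Carlo estimate; only the state-path / sigma randomness
// remains. Returns the unnormalized probability histogram (grid_e bins).
// [[Rcpp::export]]
NumericVector cpp_pda_forward_hist(NumericMatrix rates,
                                   NumericVector init_probs, double bin_ms,
                                   IntegerVector N, NumericVector distances,
                                   double R0, double sigma, double g,
                                   double lk, double de, double brightness,
                                   double bg_d, double bg_a, int grid_e,
                                   bool couple_n) {
  const int n_states = rates.nrow();
  const int n = N.size();
  std::vector<double> exit_rate(n_states, 0.0);
  for (int i = 0; i < n_states; ++i)
    for (int j = 0; j < n_states; ++j)
      if (i != j) exit_rate[i] += rates(i, j);

  // reference donor-window intensity (stationary average over the states
  // at their mean distances) for the optional count-intensity coupling
  double int_ref = 0.0;
  for (int s = 0; s < n_states; ++s) {
    double Em = 1.0 / (1.0 + std::pow(distances[s] / R0, 6.0));
    double rda = brightness * (g * Em + lk * (1.0 - Em) + de * g) + bg_a;
    double rdd = brightness * (1.0 - Em) + bg_d;
    int_ref += init_probs[s] * (rda + rdd);
  }

  NumericVector hist(grid_e);
  std::vector<double> E(n_states), dwell(n_states);

  // Fixed randomness budget per sample (common-random-numbers scheme):
  // every sample consumes exactly the same number of draws whatever its
  // path looks like, so the Monte-Carlo error of the histogram varies
  // smoothly with the rates during optimization instead of being
  // re-rolled by every parameter move. Path draws come from an inline
  // xorshift128+ stream seeded once per call from R's RNG (keeps
  // set.seed() determinism at a fraction of the per-draw cost).
  const int MAXTR = 64;
  std::vector<double> u_exp(MAXTR), u_jump(MAXTR);
  uint64_t xs0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
    (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t xs1 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
    (uint64_t)(unif_rand() * 4294967296.0);
  if (xs0 == 0) xs0 = 0x9E3779B97F4A7C15ULL;
  if (xs1 == 0) xs1 = 0xBF58476D1CE4E5B9ULL;
  auto xnext = [&]() -> double {
    uint64_t x = xs0;
    const uint64_t y = xs1;
    xs0 = y;
    x ^= x << 23;
    xs1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    // uniform in (0, 1), never exactly 0
    return (((xs1 + y) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  };

  for (int m = 0; m < n; ++m) {
    for (int s = 0; s < n_states; ++s) {
      double R = R::rnorm(distances[s], sigma * distances[s]);
      if (R < 1.0) R = 1.0;
      E[s] = 1.0 / (1.0 + std::pow(R / R0, 6.0));
      dwell[s] = 0.0;
    }
    double u0 = xnext();
    for (int k = 0; k < MAXTR; ++k) {
      u_exp[k] = -std::log(xnext());
      u_jump[k] = xnext();
    }
    int s = n_states - 1;
    double acc = 0.0;
    for (int i = 0; i < n_states; ++i) {
      acc += init_probs[i];
      if (u0 <= acc) { s = i; break; }
    }
    double t = 0.0;
    for (int k = 0; k < MAXTR && t < bin_ms; ++k) {
      double dw = (exit_rate[s] > 0.0)
        ? u_exp[k] / exit_rate[s] : R_PosInf;
      double tn = std::min(t + dw, bin_ms);
      dwell[s] += tn - t;
      if (tn >= bin_ms) { t = tn; break; }
      double v = u_jump[k] * exit_rate[s];
      double c = 0.0;
      int nxt = s;
      for (int j = 0; j < n_states; ++j) {
        if (j == s) continue;
        c += rates(s, j);
        if (v <= c) { nxt = j; break; }
      }
      s = nxt;
      t = tn;
    }
    if (t < bin_ms) dwell[s] += bin_ms - t;  // randomness budget exhausted
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n_states; ++k) {
      double rda = brightness * (g * E[k] + lk * (1.0 - E[k]) + de * g) + bg_a;
      double rdd = brightness * (1.0 - E[k]) + bg_d;
      num += dwell[k] * rda;
      den += dwell[k] * (rda + rdd);
    }
    double p = (den > 0.0) ? num / den : 0.0;
    int Nm = N[m];
    if (couple_n && int_ref > 0.0) {
      // window photon count scales with the path's detected intensity
      double i_rel = den / (bin_ms * int_ref);
      Nm = (int) std::lround(Nm * i_rel);
      if (Nm < 1) Nm = 1;
    }
    // binomial mass by outward recurrence from the mode (only the ~6-sigma
    // core carries mass above the cutoff)
    if (p <= 0.0 || p >= 1.0) {
      int a = (p >= 1.0) ? Nm : 0;
      int b = (int) std::floor(((double) a / Nm) * grid_e);
      if (b >= grid_e) b = grid_e - 1;
      hist[b] += 1.0;
    } else {
      const int mode = (int) std::floor((Nm + 1) * p);
      const double pm = R::dbinom((double) mode, (double) Nm, p, 0);
      const double odds = p / (1.0 - p);
      double mass = pm;
      for (int a = mode; a <= Nm && mass > 1e-12; ++a) {
        int b = (int) std::floor(((double) a / Nm) * grid_e);
        if (b >= grid_e) b = grid_e - 1;
        hist[b] += mass;
        mass *= odds * (double) (Nm - a) / (double) (a + 1);
      }
      mass = pm * (double) mode / (odds * (double) (Nm - mode + 1));
      for (int a = mode - 1; a >= 0 && mass > 1e-12; --a) {
        int b = (int) std::floor(((double) a / Nm) * grid_e);
        hist[b] += mass;
        mass *= (double) a / (odds * (double) (Nm - a + 1));
      }
    }
  }
  return hist;
}

// Multi-tau correlator on uniformly binned signals. Returns the symmetric
// normalized estimator G(tau) = <dx dy>/(<x><y>) on a quasi-logarithmic lag
// grid: m linear lags per cascade, bin width doubling between cascades.
// [[Rcpp::export]]
DataFrame cpp_multitau(NumericVector x, NumericVector y, double bin_s,
                       int m, int n_cascades) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> lag_out, g_out;
  double width = bin_s;

  for (int casc = 0; casc < n_cascades; ++casc) {
    const int n = (int) xv.size();
    int k_lo = (casc == 0) ? 1 : m / 2 + 1;
    if (n <= m + 1) break;
    for (int k = k_lo; k <= m; ++k) {
      const int nn = n - k;
      if (nn < 8) break;
      double sxy = 0.0, sx = 0.0, sy = 0.0;
      for (int i = 0; i < nn; ++i) {
        sxy += xv[i] * yv[i + k];
        sx  += xv[i];
        sy  += yv[i + k];
      }
      if (sx > 0.0 && sy > 0.0) {
        lag_out.push_back(k * width);
        g_out.push_back(sxy * nn / (sx * sy) - 1.0);
      }
    }
    // coarsen by 2
    const int nh = n / 2;
    for (int i = 0; i < nh; ++i) {
      xv[i] = xv[2 * i] + xv[2 * i + 1];
      yv[i] = yv[2 * i] + yv[2 * i + 1];
    }
    xv.resize(nh);
    yv.resize(nh);
    width *= 2.0;
  }
  return DataFrame::create(_["lag_s"] = lag_out, _["G"] = g_out);
}

// Accumulate photon weights onto a uniform time grid.
// [[Rcpp::export]]
NumericVector cpp_bin_weights(NumericVector t_s, NumericVector w,
                              double bin_s, double t0_s, int n_bins) {
  NumericVector out(n_bins);
  const int n = t_s.size();
  for (int i = 0; i < n; ++i) {
    int b = (int) std::floor((t_s[i] - t0_s) / bin_s);
    if (b >= 0 && b < n_bins) out[b] += w[i];
  }
  return out;
}

// ALEX-2CDE burst-asymmetry score (kernel-density construction with an
// exponential kernel of time constant tau_s). Photons must be time-ordered;
// bursts are given as 1-based inclusive index ranges. slot: 1 = donor
// excitation, 2 = acceptor excitation. Score ~0 for interleaved streams,
// ~100 for fully separated channels; +Inf when either slot has < 2 photons.
// [[Rcpp::export]]
NumericVector cpp_alex2cde(NumericVector t_s, IntegerVector slot,
                           IntegerVector start_idx, IntegerVector end_idx,
                           double tau_s) {
  const int nb = start_idx.size();
  NumericVector score(nb);

  for (int b = 0; b < nb; ++b) {
    const int i0 = start_idx[b] - 1, i1 = end_idx[b] - 1;
    const int n = i1 - i0 + 1;
    int nD = 0, nA = 0;
    for (int i = i0; i <= i1; ++i) (slot[i] == 1) ? ++nD : ++nA;
    if (nD < 2 || nA < 2) { score[b] = R_PosInf; continue; }

    std::vector<double> kdeD(n, 0.0), kdeA(n, 0.0);
    // forward pass (left neighbours, self excluded)
    double aD = 0.0, aA = 0.0, tprev = t_s[i0];
    for (int i = i0; i <= i1; ++i) {
      double dec = std::exp(-(t_s[i] - tprev) / tau_s);
      aD *= dec; aA *= dec;
      kdeD[i - i0] += aD; kdeA[i - i0] += aA;
      if (slot[i] == 1) aD += 1.0; else aA += 1.0;
      tprev = t_s[i];
    }
    // backward pass (right neighbours)
    aD = 0.0; aA = 0.0; tprev = t_s[i1];
    for (int i = i1; i >= i0; --i) {
      double dec = std::exp(-(tprev - t_s[i]) / tau_s);
      aD *= dec; aA *= dec;
      kdeD[i - i0] += aD; kdeA[i - i0] += aA;
      if (slot[i] == 1) aD += 1.0; else aA += 1.0;
      tprev = t_s[i];
    }
    // +1 in the denominator regularizes photons with an empty same-slot
    // neighbourhood (Tomov-style nbKDE correction)
    double br1 = 0.0, br2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (slot[i0 + i] == 1)
        br1 += kdeA[i] / (kdeD[i] + 1.0);
      else
        br2 += kdeD[i] / (kdeA[i] + 1.0);
    }
    br1 /= (double) nA;  // (nD/nA) * mean over donor-slot photons
    br2 /= (double) nD;
    score[b] = 100.0 - 50.0 * (br1 + br2);
  }
  return score;
}
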