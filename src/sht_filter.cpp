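#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact forward filter for the serial hypothesis-testing models.
//
// Latent state: (h, n, a) = currently tested rule, trials held, rewards
// collected since adoption; plus an optional "not testing" state when the
// test gate is enabled. Per trial the filter scores the observed choice,
// conditions on it, advances the counters with the observed reward, and
// applies the stay/switch transition kernel. The switch kernel is a
// prior-weighted softmax in hypothesis value (uniform in the prior when the
// inverse temperature is zero), with the previous hypothesis excluded and
// counters reset on adoption. All quantities that depend on learned feature
// values (switch weights, test probabilities) are precomputed in R from the
// observed stimuli/rewards -- the value trajectory never depends on the
// latent state.
//
// Arguments (R = number of rules, T = number of trials):
//   prior   length-R adoption prior at game start (sums to 1)
//   w       R x T, w(h,t) = P(observed choice at t | testing h)
//   wN      length T, P(observed choice at t | not testing); ignored if !gate
//   rewards length-T 0/1 vector
//   beta_stay, theta (length R): stay rule logistic parameters
//   sw      R x T switch weights; column t is computed from the values held
//           *before* trial t (column 1 from the zero initial values). The
//           transition after trial t uses column t+1.
//   p_test  length T, Pr(test) before trial t (from pre-trial values);
//           ignored if !gate
//   gate    whether the not-testing state exists
//
// Returns total/per-trial log-likelihood, the T x R matrix of predictive
// hypothesis marginals (before scoring each trial), and the predictive
// not-testing mass per trial.

// Deterministic per-trial quantities for the value-based switch policy:
// feature values are updated from the observed choices/stimuli/rewards with
// a single learning rate and decay; per trial (before the update from that
// trial) the prior-weighted softmax switch weights and, optionally, the
// test-gate probability are recorded. Column t is computed from the values
// held before trial t, as consumed by the forward filter.
// [[Rcpp::export]]
List sht_precompute_cpp(IntegerMatrix rule_feat, IntegerMatrix choices,
                        IntegerMatrix stimuli, IntegerVector rewards,
                        double eta, double decay, double beta_switch,
                        NumericVector prior, bool gate, double beta_test,
                        double theta_test) {
  const int T = rewards.size();
  const int R = rule_feat.nrow();
  NumericMatrix sw(R, T);
  NumericVector pt(T);
  double V[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  std::vector<double> er(R);
  for (int t = 0; t < T; ++t) {
    double ermax = R_NegInf;
    for (int h = 0; h < R; ++h) {
      double e = 0.0;
      for (int i = 0; i < 3; ++i) {
        int f = rule_feat(h, i);
        if (f > 0) e += V[i][f - 1];
      }
      er[h] = e;
      if (prior[h] > 0 && e > ermax) ermax = e;
    }
    // clamp the exponent so extreme inverse temperatures cannot underflow
    // the whole candidate set to zero (relative weights below e^-500 are
    // treated as ties; their total probability is negligible)
    for (int h = 0; h < R; ++h) {
      double u = beta_switch * (er[h] - ermax);
      sw(h, t) = prior[h] * std::exp(u < -500.0 ? -500.0 : u);
    }
    if (gate)
      pt[t] = 1.0 / (1.0 + std::exp(-beta_test * (ermax - theta_test)));
    // Rescorla-Wagner update with decay (single learning rate)
    double ER = 0.0;
    for (int i = 0; i < 3; ++i) {
      int c = choices(t, i);
      ER += c > 0 ? V[i][c - 1] : (V[i][0] + V[i][1] + V[i][2]) / 3.0;
    }
    double pe = rewards[t] - ER;
    double nV[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) nV[i][j] = V[i][j] * decay;
    for (int i = 0; i < 3; ++i) {
      int si = stimuli(t, i) - 1;
      nV[i][si] = V[i][si] + eta * pe;
    }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) V[i][j] = nV[i][j];
  }
  return List::create(_["sw"] = sw, _["p_test"] = pt);
}

// [[Rcpp::export]]
List sht_filter_cpp(NumericVector prior, NumericMatrix w, NumericVector wN,
                    IntegerVector rewards, double beta_stay,
                    NumericVector theta, NumericMatrix sw,
                    NumericVector p_test, bool gate) {
  const int R = prior.size();
  const int T = w.ncol();
  const int NC = T + 2;  // counter axis size (n can reach T)

  // state S[h][n][a], flattened
  std::vector<double> S((size_t)R * NC * NC, 0.0);
  auto idx = [&](int h, int n, int a) {
    return (size_t)h + (size_t)R * ((size_t)n + (size_t)NC * (size_t)a);
  };
  double massN = 0.0;

  if (gate) {
    double pt = p_test[0];
    for (int h = 0; h < R; ++h) S[idx(h, 0, 0)] = pt * prior[h];
    massN = 1.0 - pt;
  } else {
    for (int h = 0; h < R; ++h) S[idx(h, 0, 0)] = prior[h];
  }

  // stay probabilities depend on (n, a) and theta[h]; group rules by theta
  std::vector<double> uniq_theta;
  std::vector<int> tgrp(R);
  for (int h = 0; h < R; ++h) {
    int g = -1;
    for (size_t u = 0; u < uniq_theta.size(); ++u)
      if (uniq_theta[u] == theta[h]) { g = (int)u; break; }
    if (g < 0) { uniq_theta.push_back(theta[h]); g = uniq_theta.size() - 1; }
    tgrp[h] = g;
  }
  const int G = uniq_theta.size();
  // pstay_tab[g][n][a]
  std::vector<double> pstay_tab((size_t)G * NC * NC, 0.0);
  for (int g = 0; g < G; ++g)
    for (int n = 0; n < NC; ++n)
      for (int a = 0; a <= n; ++a) {
        double phat = (a + 1.0) / (n + 2.0);
        pstay_tab[(size_t)g + (size_t)G * ((size_t)n + (size_t)NC * a)] =
            1.0 / (1.0 + std::exp(-beta_stay * (phat - uniq_theta[g])));
      }
  auto pstay = [&](int h, int n, int a) {
    return pstay_tab[(size_t)tgrp[h] + (size_t)G * ((size_t)n +
                                                    (size_t)NC * (size_t)a)];
  };

  NumericVector ll(T);
  NumericMatrix marg(T, R);
  NumericVector massN_pre(T);
  std::vector<double> m(R), z(R);
  bool dead = false;

  std::vector<double> f(R), mg(R);
  for (int t = 0; t < T; ++t) {
    if (dead) { ll[t] = R_NegInf; continue; }
    // predictive hypothesis marginals and likelihood of the observed choice
    const double *wt = &w(0, t);
    double like = gate ? massN * wN[t] : 0.0;
    massN_pre[t] = massN;
    std::fill(mg.begin(), mg.end(), 0.0);
    for (int n = 0; n <= t; ++n)
      for (int a = 0; a <= n; ++a) {
        const double *row = &S[idx(0, n, a)];
        for (int h = 0; h < R; ++h) mg[h] += row[h];
      }
    for (int h = 0; h < R; ++h) {
      marg(t, h) = mg[h];
      like += mg[h] * wt[h];
    }
    if (!(like > 0.0) || !std::isfinite(like)) {
      ll[t] = R_NegInf;
      dead = true;
      continue;
    }
    ll[t] = std::log(like);

    // condition on the observed choice and advance counters with the
    // observed reward in one pass: (n, a) -> (n+1, a+r), scaled by
    // w(h, t) / like. Process n descending so targets never clobber
    // unread sources; clear the slot at each target level no source maps to.
    for (int h = 0; h < R; ++h) f[h] = wt[h] / like;
    if (gate) massN *= wN[t] / like;
    int r = rewards[t];
    for (int n = t; n >= 0; --n) {
      for (int a = n; a >= 0; --a) {
        const double *src = &S[idx(0, n, a)];
        double *dst = &S[idx(0, n + 1, a + r)];
        for (int h = 0; h < R; ++h) dst[h] = src[h] * f[h];
      }
      double *gap = r == 1 ? &S[idx(0, n + 1, 0)] : &S[idx(0, n + 1, n + 1)];
      for (int h = 0; h < R; ++h) gap[h] = 0.0;
    }
    for (int a = 0; a <= t + 1; ++a) {
      double *row = &S[idx(0, 0, a)];
      for (int h = 0; h < R; ++h) row[h] = 0.0;
    }

    if (t == T - 1) break;

    // stay/switch transition; switch weights from the post-outcome values
    const double *swt = &sw(0, t + 1);
    double sw_sum = 0.0;
    for (int h = 0; h < R; ++h) sw_sum += swt[h];
    for (int h = 0; h < R; ++h) m[h] = 0.0;
    for (int n = 1; n <= t + 1; ++n)
      for (int a = 0; a <= n; ++a) {
        double *row = &S[idx(0, n, a)];
        if (G == 1) {
          double ps = pstay(0, n, a);
          for (int h = 0; h < R; ++h) {
            m[h] += row[h] * (1.0 - ps);
            row[h] *= ps;
          }
        } else {
          for (int h = 0; h < R; ++h) {
            double ps = pstay(h, n, a);
            m[h] += row[h] * (1.0 - ps);
            row[h] *= ps;
          }
        }
      }
    // All exclusive sums are computed directly (O(R^2), R = 63): forming
    // them as total-minus-term cancels catastrophically when one
    // hypothesis dominates the switch weights by more than ~1e16.
    double m_tot = 0.0;
    for (int h = 0; h < R; ++h) {
      m_tot += m[h];
      if (m[h] == 0.0) { z[h] = 0.0; continue; }
      double denom = 0.0;
      for (int h2 = 0; h2 < R; ++h2)
        if (h2 != h) denom += swt[h2];
      if (!(denom > 0.0))
        stop("empty switch candidate set (all switch weight on the current "
             "hypothesis)");
      z[h] = m[h] / denom;
    }
    double pt = gate ? p_test[t + 1] : 1.0;
    double enter = gate ? massN * pt : 0.0;
    for (int h = 0; h < R; ++h) {
      if (swt[h] == 0.0 && enter == 0.0) continue;
      double acc = 0.0;
      for (int h2 = 0; h2 < R; ++h2)
        if (h2 != h) acc += z[h2];
      S[idx(h, 0, 0)] += pt * swt[h] * acc +
                         (gate ? enter * swt[h] / sw_sum : 0.0);
    }
    if (gate) massN = massN * (1.0 - pt) + (1.0 - pt) * m_tot;
  }

  double total = 0.0;
  for (int t = 0; t < T; ++t) total += ll[t];
  return List::create(_["total"] = total, _["by_trial"] = ll,
                      _["hyp_marginals"] = marg,
                      _["not_testing_mass"] = massN_pre);
}
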