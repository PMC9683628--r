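#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-game likelihood kernels for the feature RL and Bayesian rule-learning
// models. These mirror the R primitives exactly (softmax with
// max-subtraction, Rescorla-Wagner update with decay, Bayes update from the
// realized stimulus); tests assert the equivalence.

// softmax log-probability of one index given utilities beta * er
static double softmax_logp(const std::vector<double> &er, double beta,
                           int pick) {
  double mx = R_NegInf;
  for (double e : er) if (beta * e > mx) mx = beta * e;
  double s = 0.0;
  for (double e : er) s += std::exp(beta * e - mx);
  return beta * er[pick] - mx - std::log(s);
}

// [[Rcpp::export]]
double rl_game_ll_cpp(IntegerMatrix configs, IntegerMatrix choices,
                      IntegerVector choice_idx, IntegerMatrix stimuli,
                      IntegerVector rewards, double beta, double eta_s,
                      double eta_r, double decay) {
  const int T = rewards.size();
  const int C = configs.nrow();
  double V[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  std::vector<double> er(C);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double dimval[3][4];
    for (int i = 0; i < 3; ++i) {
      dimval[i][0] = (V[i][0] + V[i][1] + V[i][2]) / 3.0;
      for (int j = 0; j < 3; ++j) dimval[i][j + 1] = V[i][j];
    }
    for (int c = 0; c < C; ++c)
      er[c] = dimval[0][configs(c, 0)] + dimval[1][configs(c, 1)] +
              dimval[2][configs(c, 2)];
    ll += softmax_logp(er, beta, choice_idx[t] - 1);
    // update: PE against the chosen configuration's expected reward
    double ER = dimval[0][choices(t, 0)] + dimval[1][choices(t, 1)] +
                dimval[2][choices(t, 2)];
    double pe = rewards[t] - ER;
    double nV[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) nV[i][j] = V[i][j] * decay;
    for (int i = 0; i < 3; ++i) {
      int si = stimuli(t, i) - 1;
      double eta = choices(t, i) > 0 ? eta_s : eta_r;
      nV[i][si] = V[i][si] + eta * pe;
    }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) V[i][j] = nV[i][j];
  }
  return ll;
}

// [[Rcpp::export]]
double bayes_game_ll_cpp(IntegerVector choice_idx, IntegerVector stim_idx,
                         IntegerVector rewards, double beta,
                         IntegerVector support, NumericMatrix er_mat,
                         NumericMatrix rp_mat) {
  const int T = rewards.size();
  const int H = support.size();
  const int C = er_mat.ncol();
  std::vector<double> b(H, 1.0 / H);
  std::vector<double> er(C);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    std::fill(er.begin(), er.end(), 0.0);
    for (int k = 0; k < H; ++k) {
      int h = support[k] - 1;
      for (int c = 0; c < C; ++c) er[c] += b[k] * er_mat(h, c);
    }
    ll += softmax_logp(er, beta, choice_idx[t] - 1);
    double z = 0.0;
    for (int k = 0; k < H; ++k) {
      double rp = rp_mat(support[k] - 1, stim_idx[t] - 1);
      b[k] *= rewards[t] == 1 ? rp : 1.0 - rp;
      z += b[k];
    }
    for (int k = 0; k < H; ++k) b[k] /= z;
  }
  return ll;
}
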