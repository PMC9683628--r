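test_that("the hypothesis adoption prior weights dimensionality against the instruction", {
  spec1 <- game_spec(1, TRUE, c(1L, 0L, 0L))
  # strict instruction-following: uniform on the 9 matching rules
  p <- sht_hypothesis_prior(spec1, 0, 0)
  expect_equal(p[mdprl:::rule_dims() == 1], rep(1 / 9, 9))
  expect_equal(sum(p[mdprl:::rule_dims() > 1]), 0)
  # ignoring the hint: uniform over all 63
  expect_equal(sht_hypothesis_prior(spec1, 1, 1), rep(1 / 63, 63))
  # known 2D with w_l = 0.5, w_h = 0.2: normalizer 9*0.5 + 27 + 27*0.2
  spec2 <- game_spec(2, TRUE, c(1L, 2L, 0L))
  p2 <- sht_hypothesis_prior(spec2, 0.5, 0.2)
  expect_equal(p2[mdprl:::rule_dims() == 2], rep(1 / 36.9, 27))
  expect_equal(p2[mdprl:::rule_dims() == 1], rep(0.5 / 36.9, 9))
  # unknown games average the three known priors
  specu <- game_spec(2, FALSE, c(1L, 2L, 0L))
  pu <- sht_hypothesis_prior(specu, 0.5, 0.2)
  manual <- (sht_hypothesis_prior(game_spec(1, TRUE, c(1L, 0L, 0L)), .5, .2) +
               sht_hypothesis_prior(spec2, .5, .2) +
               sht_hypothesis_prior(game_spec(3, TRUE, c(1L, 1L, 1L)),
                                    .5, .2)) / 3
  expect_equal(pu, manual)
  expect_equal(sum(pu), 1, tolerance = 1e-12)
})

test_that("the count-based reward estimate and stay rule behave as specified", {
  expect_equal(p_hat(0, 0), 0.5)
  expect_equal(p_hat(3, 4), 4 / 6)
  expect_equal(p_hat(0, 8), 0.1)
  prm <- sht_params(beta_stay = 7, theta = 0.5, lambda = 0.1)
  expect_equal(stay_probability(2, 4, prm), 0.5)  # p_hat = theta
  prm0 <- sht_params(beta_stay = 0, theta = 0.9, lambda = 0.1)
  expect_equal(stay_probability(9, 9, prm0), 0.5)
  prm_inf <- sht_params(beta_stay = 1e4, theta = 0.3, lambda = 0.1)
  expect_gt(stay_probability(5, 5, prm_inf), 1 - 1e-10)
  expect_lt(stay_probability(0, 10, prm_inf), 1e-10)
  # monotone in reward count at fixed trial count
  ps <- vapply(0:10, function(a) stay_probability(a, 10, prm), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("target reward probabilities follow the attainable rates per game type", {
  k3 <- game_spec(3, TRUE, c(1L, 1L, 1L))
  expect_equal(rp_target(c(1L, 0L, 0L), k3), 0.4)
  expect_equal(rp_target(c(1L, 2L, 0L), k3), 0.6)
  expect_equal(rp_target(c(1L, 2L, 3L), k3), 0.8)
  k1 <- game_spec(1, TRUE, c(1L, 0L, 0L))
  expect_equal(rp_target(c(2L, 0L, 0L), k1), 0.8)
  expect_equal(rp_target(c(1L, 2L, 3L), k1), 0.8)  # D(h) >= D
  u <- game_spec(2, FALSE, c(1L, 2L, 0L))
  expect_equal(rp_target(c(1L, 0L, 0L), u), 0.6)
  expect_equal(rp_target(c(1L, 2L, 0L), u), 0.733)
  expect_equal(rp_target(c(1L, 2L, 3L), u), 0.8)
})

test_that("switch distributions renormalize the weighted prior without the previous rule", {
  spec <- game_spec(1, TRUE, c(1L, 0L, 0L))
  prior <- sht_hypothesis_prior(spec, 1, 1)
  v0 <- rl_init_values()
  # uniform prior: each of the other 62 rules at 1/62
  prm <- sht_params(w_l = 1, w_h = 1, switch_policy = "random",
                    lambda = 0.1)
  q <- sht_switch_distribution(5L, prior, v0, prm)
  expect_equal(q[5L], 0)
  expect_equal(q[-5L], rep(1 / 62, 62))
  # value policy with zero values or zero temperature reduces to the same
  prmv <- sht_params(w_l = 1, w_h = 1, switch_policy = "value", eta = 0.4,
                     decay = 0.5, beta_switch = 8, lambda = 0.1)
  expect_equal(sht_switch_distribution(5L, prior, v0, prmv), q)
  v <- matrix(rnorm(9), 3, 3)
  prmv0 <- sht_params(w_l = 1, w_h = 1, switch_policy = "value", eta = 0.4,
                      decay = 0.5, beta_switch = 0, lambda = 0.1)
  expect_equal(sht_switch_distribution(5L, prior, v, prmv0), q)
  # value weighting favors high-value hypotheses
  v2 <- matrix(0, 3, 3); v2[1, 1] <- 1
  q2 <- sht_switch_distribution(5L, prior, v2, prmv)
  h_good <- which(enumerate_rules()[, 1] == 1L & mdprl:::rule_dims() == 1L)
  expect_gt(q2[h_good], max(q2[setdiff(which(mdprl:::rule_dims() == 1L), h_good)]))
})

test_that("the test gate is logistic in the best available hypothesis value", {
  prior <- rep(1 / 63, 63)
  prm <- sht_params(test_gate = TRUE, beta_test = 6, theta_test = 0.4,
                    lambda = 0.1)
  v <- matrix(0, 3, 3); v[2, 3] <- 0.4
  expect_equal(sht_test_probability(v, prm, prior), 0.5)
  prm0 <- sht_params(test_gate = TRUE, beta_test = 0, theta_test = 0.9,
                     lambda = 0.1)
  expect_equal(sht_test_probability(rl_init_values(), prm0, prior), 0.5)
  prm_hi <- sht_params(test_gate = TRUE, beta_test = 1e4, theta_test = 0.5,
                       lambda = 0.1)
  expect_lt(sht_test_probability(rl_init_values(), prm_hi, prior), 1e-10)
})

test_that("choice policies place lapse and superset mass correctly", {
  prm <- sht_params(lambda = 0, w_l = 1, w_h = 1)
  m <- sht_choice_matrix(prm)
  rci <- mdprl:::rule_config_index()
  expect_equal(m[cbind(1:63, rci)], rep(1, 63))
  prm2 <- sht_params(lambda = 0.2, w_l = 1, w_h = 1)
  m2 <- sht_choice_matrix(prm2)
  expect_equal(rowSums(m2), rep(1, 63), tolerance = 1e-12)
  expect_equal(max(m2[1, ]), 0.8 + 0.2 / 64)
  # superset policy: 1D hypothesis, k = 0, lambda = 0 -> 1/16 on each of its
  # 16 supersets
  prm3 <- sht_params(lambda = 0, superset_choice = TRUE, k = 0,
                     w_l = 1, w_h = 1)
  m3 <- sht_choice_matrix(prm3)
  h1 <- which(mdprl:::rule_dims() == 1L)[1L]
  expect_equal(sort(unique(round(m3[h1, ], 12))), c(0, 1 / 16))
  expect_equal(sum(m3[h1, ] > 0), 16L)
  expect_equal(rowSums(sht_choice_matrix(
    sht_params(lambda = 0.3, superset_choice = TRUE, k = 1.2,
               w_l = 1, w_h = 1))), rep(1, 63), tolerance = 1e-12)
})

test_that("simulation limits: never switching, switching every trial, determinism", {
  spec <- game_spec(1, TRUE, c(2L, 0L, 0L), n_trials = 20L)
  # beta_stay large, theta = 0: stay forever; lambda = 0: constant choice
  prm_stay <- sht_params(w_l = 0.1, w_h = 0.1, beta_stay = 1e4, theta = 0,
                         lambda = 0, switch_policy = "random")
  set.seed(31)
  g <- sht_simulate_game(spec, prm_stay)
  expect_equal(length(unique(attr(g, "hypothesis"))), 1L)
  expect_equal(length(unique(g$choice_idx)), 1L)
  expect_false(any(identify_switch_trials(g)))
  # theta = 1, beta_stay large: switch every trial
  prm_switch <- sht_params(w_l = 1, w_h = 1, beta_stay = 1e4, theta = 1,
                           lambda = 0, switch_policy = "random")
  set.seed(32)
  g2 <- sht_simulate_game(spec, prm_switch)
  expect_true(all(diff(attr(g2, "hypothesis")) != 0))
  # fixed seed reproduces the trajectory
  set.seed(33)
  a <- sht_simulate_game(spec, sht_params(w_l = .2, w_h = .2, beta_stay = 8,
                                          theta = .5, lambda = .1,
                                          switch_policy = "value",
                                          eta = .4, decay = .6,
                                          beta_switch = 5))
  set.seed(33)
  b <- sht_simulate_game(spec, sht_params(w_l = .2, w_h = .2, beta_stay = 8,
                                          theta = .5, lambda = .1,
                                          switch_policy = "value",
                                          eta = .4, decay = .6,
                                          beta_switch = 5))
  expect_identical(a$choices, b$choices)
  expect_identical(attr(a, "hypothesis"), attr(b, "hypothesis"))
})

test_that("forward filter: closed forms, mass conservation and lapse limit", {
  set.seed(35)
  prm <- sht_params(w_l = .3, w_h = .2, beta_stay = 6, theta = .5,
                    lambda = 1, switch_policy = "value", eta = .3,
                    decay = .7, beta_switch = 4)
  spec <- game_spec(2, FALSE, c(1L, 3L, 0L), n_trials = 12L)
  g <- sht_simulate_game(spec, prm)
  out <- sht_game_loglik(g, prm)
  # lambda = 1: uniform predictive, T log(1/64)
  expect_equal(out$total, 12 * log(1 / 64), tolerance = 1e-10)
  expect_equal(as.numeric(out$predictive), rep(1 / 64, 12 * 64),
               tolerance = 1e-10)

  # mass conservation of the latent state at every trial
  prm2 <- sht_params(w_l = .3, w_h = .2, beta_stay = 6, theta = .5,
                     lambda = .15, switch_policy = "value", eta = .3,
                     decay = .7, beta_switch = 4)
  set.seed(36)
  g2 <- sht_simulate_game(spec, prm2)
  out2 <- sht_game_loglik(g2, prm2)
  expect_lt(max(abs(rowSums(out2$hyp_marginals) +
                      out2$not_testing_mass - 1)), 1e-10)
  expect_equal(rowSums(out2$predictive), rep(1, 12), tolerance = 1e-10)

  # single-trial game: log sum_h P(h) P(c1 | h)
  spec1 <- game_spec(1, TRUE, c(2L, 0L, 0L), n_trials = 1L)
  g1 <- new_game(spec1, rbind(c(2L, 0L, 0L)), rbind(c(2L, 1L, 3L)), 1L)
  prior <- sht_hypothesis_prior(spec1, prm2$w_l, prm2$w_h)
  cgh <- sht_choice_matrix(prm2)
  expect_equal(sht_game_loglik(g1, prm2)$total,
               log(sum(prior * cgh[, g1$choice_idx])), tolerance = 1e-12)

  # lambda = 0 with a choice matching no hypothesis is impossible
  prm0 <- sht_params(w_l = 1, w_h = 1, beta_stay = 6, theta = .5,
                     lambda = 0, switch_policy = "random")
  g0 <- new_game(spec1, rbind(c(0L, 0L, 0L)), rbind(c(2L, 1L, 3L)), 1L)
  expect_equal(sht_game_loglik(g0, prm0)$total, -Inf)
})
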