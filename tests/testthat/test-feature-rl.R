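test_that("expected reward sums feature values with dimension means for unselected dimensions", {
  v <- rl_init_values()
  expect_equal(rl_expected_reward(v, c(1, 2, 3)), 0)
  v2 <- rbind(c(.5, 0, 0), c(0, .3, 0), c(.1, .2, .3))
  expect_equal(rl_expected_reward(v2, c(1, 2, 0)), 1.0)  # 0.5 + 0.3 + 0.2
  expect_equal(rl_expected_reward(v2, c(0, 0, 0)), sum(v2) / 3)
})

test_that("softmax choice probabilities normalize and respect symmetry", {
  v <- matrix(rnorm(9, sd = 0.3), 3, 3)
  p0 <- rl_choice_probabilities(v, 0)
  expect_equal(p0, rep(1 / 64, 64))
  p <- rl_choice_probabilities(v, 7)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # equal expected reward implies equal probability
  v_eq <- matrix(0.2, 3, 3)
  expect_equal(diff(range(rl_choice_probabilities(v_eq, 5))), 0)
  # extreme values do not overflow
  expect_true(all(is.finite(rl_choice_probabilities(matrix(50, 3, 3), 100))))
})

test_that("the value update applies learning rates by selection and decays absent features", {
  p <- rl_params(1, 0.5, 0.25, 0.5)
  v <- rl_init_values()
  v1 <- rl_update(v, c(1, 2, 3), c(1, 2, 3), 1, p)
  expect_equal(v1[cbind(1:3, c(1, 2, 3))], rep(0.5, 3))  # PE = 1 - 0
  expect_equal(sum(v1), 1.5)  # everything else stays 0 (decay of 0)
  # computer-filled dimension uses eta_r
  v2 <- rl_update(v, c(1, 0, 0), c(1, 2, 3), 1, p)
  expect_equal(v2[1, 1], 0.5)
  expect_equal(v2[2, 2], 0.25)
  expect_equal(v2[3, 3], 0.25)
  # decay halves a value not in the stimulus
  v3 <- matrix(0, 3, 3); v3[1, 2] <- 0.4
  v4 <- rl_update(v3, c(1, 0, 0), c(1, 1, 1), 0, p)
  expect_equal(v4[1, 2], 0.2)
  # zero prediction error and no decay leave values unchanged
  v5 <- matrix(0.1, 3, 3)
  pd1 <- rl_params(1, 0.5, 0.25, 1)
  expect_equal(rl_update(v5, c(1, 2, 3), c(1, 2, 3), 0.3, pd1), v5)
  expect_error(rl_update(v, c(1, 0, 0), c(2, 1, 1), 1, p), "inconsistent")
})

test_that("session likelihood matches the independent step-by-step trace and basic identities", {
  g <- fixture_rl_game()
  s <- fixture_session(g)
  ll <- rl_session_loglik(s, rl_params(2, 0.5, 0.25, 0.8))$total
  expect_equal(ll, oracle_rl_game_ll(g, 2, 0.5, 0.25, 0.8),
               tolerance = 1e-12)
  expect_equal(ll, -12.1889374364, tolerance = 1e-9)  # frozen oracle value
  # beta = 0: uniform choice
  expect_equal(rl_session_loglik(s, rl_params(0, .3, .3, .9))$total,
               3 * log(1 / 64))
  expect_lt(ll, 0)
  # further randomized params against the oracle
  set.seed(3)
  for (i in 1:5) {
    b <- runif(1, 0, 6); es <- runif(1); er <- runif(1); d <- runif(1)
    expect_equal(rl_session_loglik(s, rl_params(b, es, er, d))$total,
                 oracle_rl_game_ll(g, b, es, er, d), tolerance = 1e-10)
  }
})

test_that("frozen learning rates and unit decay pin behavior at initialization", {
  set.seed(5)
  p <- rl_params(3, 0, 0, 1)
  spec <- game_spec(1, TRUE, c(1L, 0L, 0L), n_trials = 15L)
  gm <- rl_simulate_game(spec, p)
  s <- new_session("x", list(gm))
  expect_equal(rl_session_loglik(s, p)$total, 15 * log(1 / 64))
})

test_that("simulation is reproducible and hits chance / ceiling reward rates in the limits", {
  set.seed(9)
  spec <- game_spec(2, TRUE, c(1L, 2L, 0L), n_trials = 30L)
  g1 <- rl_simulate_game(spec, rl_params(5, .4, .2, .7))
  set.seed(9)
  g2 <- rl_simulate_game(spec, rl_params(5, .4, .2, .7))
  expect_identical(g1$choices, g2$choices)
  expect_identical(g1$rewards, g2$rewards)

  # beta = 0 agent earns at the 0.4 chance rate (3 s.e. band)
  set.seed(10)
  n <- 3000L
  rw <- unlist(lapply(1:(n / 30), function(i) {
    rl_simulate_game(game_spec(3, FALSE, c(1L, 1L, 1L), 30L),
                     rl_params(0, 0, 0, 1))$rewards
  }))
  expect_lt(abs(mean(rw) - 0.4), 3 * sqrt(0.4 * 0.6 / n))

  # greedy agent with values pre-seeded at the truth earns at 0.8
  v <- matrix(0, 3, 3); v[cbind(1:2, c(1, 2))] <- 1
  p_greedy <- rl_choice_probabilities(v, 100)
  best <- configurations()[which.max(p_greedy), ]
  expect_equal(best[1:2], c(color = 1L, shape = 2L))
  expect_equal(reward_probability(c(1, 2, 0), ifelse(best > 0, best, 1L)),
               0.8)
})
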