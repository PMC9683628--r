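test_that("maximum-likelihood fits are locally optimal, deterministic and recover a 1-parameter model", {
  set.seed(201)
  # 540 trials simulated from the Bayesian learner at beta = 3
  s <- simulate_session(generate_design(3, 30), "bayes", c(beta = 3),
                        id = "b3")
  fit <- fit_mle(s, "bayes", n_restarts = 4, seed = 7)
  expect_lt(abs(fit$par[["beta"]] - 3) / 3, 0.3)
  # best-of-restarts dominates every restart
  expect_true(all(fit$loglik >= fit$restarts$loglik - 1e-8))
  # refitting from the optimum does not improve beyond tolerance
  refit <- fit_mle(s, "bayes", n_restarts = 1, seed = 8, init = fit$par)
  expect_lt(refit$loglik - fit$loglik, 1e-4)
  # same seed, same result
  fit2 <- fit_mle(s, "bayes", n_restarts = 4, seed = 7)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("leave-one-game-out folds are exhaustive and disjoint and chance scores 1/64", {
  set.seed(203)
  s <- sim_mini_session("rl", model_info("rl")$default_par,
                        n_per_type = 1L, n_trials = 8L, seed = 203)
  # a pure-lapse SHT agent is the uniform-random model: held-out likelihood
  # is exactly 1/64 per trial whatever the fitted parameters
  cv <- logo_cv(s, "sht_random", n_restarts = 1, seed = 1,
                warm_start = FALSE)
  expect_equal(length(cv$by_game), 6L)
  expect_equal(sum(cv$n_trials), 48L)
  expect_true(cv$geom_lik > 0 && cv$geom_lik <= 1)

  prm_uniform <- c(w_l = 1, w_h = 1, beta_stay = 5, theta = 0.5, lambda = 1)
  ll <- model_loglik("sht_random", s, prm_uniform)
  expect_equal(exp(ll$total / sum(ll$n_trials)), 1 / 64, tolerance = 1e-12)
})

test_that("contribution metrics difference the hybrid against its component models", {
  set.seed(205)
  s <- sim_mini_session("sht_value", model_info("sht_value")$default_par,
                        n_per_type = 1L, n_trials = 10L, seed = 205)
  # synthetic CV objects with known values exercise the arithmetic without
  # refitting
  mk_cv <- function(ll_per_trial) {
    nt <- vapply(s$games, function(g) length(g$rewards), integer(1))
    structure(list(model = "x", by_game = ll_per_trial * nt, n_trials = nt,
                   geom_lik = exp(ll_per_trial)), class = "mdprl_cv")
  }
  cv_h <- mk_cv(log(0.20)); cv_r <- mk_cv(log(0.12)); cv_s <- mk_cv(log(0.16))
  tab <- contribution_metrics(cv_h, cv_r, cv_s, s)
  expect_equal(nrow(tab), 7L)
  ov <- tab[tab$scope == "overall", ]
  expect_equal(ov$sht_contribution, 0.20 - 0.12, tolerance = 1e-12)
  expect_equal(ov$rl_contribution, 0.20 - 0.16, tolerance = 1e-12)
  # identical models give zero contribution
  tab0 <- contribution_metrics(cv_h, cv_h, cv_h, s)
  expect_equal(tab0$sht_contribution, rep(0, 7))
  # per-type log-likelihoods recombine to the overall value by trial count
  types <- tab[tab$scope != "overall", ]
  expect_equal(sum(types$loglik_hybrid * types$n_trials) / sum(types$n_trials),
               ov$loglik_hybrid, tolerance = 1e-12)
  # mismatched session is rejected
  s2 <- sim_mini_session("rl", model_info("rl")$default_par,
                         n_per_type = 1L, n_trials = 9L, seed = 1)
  expect_error(contribution_metrics(cv_h, cv_r, cv_s, s2), "match")
})

test_that("the comparison table aggregates cohort likelihoods with s.e.m.", {
  cv1 <- structure(list(geom_lik = 0.2), class = "mdprl_cv")
  cv2 <- structure(list(geom_lik = 0.1), class = "mdprl_cv")
  one <- model_comparison_table(list(list(a = cv1, b = cv2)))
  expect_equal(one$mean_lik_per_trial, c(0.2, 0.1))
  expect_true(all(is.na(one$sem)))
  expect_equal(one$chance, rep(1 / 64, 2))
  # duplicating a session leaves the mean unchanged
  two <- model_comparison_table(list(list(a = cv1, b = cv2),
                                     list(a = cv1, b = cv2)))
  expect_equal(two$mean_lik_per_trial, one$mean_lik_per_trial)
  expect_equal(two$sem, c(0, 0))
})

test_that("nesting: value-based SHT fits random-switch data at least as well as random-switch", {
  set.seed(207)
  s <- sim_mini_session("sht_random", model_info("sht_random")$default_par,
                        n_per_type = 1L, n_trials = 15L, seed = 207)
  f_r <- fit_mle(s, "sht_random", n_restarts = 2, seed = 11)
  f_v <- fit_mle(s, "sht_value", n_restarts = 2, seed = 11,
                 init = c(f_r$par, eta = 0, decay = 0.5, beta_switch = 1e-3))
  expect_gte(f_v$loglik, f_r$loglik - 1e-4)
})
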