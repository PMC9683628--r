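# Serial hypothesis testing (SHT): the agent tests one candidate rule at a
# time, estimates its reward probability from counts, stays or switches by a
# logistic rule on that estimate, and emits the hypothesis-consistent
# configuration with a lapse rate. The hypothesis trajectory is latent;
# likelihoods come from an exact forward filter over (hypothesis,
# reward-count, trial-count) states. The value-based (hybrid) variant weights
# the switch distribution by feature values learned in parallel by the RL
# rule with a single learning rate; the random-switch model is its exact
# special case at eta = 0, beta_switch = 0.

#' Parameters of the serial hypothesis-testing model family
#'
#' @param w_l,w_h Prior weights (>= 0) for hypotheses of lower/higher
#'   dimensionality than the instructed one (known games); hypotheses of the
#'   instructed dimensionality get weight 1. `w_l = w_h = 0` is strict
#'   instruction-following; `w_l = w_h = 1` ignores the hint.
#' @param beta_stay Slope of the logistic stay rule (>= 0).
#' @param theta Stay threshold on the estimated reward probability, in
#'   \[0, 1\]. Ignored when `rp_target = TRUE`.
#' @param lambda Lapse rate in \[0, 1\]: probability of a uniformly random
#'   configuration instead of the hypothesis-consistent choice.
#' @param switch_policy `"random"` (switch to another hypothesis according to
#'   the prior) or `"value"` (prior-weighted softmax in learned hypothesis
#'   value, slope `beta_switch`).
#' @param eta,decay Learning rate and decay of the parallel feature-value
#'   learner (value policy; a single rate for all stimulus features).
#' @param beta_switch Inverse temperature of the value-based switch softmax.
#' @param test_gate Enable the "not always testing" variant: at game start
#'   and at switch points the agent only starts testing with probability
#'   logistic(`beta_test` * (max hypothesis value - `theta_test`)), otherwise
#'   it selects nothing and lets the computer build the stimulus.
#' @param beta_test,theta_test Test-gate logistic parameters.
#' @param rp_target Enable the reward-probability-target variant: the stay
#'   threshold becomes the hypothesis's attainable reward probability in the
#'   current game type (see [rp_target()]) plus the offset `delta`.
#' @param delta Threshold offset for the `rp_target` variant, in
#'   \[-0.5, 0.5\].
#' @param superset_choice Enable the superset choice policy: non-lapse mass
#'   is spread over configurations that are supersets of the hypothesis with
#'   weights exp(`k` * (D(c) - D(h))); lapses cover the non-supersets.
#' @param k Superset dimensionality weight.
#' @return An `sht_params` list.
#' @export
sht_params <- function(w_l = 1, w_h = 1, beta_stay = 5, theta = 0.5,
                       lambda = 0.1,
                       switch_policy = c("random", "value"),
                       eta = 0, decay = 1, beta_switch = 0,
                       test_gate = FALSE, beta_test = 0, theta_test = 0,
                       rp_target = FALSE, delta = 0,
                       superset_choice = FALSE, k = 0) {
  switch_policy <- match.arg(switch_policy)
  stopifnot(w_l >= 0, w_h >= 0, beta_stay >= 0, theta >= 0, theta <= 1,
            lambda >= 0, lambda <= 1, eta >= 0, eta <= 1,
            decay >= 0, decay <= 1, beta_switch >= 0, beta_test >= 0,
            delta >= -0.5, delta <= 0.5)
  if (switch_policy == "random") {
    eta <- 0; beta_switch <- 0
  }
  structure(list(w_l = w_l, w_h = w_h, beta_stay = beta_stay, theta = theta,
                 lambda = lambda, switch_policy = switch_policy, eta = eta,
                 decay = decay, beta_switch = beta_switch,
                 test_gate = test_gate, beta_test = beta_test,
                 theta_test = theta_test, rp_target = rp_target,
                 delta = delta, superset_choice = superset_choice, k = k),
            class = "sht_params")
}

#' Hypothesis adoption prior over the 63 rules
#'
#' Known games: weight `w_l` for rules of lower dimensionality than the
#' instructed `D`, 1 for matching dimensionality, `w_h` for higher, then
#' normalized. Unknown games: the arithmetic mean of the three known-game
#' normalized priors.
#'
#' @param spec A [game_spec()] (only `complexity` and `known` are used).
#' @param w_l,w_h Prior weights (>= 0).
#' @return Probability vector of length 63 in canonical rule order.
#' @export
sht_hypothesis_prior <- function(spec, w_l, w_h) {
  dh <- rule_dims()
  known_prior <- function(D) {
    w <- ifelse(dh < D, w_l, ifelse(dh == D, 1, w_h))
    s <- sum(w)
    if (s <= 0) stop("hypothesis prior has zero total mass", call. = FALSE)
    w / s
  }
  if (spec$known) known_prior(spec$complexity)
  else (known_prior(1) + known_prior(2) + known_prior(3)) / 3
}

#' Count-based reward-probability estimate
#'
#' Posterior mean of a Bernoulli rate under a uniform prior:
#' `(rewards + 1) / (trials + 2)`.
#'
#' @param rewards,trials Non-negative counts with `rewards <= trials`,
#'   accumulated since the current hypothesis was adopted.
#' @return Estimated reward probability.
#' @export
p_hat <- function(rewards, trials) {
  stopifnot(all(rewards >= 0), all(trials >= rewards))
  (rewards + 1) / (trials + 2)
}

#' Target reward probability of a hypothesis in a game
#'
#' The reward probability the hypothesis would attain if all its features
#' were rewarding: 0.8 when the hypothesis dimensionality is at least the
#' instructed one, otherwise the task's interpolated value
#' `0.2 + 0.6 * D(h) / D`. Unknown games use the fixed targets 0.6, 0.733
#' and 0.8 for 1D, 2D and 3D hypotheses.
#'
#' @param hypothesis A rule (length-3 vector, 0 = unassigned).
#' @param spec A [game_spec()].
#' @return Target reward probability.
#' @export
rp_target <- function(hypothesis, spec) {
  dh <- rule_dimensionality(hypothesis)
  if (spec$known) {
    D <- spec$complexity
    if (dh >= D) 0.8 else 0.2 + 0.6 * dh / D
  } else {
    c(0.6, 0.733, 0.8)[dh]
  }
}

# stay threshold per canonical rule for one game
sht_theta_vec <- function(params, spec) {
  if (!params$rp_target) return(rep(params$theta, 63L))
  dh <- rule_dims()
  tgt <- if (spec$known) {
    D <- spec$complexity
    ifelse(dh >= D, 0.8, 0.2 + 0.6 * dh / D)
  } else {
    c(0.6, 0.733, 0.8)[dh]
  }
  tgt + params$delta
}

#' Probability of staying with the current hypothesis
#'
#' Logistic in the count-based reward estimate:
#' `plogis(beta_stay * (p_hat - theta))`, where `theta` is the fixed stay
#' threshold or, under the reward-probability-target variant, the
#' hypothesis's [rp_target()] plus the offset `delta`.
#'
#' @param rewards,trials Counts since the hypothesis was adopted.
#' @param params An [sht_params()] object.
#' @param hypothesis The tested rule (used only by the `rp_target` variant).
#' @param spec The game (used only by the `rp_target` variant).
#' @return Stay probability.
#' @export
stay_probability <- function(rewards, trials, params, hypothesis = NULL,
                             spec = NULL) {
  theta <- if (params$rp_target) {
    rp_target(hypothesis, spec) + params$delta
  } else {
    params$theta
  }
  plogis(params$beta_stay * (p_hat(rewards, trials) - theta))
}

# learned value of each rule: sum of its constituent feature values
# (no dimension-mean padding, unlike the configuration value in Eq-1 style)
sht_er_h <- function(values) {
  r <- enumerate_rules()
  er <- numeric(63L)
  for (i in 1:3) {
    a <- r[, i] > 0L
    er[a] <- er[a] + values[i, r[a, i]]
  }
  er
}

# unnormalized switch/adoption weights: prior-weighted softmax in hypothesis
# value (scale-safe; reduces to the prior when beta_switch = 0)
sht_switch_weights <- function(prior, values, params) {
  u <- params$beta_switch * sht_er_h(values)
  pos <- prior > 0
  if (!any(pos)) stop("hypothesis prior has zero total mass", call. = FALSE)
  # clamp as in the C++ precompute: keep all weights strictly positive so
  # extreme temperatures cannot empty the switch candidate set numerically
  prior * exp(pmax(u - max(u[pos]), -500))
}

#' Conditional-on-switch distribution over the other hypotheses
#'
#' Under the random policy the adoption prior is renormalized with the
#' previous hypothesis excluded; under the value policy the prior is first
#' reweighted by exp(beta_switch * value of the hypothesis).
#'
#' @param prev Index of the previous rule in the canonical 63-rule order.
#' @param prior Adoption prior from [sht_hypothesis_prior()].
#' @param values 3 x 3 feature-value matrix (value policy).
#' @param params An [sht_params()] object.
#' @return Probability vector of length 63 with a zero at `prev`.
#' @export
sht_switch_distribution <- function(prev, prior, values, params) {
  w <- sht_switch_weights(prior, values, params)
  w[prev] <- 0
  s <- sum(w)
  if (s <= 0) stop("empty switch candidate set", call. = FALSE)
  w / s
}

#' Probability of testing a hypothesis (test-gate variant)
#'
#' Logistic in the best available hypothesis value:
#' `plogis(beta_test * (max_h value(h) - theta_test))`, the maximum taken
#' over hypotheses with non-zero prior mass.
#'
#' @param values 3 x 3 feature-value matrix.
#' @param params An [sht_params()] object with `test_gate = TRUE`.
#' @param prior Adoption prior defining the hypothesis space.
#' @return Probability of entering the testing state.
#' @export
sht_test_probability <- function(values, params, prior) {
  er <- sht_er_h(values)
  plogis(params$beta_test * (max(er[prior > 0]) - params$theta_test))
}

# cached 63 x 64 logical superset relation: config c is a superset of rule h
superset_matrix <- function() {
  .cache_get("superset", function() {
    r <- enumerate_rules()
    g <- configurations()
    m <- matrix(TRUE, 63L, 64L)
    for (i in 1:3) {
      a <- r[, i] > 0L
      m[a, ] <- m[a, ] & outer(r[a, i], g[, i], "==")
    }
    m
  })
}

#' Choice distribution given the tested hypothesis
#'
#' Baseline policy: the configuration that selects exactly the hypothesis's
#' features gets mass `1 - lambda`, and a lapse spreads `lambda` uniformly
#' over all 64 configurations. Superset variant: the non-lapse mass is
#' spread over superset configurations with weights
#' exp(`k` * (D(c) - D(h))), and `lambda` is spread uniformly over the
#' non-superset configurations.
#'
#' @param params An [sht_params()] object.
#' @return A 63 x 64 matrix; row h is the choice distribution when testing
#'   canonical rule h.
#' @export
sht_choice_matrix <- function(params) {
  lam <- params$lambda
  if (!params$superset_choice) {
    m <- matrix(lam / 64, 63L, 64L)
    m[cbind(seq_len(63L), rule_config_index())] <-
      lam / 64 + (1 - lam)
    return(m)
  }
  sup <- superset_matrix()
  dc <- rowSums(configurations() > 0L)
  dh <- rule_dims()
  m <- matrix(0, 63L, 64L)
  for (h in seq_len(63L)) {
    w <- exp(params$k * (dc[sup[h, ]] - dh[h]))
    m[h, sup[h, ]] <- (1 - lam) * w / sum(w)
    n_out <- sum(!sup[h, ])
    m[h, !sup[h, ]] <- lam / n_out
  }
  m
}

# emission distribution of the not-testing state: empty configuration with
# probability (1 - lambda) + lambda/64, lapse otherwise
sht_not_testing_emission <- function(params) {
  e <- rep(params$lambda / 64, 64L)
  e[1L] <- e[1L] + (1 - params$lambda)
  e
}

# Deterministic feature-value trajectory from the observed trials (single
# learning rate; the trajectory never depends on the latent hypothesis).
# Returns, per trial t, the switch weights and test probability computed from
# the values held *before* trial t (column/element 1 uses the zero initial
# values), as consumed by the forward filter.
sht_precompute_values <- function(game, params, prior) {
  sht_precompute_cpp(enumerate_rules(), game$choices, game$stimuli,
                     game$rewards, params$eta, params$decay,
                     params$beta_switch, prior, params$test_gate,
                     params$beta_test, params$theta_test)
}

#' Forward-filter log-likelihood of one game under an SHT model
#'
#' Exact marginal likelihood of the observed choice sequence, filtering over
#' the latent (hypothesis, reward-count, trial-count) state: initialize from
#' the adoption prior, score each observed choice through the choice policy,
#' condition, advance the counters with the observed reward, and apply the
#' stay/switch kernel between trials. With `lambda = 0` a choice matching no
#' hypothesis has probability zero and the log-likelihood is `-Inf`.
#'
#' @param game A played `game` (see [new_game()]).
#' @param params An [sht_params()] object.
#' @param predictive If `TRUE` (default), also return the per-trial
#'   predictive distributions (skipped inside fitting loops for speed).
#' @return List with `total` log-likelihood, `by_trial`, the per-trial
#'   predictive distribution over the 64 configurations (`predictive`), and
#'   the per-trial predictive hypothesis marginals (`hyp_marginals`, columns
#'   in canonical rule order; under the test gate the not-testing mass is in
#'   `not_testing_mass`).
#' @export
sht_game_loglik <- function(game, params, predictive = TRUE) {
  spec <- game$spec
  prior <- sht_hypothesis_prior(spec, params$w_l, params$w_h)
  theta <- sht_theta_vec(params, spec)
  cgh <- sht_choice_matrix(params)
  pre <- sht_precompute_values(game, params, prior)
  w <- cgh[, game$choice_idx, drop = FALSE]
  emisN <- sht_not_testing_emission(params)
  wN <- emisN[game$choice_idx]
  out <- sht_filter_cpp(prior, w, wN, game$rewards, params$beta_stay, theta,
                        pre$sw, pre$p_test, params$test_gate)
  res <- list(total = out$total, by_trial = as.numeric(out$by_trial),
              hyp_marginals = out$hyp_marginals,
              not_testing_mass = as.numeric(out$not_testing_mass))
  if (predictive) {
    pred <- out$hyp_marginals %*% cgh
    if (params$test_gate) {
      pred <- pred + outer(as.numeric(out$not_testing_mass), emisN)
    }
    res$predictive <- pred
  }
  res
}

#' Session log-likelihood under an SHT model
#'
#' @param session A [new_session()] object.
#' @param params An [sht_params()] object.
#' @param games Indices of games to include (default all).
#' @return List with `total`, `by_game`, `n_trials` as in
#'   [rl_session_loglik()].
#' @export
sht_session_loglik <- function(session, params, games = NULL) {
  if (is.null(games)) games <- seq_along(session$games)
  by_game <- vapply(session$games[games],
                    function(g) sht_game_loglik(g, params,
                                                predictive = FALSE)$total,
                    numeric(1))
  n_trials <- vapply(session$games[games],
                     function(g) length(g$rewards), integer(1))
  list(total = sum(by_game), by_game = by_game, n_trials = n_trials)
}

#' Simulate one game with an SHT agent
#'
#' Generative counterpart of the forward filter: the first hypothesis is
#' drawn from the adoption prior (gated by the test rule if enabled); on each
#' trial the agent emits a choice through the choice policy, the stimulus is
#' realized, reward is drawn from the true rule, the counters advance, the
#' feature values update, and between trials the stay/switch rule is applied
#' with counters reset on switch.
#'
#' @param spec A [game_spec()].
#' @param params An [sht_params()] object.
#' @return A played `game` with attributes `hypothesis` (canonical rule index
#'   per trial, `NA` while not testing) and `testing` (logical per trial).
#'   Uses R's global RNG.
#' @export
sht_simulate_game <- function(spec, params) {
  g <- configurations()
  T_ <- spec$n_trials
  prior <- sht_hypothesis_prior(spec, params$w_l, params$w_h)
  cgh <- sht_choice_matrix(params)
  emisN <- sht_not_testing_emission(params)
  upd <- rl_params(0, params$eta, params$eta, params$decay)

  choices <- matrix(0L, T_, 3)
  stims <- matrix(0L, T_, 3)
  rewards <- integer(T_)
  hyp <- rep(NA_integer_, T_)
  testing <- logical(T_)
  v <- rl_init_values()
  a <- 0L; n <- 0L

  draw_entry <- function(values) {
    w <- sht_switch_weights(prior, values, params)
    sample.int(63L, 1L, prob = w / sum(w))
  }
  is_testing <- if (params$test_gate) {
    runif(1) < sht_test_probability(v, params, prior)
  } else TRUE
  h <- if (is_testing) draw_entry(v) else NA_integer_

  for (t in seq_len(T_)) {
    hyp[t] <- h
    testing[t] <- is_testing
    p <- if (is_testing) cgh[h, ] else emisN
    ci <- sample.int(64L, 1L, prob = p)
    choices[t, ] <- g[ci, ]
    stims[t, ] <- realize_stimulus(choices[t, ])
    rewards[t] <- rbinom(1L, 1L, reward_probability(spec$true_rule,
                                                    stims[t, ]))
    if (is_testing) { n <- n + 1L; a <- a + rewards[t] }
    v <- rl_update(v, choices[t, ], stims[t, ], rewards[t], upd)
    if (t == T_) break
    if (is_testing) {
      theta_h <- if (params$rp_target) {
        rp_target(enumerate_rules()[h, ], spec) + params$delta
      } else params$theta
      p_stay <- plogis(params$beta_stay * (p_hat(a, n) - theta_h))
      if (runif(1) >= p_stay) {  # switch point
        start_new <- if (params$test_gate) {
          runif(1) < sht_test_probability(v, params, prior)
        } else TRUE
        if (start_new) {
          h <- {
            q <- sht_switch_distribution(h, prior, v, params)
            sample.int(63L, 1L, prob = q)
          }
          a <- 0L; n <- 0L
        } else {
          is_testing <- FALSE; h <- NA_integer_; a <- 0L; n <- 0L
        }
      }
    } else {
      if (runif(1) < sht_test_probability(v, params, prior)) {
        is_testing <- TRUE
        h <- draw_entry(v)
        a <- 0L; n <- 0L
      }
    }
  }
  gm <- new_game(spec, choices, stims, rewards)
  attr(gm, "hypothesis") <- hyp
  attr(gm, "testing") <- testing
  gm
}
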