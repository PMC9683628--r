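# Independent oracles, written from the model equations with their own local
# enumerations and naive arithmetic. They share no code path with the package
# likelihoods they check.

# all 64 configurations / 63 rules in a local (package-independent) order
.oracle_cfgs <- function() as.matrix(expand.grid(d1 = 0:3, d2 = 0:3,
                                                 d3 = 0:3))
.oracle_stims <- function() as.matrix(expand.grid(d1 = 1:3, d2 = 1:3,
                                                  d3 = 1:3))

.oracle_rp <- function(rule, stim) {
  D <- sum(rule > 0)
  m <- sum(rule > 0 & rule == stim)
  0.2 + 0.6 * m / D
}

# mean reward probability over the uniform computer fill of a choice
.oracle_er_rule_choice <- function(rule, choice) {
  stims <- .oracle_stims()
  ok <- apply(stims, 1, function(s) all(choice == 0 | s == choice))
  mean(apply(stims[ok, , drop = FALSE], 1, .oracle_rp, rule = rule))
}

# step-by-step feature RL likelihood (value learning + softmax choice)
oracle_rl_game_ll <- function(game, beta, eta_s, eta_r, d) {
  cfgs <- .oracle_cfgs()
  er_of <- function(cfg, V) {
    sum(vapply(1:3, function(i) {
      if (cfg[i] > 0) V[i, cfg[i]] else mean(V[i, ])
    }, numeric(1)))
  }
  V <- matrix(0, 3, 3)
  ll <- 0
  for (t in seq_along(game$rewards)) {
    ers <- apply(cfgs, 1, er_of, V = V)
    probs <- exp(beta * ers) / sum(exp(beta * ers))
    pick <- which(cfgs[, 1] == game$choices[t, 1] &
                    cfgs[, 2] == game$choices[t, 2] &
                    cfgs[, 3] == game$choices[t, 3])
    ll <- ll + log(probs[pick])
    pe <- game$rewards[t] - er_of(game$choices[t, ], V)
    Vnew <- d * V
    for (i in 1:3) {
      j <- game$stimuli[t, i]
      eta <- if (game$choices[t, i] > 0) eta_s else eta_r
      Vnew[i, j] <- V[i, j] + eta * pe
    }
    V <- Vnew
  }
  ll
}

# step-by-step Bayesian rule-learning likelihood; expected reward of a
# choice under a rule computed by brute-force enumeration of the fill
oracle_bayes_game_ll <- function(game, beta) {
  cfgs <- .oracle_cfgs()
  rules <- cfgs[rowSums(cfgs > 0) > 0, , drop = FALSE]
  Dh <- rowSums(rules > 0)
  hint_ok <- if (game$spec$known) Dh == game$spec$complexity else
    rep(TRUE, nrow(rules))
  rules <- rules[hint_ok, , drop = FALSE]
  ermat <- t(apply(rules, 1, function(r) {
    apply(cfgs, 1, .oracle_er_rule_choice, rule = r)
  }))
  b <- rep(1 / nrow(rules), nrow(rules))
  ll <- 0
  for (t in seq_along(game$rewards)) {
    ers <- as.numeric(b %*% ermat)
    probs <- exp(beta * ers) / sum(exp(beta * ers))
    pick <- which(cfgs[, 1] == game$choices[t, 1] &
                    cfgs[, 2] == game$choices[t, 2] &
                    cfgs[, 3] == game$choices[t, 3])
    ll <- ll + log(probs[pick])
    lik <- apply(rules, 1, .oracle_rp, stim = game$stimuli[t, ])
    if (game$rewards[t] == 0) lik <- 1 - lik
    b <- b * lik
    b <- b / sum(b)
  }
  ll
}

# exact SHT likelihood by brute-force enumeration over all latent hypothesis
# paths (feasible for short games and small hypothesis spaces); supports the
# test-gate, reward-probability-target and superset-choice variants
oracle_sht_game_ll <- function(game, params) {
  cfgs <- .oracle_cfgs()
  rules <- cfgs[rowSums(cfgs > 0) > 0, , drop = FALSE]
  Dh <- rowSums(rules > 0)
  nT <- length(game$rewards)
  spec <- game$spec

  kp <- function(Dg) {
    w <- ifelse(Dh < Dg, params$w_l, ifelse(Dh == Dg, 1, params$w_h))
    w / sum(w)
  }
  prior <- if (spec$known) kp(spec$complexity) else (kp(1) + kp(2) + kp(3)) / 3
  sup <- which(prior > 0)

  theta_h <- if (params$rp_target) {
    tgt <- if (spec$known) {
      ifelse(Dh >= spec$complexity, 0.8, 0.2 + 0.6 * Dh / spec$complexity)
    } else c(0.6, 0.733, 0.8)[Dh]
    tgt + params$delta
  } else rep(params$theta, nrow(rules))

  # emission of the observed choice under each rule, and when not testing
  lam <- params$lambda
  em <- matrix(0, nrow(rules), nT)
  emN <- numeric(nT)
  for (t in seq_len(nT)) {
    ch <- game$choices[t, ]
    for (h in seq_len(nrow(rules))) {
      if (params$superset_choice) {
        is_sup <- apply(cfgs, 1, function(c) all(rules[h, ] == 0 |
                                                   c == rules[h, ]))
        wts <- exp(params$k * (rowSums(cfgs > 0) - Dh[h]))
        pick <- which(cfgs[, 1] == ch[1] & cfgs[, 2] == ch[2] &
                        cfgs[, 3] == ch[3])
        em[h, t] <- if (is_sup[pick]) {
          (1 - lam) * wts[pick] / sum(wts[is_sup])
        } else lam / sum(!is_sup)
      } else {
        em[h, t] <- lam / 64 + (1 - lam) * all(ch == rules[h, ])
      }
    }
    emN[t] <- lam / 64 + (1 - lam) * all(ch == 0)
  }

  # deterministic value trajectory -> switch weights / test probabilities
  # before each trial (element 1 from the zero initial values)
  swcols <- matrix(0, nrow(rules), nT)
  ptv <- numeric(nT)
  V <- matrix(0, 3, 3)
  for (t in seq_len(nT)) {
    er_h <- apply(rules, 1, function(r) {
      sum(vapply(1:3, function(i) if (r[i] > 0) V[i, r[i]] else 0,
                 numeric(1)))
    })
    swcols[, t] <- prior * exp(params$beta_switch * er_h)
    ptv[t] <- plogis(params$beta_test * (max(er_h[sup]) - params$theta_test))
    er_c <- sum(vapply(1:3, function(i) {
      if (game$choices[t, i] > 0) V[i, game$choices[t, i]] else mean(V[i, ])
    }, numeric(1)))
    pe <- game$rewards[t] - er_c
    Vnew <- params$decay * V
    for (i in 1:3) {
      j <- game$stimuli[t, i]
      Vnew[i, j] <- V[i, j] + params$eta * pe
    }
    V <- Vnew
  }

  # recursive sum over hypothesis paths; state 0 = not testing
  rec <- function(t, s, a, n) {
    e <- if (s == 0) emN[t] else em[s, t]
    if (t == nT) return(e)
    if (s != 0) { n2 <- n + 1; a2 <- a + game$rewards[t] }
    acc <- 0
    if (s == 0) {
      pt <- ptv[t + 1]
      acc <- acc + (1 - pt) * rec(t + 1, 0, 0, 0)
      en <- swcols[, t + 1] / sum(swcols[, t + 1])
      for (h in sup) {
        if (en[h] > 0) acc <- acc + pt * en[h] * rec(t + 1, h, 0, 0)
      }
    } else {
      ps <- plogis(params$beta_stay * ((a2 + 1) / (n2 + 2) - theta_h[s]))
      acc <- acc + ps * rec(t + 1, s, a2, n2)
      swv <- swcols[, t + 1]
      swv[s] <- 0
      K <- swv / sum(swv)
      pt <- if (params$test_gate) ptv[t + 1] else 1
      if (params$test_gate) {
        acc <- acc + (1 - ps) * (1 - pt) * rec(t + 1, 0, 0, 0)
      }
      for (h in sup) {
        if (h != s && K[h] > 0) {
          acc <- acc + (1 - ps) * pt * K[h] * rec(t + 1, h, 0, 0)
        }
      }
    }
    e * acc
  }
  total <- if (params$test_gate) {
    (1 - ptv[1]) * rec(1, 0, 0, 0) +
      ptv[1] * sum(vapply(sup, function(h) prior[h] * rec(1, h, 0, 0),
                          numeric(1)))
  } else {
    sum(vapply(sup, function(h) prior[h] * rec(1, h, 0, 0), numeric(1)))
  }
  log(total)
}
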