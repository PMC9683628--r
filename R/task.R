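#' @useDynLib mdprl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rbinom runif sd plogis setNames cor
#' @importFrom utils read.csv write.csv
NULL

# Combinatorial structure of the task: stimuli have 3 dimensions (color,
# shape, texture) with 3 features each. A configuration assigns a feature
# (1..3) or nothing (0) to each dimension; a rule/hypothesis is a non-empty
# configuration. Canonical orders are fixed so probability vectors are
# comparable across runs and serializable.

.mdprl_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, builder) {
  if (!exists(key, envir = .mdprl_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .mdprl_cache)
  }
  get(key, envir = .mdprl_cache, inherits = FALSE)
}

#' Names of the three stimulus dimensions
#'
#' Cosmetic metadata only; all computations use dimension indices 1..3.
#' @return Character vector of length 3.
#' @export
task_dimensions <- function() c("color", "shape", "texture")

#' Enumerate all 64 configurations
#'
#' A configuration is a partial feature selection: for each of the three
#' dimensions, either a feature index 1..3 or 0 (no selection). The canonical
#' order is lexicographic in (dim 1, dim 2, dim 3) with 0 sorting first, so
#' row 1 is the empty configuration.
#'
#' @return A 64 x 3 integer matrix; entry 0 means "unselected".
#' @export
configurations <- function() {
  .cache_get("configs", function() {
    g <- as.matrix(expand.grid(d3 = 0:3, d2 = 0:3, d1 = 0:3))[, 3:1]
    dimnames(g) <- list(NULL, task_dimensions())
    storage.mode(g) <- "integer"
    g
  })
}

#' Enumerate all 27 complete stimuli
#'
#' @return A 27 x 3 integer matrix with entries in 1..3, lexicographic order.
#' @export
stimuli <- function() {
  .cache_get("stimuli", function() {
    g <- configurations()
    g[rowSums(g > 0L) == 3L, , drop = FALSE]
  })
}

#' Canonical index of a configuration
#'
#' @param config Integer vector of length 3 (entries 0..3) or a matrix with
#'   one configuration per row.
#' @return Integer index into the rows of [configurations()].
#' @export
config_index <- function(config) {
  m <- rbind(config)
  as.integer(16L * m[, 1] + 4L * m[, 2] + m[, 3] + 1L)
}

#' Canonical index of a complete stimulus
#'
#' @param stimulus Integer vector of length 3 (entries 1..3) or a matrix.
#' @return Integer index into the rows of [stimuli()].
#' @export
stimulus_index <- function(stimulus) {
  m <- rbind(stimulus)
  as.integer(9L * (m[, 1] - 1L) + 3L * (m[, 2] - 1L) + m[, 3])
}

#' Enumerate rules (candidate reward hypotheses)
#'
#' A rule assigns one rewarding feature to each of 1-3 dimensions. There are
#' 9 one-dimensional, 27 two-dimensional and 27 three-dimensional rules, 63
#' in total. Canonical order is by dimensionality, then lexicographic.
#'
#' @param hint One of `1`, `2`, `3` (only rules of that dimensionality, as in
#'   "known" games) or `"unknown"` (all 63 rules).
#' @return An integer matrix with one rule per row; entry 0 means the
#'   dimension is irrelevant under that rule.
#' @export
enumerate_rules <- function(hint = "unknown") {
  all_rules <- .cache_get("rules", function() {
    g <- configurations()
    d <- rowSums(g > 0L)
    r <- g[d > 0L, , drop = FALSE]
    r[order(rowSums(r > 0L)), , drop = FALSE]
  })
  if (identical(hint, "unknown")) return(all_rules)
  if (!(is.numeric(hint) && length(hint) == 1L && hint %in% 1:3)) {
    stop("`hint` must be 1, 2, 3 or \"unknown\"", call. = FALSE)
  }
  all_rules[rowSums(all_rules > 0L) == hint, , drop = FALSE]
}

#' Dimensionality D(h) of rules
#'
#' @param rule Integer vector of length 3 or matrix of rules.
#' @return Number of assigned dimensions per rule.
#' @export
rule_dimensionality <- function(rule) {
  as.integer(rowSums(rbind(rule) > 0L))
}

# index of each canonical rule within the canonical 64-configuration set
rule_config_index <- function() {
  .cache_get("rule_cfg_idx", function() config_index(enumerate_rules()))
}

# dimensionality vector for the canonical 63 rules
rule_dims <- function() {
  .cache_get("rule_dims", function() rule_dimensionality(enumerate_rules()))
}

#' Reward probability of a stimulus under a rule
#'
#' The task's reward law: 0.2 if the stimulus contains none of the rule's
#' rewarding features, 0.8 if it contains all of them, and linear
#' interpolation in between: `0.2 + 0.6 * m / D`, where `m` is the number of
#' rule-assigned dimensions on which the stimulus matches and `D` the rule's
#' dimensionality.
#'
#' @param rule Integer vector of length 3 (0 = unassigned dimension).
#' @param stimulus Integer vector of length 3 (entries 1..3).
#' @return Reward probability in \{0.2, 0.4, 0.5, 0.6, 0.8\}.
#' @export
reward_probability <- function(rule, stimulus) {
  assigned <- rule > 0L
  D <- sum(assigned)
  stopifnot(D >= 1L, all(stimulus %in% 1:3))
  m <- sum(stimulus[assigned] == rule[assigned])
  0.2 + 0.6 * m / D
}

# 63 x 27 matrix of reward probabilities, canonical orders
rp_rule_stimulus <- function() {
  .cache_get("rp_mat", function() {
    r <- enumerate_rules()
    s <- stimuli()
    D <- rule_dims()
    m <- matrix(0L, nrow(r), nrow(s))
    for (i in seq_len(3)) {
      assigned <- r[, i] > 0L
      m <- m + outer(r[, i], s[, i], "==") * assigned
    }
    0.2 + 0.6 * m / D
  })
}

#' Expected reward of a (possibly incomplete) configuration under a rule
#'
#' Unselected dimensions are filled uniformly and independently by the
#' computer (each feature with probability 1/3); the expected reward
#' marginalizes the reward law over that fill.
#'
#' @param rule Integer vector of length 3 (0 = unassigned).
#' @param choice Integer vector of length 3 (0 = unselected).
#' @return Expected reward probability.
#' @export
expected_reward_under_rule <- function(rule, choice) {
  assigned <- rule > 0L
  D <- sum(assigned)
  stopifnot(D >= 1L)
  p_match <- ifelse(choice[assigned] == 0L, 1 / 3,
                    as.numeric(choice[assigned] == rule[assigned]))
  0.2 + 0.6 * sum(p_match) / D
}

# 63 x 64 matrix: expected reward of each configuration under each rule
er_rule_config <- function() {
  .cache_get("er_mat", function() {
    r <- enumerate_rules()
    g <- configurations()
    D <- rule_dims()
    m <- matrix(0, nrow(r), nrow(g))
    for (i in seq_len(3)) {
      assigned <- r[, i] > 0L
      pm <- outer(r[, i], g[, i], "==") + outer(rep(1, nrow(r)),
                                                g[, i] == 0L) / 3
      m <- m + pm * assigned
    }
    0.2 + 0.6 * m / D
  })
}

#' Chance reward probability for a game type
#'
#' Expected reward of a uniformly random complete stimulus under a rule of
#' the given dimensionality, by exact enumeration over the 27 stimuli. By
#' construction of the reward law this is 0.4 for every game type, so chance
#' behavior carries no information about rule dimensionality.
#'
#' @param complexity Rule dimensionality, 1, 2 or 3.
#' @return Chance reward probability.
#' @export
chance_reward_probability <- function(complexity) {
  stopifnot(complexity %in% 1:3)
  rules <- enumerate_rules(complexity)
  rule <- rules[1L, ]
  s <- stimuli()
  mean(vapply(seq_len(nrow(s)), function(i) reward_probability(rule, s[i, ]),
              numeric(1)))
}

#' Complete a configuration into a stimulus
#'
#' Selected dimensions are copied; unselected dimensions are drawn uniformly
#' and independently (the computer's random fill). Uses R's global RNG.
#'
#' @param choice Integer vector of length 3 (0 = unselected).
#' @return Integer vector of length 3 with entries in 1..3.
#' @export
realize_stimulus <- function(choice) {
  s <- as.integer(choice)
  open <- s == 0L
  if (any(open)) s[open] <- sample.int(3L, sum(open), replace = TRUE)
  s
}

#' Game specification
#'
#' @param complexity Number of relevant dimensions (1, 2 or 3).
#' @param known Logical; was the complexity revealed to the agent?
#' @param true_rule Integer vector of length 3 with `complexity` non-zero
#'   entries; drawn uniformly at random if `NULL`.
#' @param n_trials Trials in the game (default 30).
#' @return A `game_spec` list.
#' @export
game_spec <- function(complexity, known, true_rule = NULL, n_trials = 30L) {
  stopifnot(complexity %in% 1:3, is.logical(known), n_trials >= 1L)
  if (is.null(true_rule)) {
    rules <- enumerate_rules(complexity)
    true_rule <- rules[sample.int(nrow(rules), 1L), ]
  }
  true_rule <- as.integer(true_rule)
  if (sum(true_rule > 0L) != complexity) {
    stop("true_rule dimensionality must equal complexity", call. = FALSE)
  }
  structure(list(complexity = as.integer(complexity), known = known,
                 true_rule = true_rule, n_trials = as.integer(n_trials)),
            class = "game_spec")
}

# hint used by rule-based models for a game
game_hint <- function(spec) if (spec$known) spec$complexity else "unknown"

#' Assemble a played game
#'
#' @param spec A [game_spec()].
#' @param choices T x 3 integer matrix of configurations (0 = unselected).
#' @param stims T x 3 integer matrix of realized stimuli.
#' @param rewards Length-T 0/1 vector.
#' @return A `game` list with precomputed canonical choice indices.
#' @export
new_game <- function(spec, choices, stims, rewards) {
  choices <- rbind(choices); stims <- rbind(stims)
  stopifnot(nrow(choices) == length(rewards), nrow(stims) == length(rewards),
            all(rewards %in% 0:1))
  sel <- choices > 0L
  if (!all(stims[sel] == choices[sel])) {
    stop("stimulus disagrees with choice on a selected dimension",
         call. = FALSE)
  }
  structure(list(spec = spec, choices = choices, stimuli = stims,
                 rewards = as.integer(rewards),
                 choice_idx = config_index(choices),
                 stim_idx = stimulus_index(stims)),
            class = "game")
}

#' Assemble a session
#'
#' A session is the unit of fitting and cross-validation: an ordered list of
#' played games for one agent or participant.
#'
#' @param id Session identifier.
#' @param games List of games from [new_game()].
#' @return A `session` list.
#' @export
new_session <- function(id, games) {
  stopifnot(length(games) >= 1L)
  structure(list(id = id, games = games), class = "session")
}

# total trial count of a session (optionally a subset of games)
session_n_trials <- function(session, games = seq_along(session$games)) {
  sum(vapply(session$games[games], function(g) length(g$rewards), integer(1)))
}
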