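# Synthetic cohorts: full experimental sessions generated from any
# implemented model, emulating the experiment's design (18 games per
# session: 3 games of each of the 6 types formed by crossing complexity
# 1/2/3 with known/unknown, 30 trials per game, randomized game order,
# true rules drawn uniformly at dimensionality). Used for parameter- and
# model-recovery studies and learning-curve summaries in place of the
# human dataset.

#' Generate a randomized session design
#'
#' @param n_per_type Games per game type (default 3, for 18 games total).
#' @param n_trials Trials per game (default 30).
#' @return List of [game_spec()] objects in randomized order, with true
#'   rules drawn uniformly among rules of the required dimensionality. Uses
#'   R's global RNG.
#' @export
generate_design <- function(n_per_type = 3L, n_trials = 30L) {
  specs <- list()
  for (known in c(TRUE, FALSE)) {
    for (D in 1:3) {
      for (i in seq_len(n_per_type)) {
        specs[[length(specs) + 1L]] <-
          game_spec(D, known, true_rule = NULL, n_trials = n_trials)
      }
    }
  }
  specs[sample.int(length(specs))]
}

#' Cohort specification
#'
#' @param n_agents Number of simulated agents.
#' @param model Generating model identifier from [mdprl_models()].
#' @param par Named parameter vector (fixed for every agent), or `NULL` to
#'   sample per-agent parameters from `ranges`.
#' @param ranges Named list of `c(lower, upper)` sampling ranges; defaults to
#'   the model's documented `recovery_ranges`. Inverse temperatures are
#'   sampled log-uniformly.
#' @param n_per_type,n_trials Design parameters (defaults 3 and 30, the
#'   standard 18-game design).
#' @param seed Master seed; all randomness in [simulate_cohort()] flows from
#'   it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_agents, model, par = NULL, ranges = NULL,
                        n_per_type = 3L, n_trials = 30L, seed = 1L) {
  info <- model_info(model)
  if (is.null(par) && is.null(ranges)) ranges <- info$recovery_ranges
  if (is.null(par) && is.null(ranges)) {
    stop("no parameter ranges documented for model ", model,
         "; supply `par` or `ranges`", call. = FALSE)
  }
  if (!is.null(par)) stopifnot(all(info$par_names %in% names(par)))
  structure(list(n_agents = as.integer(n_agents), model = model, par = par,
                 ranges = ranges, n_per_type = as.integer(n_per_type),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw one agent's parameters from the spec (fixed or sampled)
.draw_par <- function(spec) {
  info <- model_info(spec$model)
  if (!is.null(spec$par)) return(spec$par[info$par_names])
  p <- vapply(info$par_names, function(nm) {
    rg <- spec$ranges[[nm]]
    if (is.null(rg)) stop("no range for parameter ", nm, call. = FALSE)
    if (info$log_scale[match(nm, info$par_names)]) {
      exp(runif(1, log(rg[1]), log(rg[2])))
    } else {
      runif(1, rg[1], rg[2])
    }
  }, numeric(1))
  names(p) <- info$par_names
  p
}

#' Simulate one full session from a model
#'
#' @param design List of [game_spec()]s (e.g. from [generate_design()]).
#' @param model Model identifier.
#' @param par Named parameter vector.
#' @param id Session identifier.
#' @return A `session`; each game keeps any latent attributes the model's
#'   simulator records (e.g. SHT hypothesis trajectories), for diagnostics
#'   only — fitting consumes only the observables. Uses R's global RNG.
#' @export
simulate_session <- function(design, model, par, id = "sim") {
  sim <- model_info(model)$simulate
  games <- lapply(design, function(spec) sim(spec, par))
  s <- new_session(id, games)
  attr(s, "model") <- model
  attr(s, "par") <- par
  s
}

#' Simulate a reproducible cohort
#'
#' @param spec A [cohort_spec()].
#' @return A `mdprl_cohort` list of sessions; `attr(, "spec")` records the
#'   generating specification and each session records its generating
#'   parameters. Fully determined by the spec's master seed.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sessions <- lapply(seq_len(spec$n_agents), function(i) {
    par <- .draw_par(spec)
    design <- generate_design(spec$n_per_type, spec$n_trials)
    simulate_session(design, spec$model, par,
                     id = sprintf("%s_agent%02d", spec$model, i))
  })
  structure(sessions, class = "mdprl_cohort", spec = spec)
}

#' Parameter-recovery study
#'
#' Simulates a cohort with parameters sampled from documented ranges, refits
#' the generating model to each session by maximum likelihood, and tabulates
#' generating against recovered parameters with per-parameter Spearman rank
#' correlations.
#'
#' @param model Model identifier.
#' @param n_agents Number of simulated agents (sessions).
#' @param ranges Sampling ranges (default: the model's documented
#'   `recovery_ranges`).
#' @param n_restarts Restarts per fit.
#' @param n_per_type,n_trials Design parameters.
#' @param seed Master seed.
#' @return List with `table` (long data.frame: session, parameter, true,
#'   recovered) and `rank_cor` (named Spearman correlations).
#' @export
recovery_study <- function(model, n_agents = 30L, ranges = NULL,
                           n_restarts = 5L, n_per_type = 3L, n_trials = 30L,
                           seed = 1L) {
  cs <- cohort_spec(n_agents, model, par = NULL, ranges = ranges,
                    n_per_type = n_per_type, n_trials = n_trials,
                    seed = seed)
  cohort <- simulate_cohort(cs)
  info <- model_info(model)
  rows <- list()
  for (i in seq_along(cohort)) {
    true_par <- attr(cohort[[i]], "par")
    fit <- fit_mle(cohort[[i]], model, n_restarts = n_restarts,
                   seed = seed + 1000L + i)
    rows[[i]] <- data.frame(session = cohort[[i]]$id,
                            parameter = info$par_names,
                            true = unname(true_par[info$par_names]),
                            recovered = unname(fit$par[info$par_names]))
  }
  tab <- do.call(rbind, rows)
  rank_cor <- vapply(info$par_names, function(nm) {
    sub <- tab[tab$parameter == nm, ]
    if (sd(sub$true) == 0 || sd(sub$recovered) == 0) return(NA_real_)
    cor(sub$true, sub$recovered, method = "spearman")
  }, numeric(1))
  list(table = tab, rank_cor = rank_cor)
}

#' Model-recovery study (confusion matrix)
#'
#' Simulates a cohort from each generating model at its documented reference
#' parameters, evaluates every candidate model on every session with
#' leave-one-game-out cross-validation, and reports the mean geometric
#' likelihood per trial in a generating-by-candidate matrix. Successful
#' recovery puts the row-wise maximum on the diagonal.
#'
#' @param models Model identifiers (default: the four main models).
#' @param n_agents Agents per generating model.
#' @param n_restarts Restarts per CV fold.
#' @param maxit Optimizer iteration budget per CV fit (default 60; the
#'   fits are warm-started, and the cap also curbs overfitting of the
#'   flexible models in the short training sets).
#' @param cross_pass If `TRUE` (default), re-run the random-switch CV with
#'   the value-based optima projected onto the shared parameters as extra
#'   starts (symmetric treatment of the nested pair).
#' @param n_per_type,n_trials Design parameters.
#' @param seed Master seed.
#' @return List with `confusion` (matrix of mean CV likelihood per trial,
#'   rows = generating model) and `cv` (nested per-session results).
#' @export
model_recovery <- function(models = c("rl", "bayes", "sht_random",
                                      "sht_value"),
                           n_agents = 20L, n_restarts = 2L,
                           n_per_type = 3L, n_trials = 30L, seed = 1L,
                           maxit = 60L, cross_pass = TRUE) {
  confusion <- matrix(NA_real_, length(models), length(models),
                      dimnames = list(generator = models, fitted = models))
  cv_all <- list()
  for (gi in seq_along(models)) {
    gen <- models[gi]
    cs <- cohort_spec(n_agents, gen, par = model_info(gen)$default_par,
                      n_per_type = n_per_type, n_trials = n_trials,
                      seed = seed + 17L * gi)
    cohort <- simulate_cohort(cs)
    cv_by_session <- lapply(seq_along(cohort), function(i) {
      res <- list()
      for (m in models) {
        # the value-based SHT model nests the random-switch model; seed its
        # all-games fit and every fold fit with the corresponding fitted
        # random-switch optimum, so the nested comparison is decided by
        # generalization rather than optimizer luck
        init <- NULL
        fold_init <- NULL
        if (m == "sht_value" && !is.null(res[["sht_random"]])) {
          nest <- function(p) c(p, eta = 0, decay = 0.5, beta_switch = 1e-3)
          if (!is.null(res[["sht_random"]]$full_par)) {
            init <- nest(res[["sht_random"]]$full_par)
          }
          fp <- res[["sht_random"]]$fold_par
          fold_init <- cbind(fp, eta = 0, decay = 0.5, beta_switch = 1e-3)
        }
        res[[m]] <- logo_cv(cohort[[i]], m, n_restarts = n_restarts,
                            seed = seed + 100L * gi + i, init = init,
                            fold_init = fold_init, maxit = maxit)
      }
      # symmetric second pass for the nested pair: re-run the random-switch
      # CV with the value-based optima projected onto the shared parameters
      # as additional starts (start selection inside each fit remains by
      # training likelihood)
      if (cross_pass && all(c("sht_random", "sht_value") %in% models)) {
        shared <- model_info("sht_random")$par_names
        v <- res[["sht_value"]]
        init_r <- rbind(res[["sht_random"]]$full_par,
                        if (!is.null(v$full_par)) v$full_par[shared])
        res[["sht_random"]] <- logo_cv(cohort[[i]], "sht_random",
                                       n_restarts = n_restarts,
                                       seed = seed + 100L * gi + i,
                                       init = init_r, maxit = maxit,
                                       fold_init = v$fold_par[, shared,
                                                              drop = FALSE])
      }
      res
    })
    cv_all[[gen]] <- cv_by_session
    for (m in models) {
      confusion[gen, m] <- mean(vapply(cv_by_session,
                                       function(s) s[[m]]$geom_lik,
                                       numeric(1)))
    }
  }
  list(confusion = confusion, cv = cv_all)
}
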