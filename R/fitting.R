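# Maximum-likelihood fitting with multiple random restarts, leave-one-game-
# out cross-validation, and the model-comparison / mechanism-contribution
# summaries. Inverse temperatures are optimized on a log scale; all other
# parameters on their natural scale, under box constraints (L-BFGS-B with
# numeric gradients).

.to_opt_space <- function(par, info) ifelse(info$log_scale, log(par), par)
.from_opt_space <- function(u, info) {
  p <- ifelse(info$log_scale, exp(u), u)
  names(p) <- info$par_names
  p
}

#' Fit a model to a session by maximum likelihood
#'
#' Bounded quasi-Newton optimization (L-BFGS-B, numeric gradients) of the
#' negative log-likelihood from `n_restarts` random starting points, uniform
#' within bounds (log-uniform for inverse temperatures); the best restart is
#' returned. Restart draws are derived from `seed`, so the fit is fully
#' reproducible.
#'
#' @param session A [new_session()] object.
#' @param model A model identifier from [mdprl_models()].
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param games Indices of games to fit on (default all; used by
#'   cross-validation).
#' @param init Optional named parameter vector (or matrix with one
#'   parameter set per row) tried as additional starting points (warm
#'   starts).
#' @param maxit Iteration budget per optimization (default 500).
#' @return An `mdprl_fit` list: `model`, best `par` (natural scale),
#'   `loglik`, `by_game`, `n_trials`, per-restart table `restarts`, and
#'   overall `convergence` flag (0 = converged).
#' @export
fit_mle <- function(session, model, n_restarts = 10, seed = 1L,
                    games = NULL, init = NULL, maxit = 500L) {
  stopifnot(n_restarts >= 1 || !is.null(init))
  info <- model_info(model)
  npar <- length(info$par_names)
  lo <- .to_opt_space(info$lower, info)
  hi <- .to_opt_space(info$upper, info)

  nll <- function(u) {
    p <- .from_opt_space(u, info)
    v <- tryCatch(info$loglik(session, p, games)$total,
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  # forward-difference gradient (n+1 evaluations instead of optim's 2n),
  # reusing the objective value L-BFGS-B just computed at the same point
  last_eval <- NULL
  nll_cached <- function(u) {
    v <- nll(u)
    last_eval <<- list(u = u, v = v)
    v
  }
  grad <- function(u) {
    v0 <- if (!is.null(last_eval) && identical(last_eval$u, u)) {
      last_eval$v
    } else {
      nll(u)
    }
    g <- numeric(npar)
    h <- 1e-6 * pmax(abs(u), 1)
    for (i in seq_len(npar)) {
      u2 <- u
      u2[i] <- u[i] + h[i]
      if (u2[i] > hi[i]) u2[i] <- u[i] - h[i]  # step inside at the bound
      g[i] <- (nll(u2) - v0) / (u2[i] - u[i])
    }
    g
  }

  set.seed(seed)
  starts <- matrix(runif(n_restarts * npar, rep(lo, each = n_restarts),
                         rep(hi, each = n_restarts)),
                   nrow = n_restarts, ncol = npar)
  if (!is.null(init)) {
    im <- rbind(init)
    im <- im[, info$par_names, drop = FALSE]
    u0 <- matrix(NA_real_, nrow(im), npar)
    for (r in seq_len(nrow(im))) {
      u0[r, ] <- pmin(pmax(.to_opt_space(im[r, ], info), lo), hi)
    }
    starts <- rbind(u0, starts)
  }

  best <- NULL
  restarts <- data.frame(restart = integer(), loglik = numeric(),
                         convergence = integer())
  for (r in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[r, ], nll_cached, gr = grad, method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    restarts <- rbind(restarts,
                      data.frame(restart = r, loglik = -opt$value,
                                 convergence = opt$convergence))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all restarts failed", call. = FALSE)
  par <- .from_opt_space(best$par, info)
  ll <- tryCatch(info$loglik(session, par, games),
                 error = function(e) list(total = -Inf,
                                          by_game = NA_real_,
                                          n_trials = NA_integer_))
  structure(list(model = model, par = par, loglik = ll$total,
                 by_game = ll$by_game, n_trials = ll$n_trials,
                 restarts = restarts, convergence = best$convergence),
            class = "mdprl_fit")
}

#' Leave-one-game-out cross-validation
#'
#' One fold per game: the model is fit on the other games and the held-out
#' game's log-likelihood is evaluated at those parameters. The summary
#' statistic is the geometric average likelihood per trial,
#' `exp(sum(held-out loglik) / sum(held-out trials))`; chance level for the
#' 64-configuration choice set is 1/64.
#'
#' @param session A [new_session()] object with at least 2 games.
#' @param model A model identifier.
#' @param n_restarts Random restarts per fold; 0 is allowed with
#'   `warm_start = TRUE` (folds then re-optimize from the all-games optimum
#'   only).
#' @param seed Integer seed; fold `g` uses `seed + g`.
#' @param warm_start If `TRUE` (default), an all-games fit is computed first
#'   and its optimum is added as a starting point in every fold.
#' @param init Optional named parameter vector tried as an additional
#'   starting point for the all-games fit (e.g. the optimum of a nested
#'   model).
#' @param fold_init Optional matrix (one row per game, columns named by
#'   parameter) of additional per-fold starting points, e.g. the per-fold
#'   optima of a nested model.
#' @param maxit Iteration budget per optimization (default 500).
#' @return An `mdprl_cv` list: `model`, per-fold held-out `by_game`
#'   log-likelihoods and `n_trials`, `geom_lik`, the per-fold parameter
#'   matrix `fold_par`, and the all-games optimum `full_par` when
#'   `warm_start` is used.
#' @export
logo_cv <- function(session, model, n_restarts = 10, seed = 1L,
                    warm_start = TRUE, init = NULL, fold_init = NULL,
                    maxit = 500L) {
  n_games <- length(session$games)
  stopifnot(n_games >= 2)
  info <- model_info(model)
  init <- if (warm_start) {
    fit_mle(session, model, n_restarts = max(1L, n_restarts),
            seed = seed, init = init, maxit = maxit)$par
  } else init
  if (!is.null(fold_init)) {
    stopifnot(nrow(fold_init) == n_games)
    fold_init <- fold_init[, info$par_names, drop = FALSE]
  }
  by_game <- numeric(n_games)
  n_trials <- integer(n_games)
  fold_par <- matrix(NA_real_, n_games, length(info$par_names),
                     dimnames = list(NULL, info$par_names))
  for (g in seq_len(n_games)) {
    inits_g <- init
    if (!is.null(fold_init)) {
      base <- if (!is.null(init)) {
        rbind(init)[, info$par_names, drop = FALSE]
      }
      inits_g <- rbind(base, fold_init[g, , drop = FALSE])
    }
    fit <- fit_mle(session, model, n_restarts = n_restarts,
                   seed = seed + g, games = setdiff(seq_len(n_games), g),
                   init = inits_g, maxit = maxit)
    held <- info$loglik(session, fit$par, games = g)
    by_game[g] <- held$total
    n_trials[g] <- held$n_trials
    fold_par[g, ] <- fit$par
  }
  structure(list(model = model, by_game = by_game, n_trials = n_trials,
                 geom_lik = exp(sum(by_game) / sum(n_trials)),
                 fold_par = fold_par, full_par = init),
            class = "mdprl_cv")
}

# geometric likelihood per trial on a subset of games
.geom_lik_subset <- function(cv, idx) {
  exp(sum(cv$by_game[idx]) / sum(cv$n_trials[idx]))
}

#' Mechanism contributions from cross-validated likelihoods
#'
#' The contribution of each learning mechanism is read off as the difference
#' in cross-validated likelihood per trial between the hybrid (value-based
#' SHT) model and the component model that omits the mechanism: the SHT
#' contribution is hybrid minus feature RL, the RL contribution is hybrid
#' minus random-switch SHT. Reported overall and per game type. Per-trial
#' log-likelihood columns are included as well; unlike the geometric
#' likelihoods, they recombine additively across game types when weighted by
#' trial counts.
#'
#' @param cv_hybrid,cv_rl,cv_sht `mdprl_cv` results for the hybrid,
#'   feature-RL, and random-switch SHT models on the same session.
#' @param session The session the CV results were computed on.
#' @return A data.frame with one row overall and one per game type.
#' @export
contribution_metrics <- function(cv_hybrid, cv_rl, cv_sht, session) {
  n_games <- length(session$games)
  for (cv in list(cv_hybrid, cv_rl, cv_sht)) {
    if (length(cv$by_game) != n_games ||
        !identical(as.integer(cv$n_trials),
                   vapply(session$games, function(g) length(g$rewards),
                          integer(1)))) {
      stop("CV results do not match the session", call. = FALSE)
    }
  }
  cx <- vapply(session$games, function(g) g$spec$complexity, integer(1))
  kn <- vapply(session$games, function(g) g$spec$known, logical(1))
  groups <- c(list(overall = seq_len(n_games)),
              stats::setNames(
                lapply(seq_len(6), function(i) {
                  D <- ((i - 1) %% 3) + 1
                  K <- i <= 3
                  which(cx == D & kn == K)
                }),
                paste0(rep(c("known", "unknown"), each = 3), "_",
                       rep(1:3, 2), "D")))
  rows <- lapply(names(groups), function(nm) {
    idx <- groups[[nm]]
    nt <- sum(cv_hybrid$n_trials[idx])
    lh <- .geom_lik_subset(cv_hybrid, idx)
    lr <- .geom_lik_subset(cv_rl, idx)
    ls <- .geom_lik_subset(cv_sht, idx)
    data.frame(scope = nm, n_trials = nt,
               lik_hybrid = lh, lik_rl = lr, lik_sht_random = ls,
               sht_contribution = lh - lr, rl_contribution = lh - ls,
               loglik_hybrid = log(lh), loglik_rl = log(lr),
               loglik_sht_random = log(ls))
  })
  do.call(rbind, rows)
}

#' Model-comparison table over a cohort
#'
#' Mean and standard error across sessions of the cross-validated geometric
#' likelihood per trial for each model, with the chance level 1/64.
#'
#' @param cv_by_session List over sessions; each element a named list of
#'   `mdprl_cv` results keyed by model.
#' @return A data.frame with one row per model, sorted by mean likelihood.
#' @export
model_comparison_table <- function(cv_by_session) {
  stopifnot(length(cv_by_session) >= 1)
  models <- names(cv_by_session[[1]])
  rows <- lapply(models, function(m) {
    liks <- vapply(cv_by_session, function(s) s[[m]]$geom_lik, numeric(1))
    data.frame(model = m, n_sessions = length(liks),
               mean_lik_per_trial = mean(liks),
               sem = if (length(liks) > 1) sd(liks) / sqrt(length(liks))
                     else NA_real_,
               chance = 1 / 64)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_lik_per_trial), ]
}
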