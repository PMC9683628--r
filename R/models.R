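# Model registry: a uniform surface (parameter names, bounds, log-scale
# flags, likelihood and simulator) over the four main models and the
# published variants of the value-based SHT model, so fitting,
# cross-validation and recovery studies can treat models generically.

.sht_par_to_params <- function(model, par) {
  base <- list(w_l = par[["w_l"]], w_h = par[["w_h"]],
               beta_stay = par[["beta_stay"]], lambda = par[["lambda"]])
  extra <- switch(model,
    sht_random = list(theta = par[["theta"]], switch_policy = "random"),
    sht_value = list(theta = par[["theta"]], switch_policy = "value",
                     eta = par[["eta"]], decay = par[["decay"]],
                     beta_switch = par[["beta_switch"]]),
    sht_value_gate = list(theta = par[["theta"]], switch_policy = "value",
                          eta = par[["eta"]], decay = par[["decay"]],
                          beta_switch = par[["beta_switch"]],
                          test_gate = TRUE, beta_test = par[["beta_test"]],
                          theta_test = par[["theta_test"]]),
    sht_value_rp = list(switch_policy = "value", eta = par[["eta"]],
                        decay = par[["decay"]],
                        beta_switch = par[["beta_switch"]],
                        rp_target = TRUE, delta = par[["delta"]]),
    sht_value_superset = list(theta = par[["theta"]],
                              switch_policy = "value", eta = par[["eta"]],
                              decay = par[["decay"]],
                              beta_switch = par[["beta_switch"]],
                              superset_choice = TRUE, k = par[["k"]]),
    sht_value_full = list(theta = par[["theta"]], switch_policy = "value",
                          eta = par[["eta"]], decay = par[["decay"]],
                          beta_switch = par[["beta_switch"]],
                          test_gate = TRUE, beta_test = par[["beta_test"]],
                          theta_test = par[["theta_test"]],
                          superset_choice = TRUE, k = par[["k"]]),
    stop("unknown SHT model: ", model, call. = FALSE))
  do.call(sht_params, c(base, extra))
}

.registry <- function() {
  beta_b <- c(1e-3, 100)  # log scale cannot include 0; 1e-3 is effectively 0
  unit <- c(0, 1)
  w_b <- c(0, 10)
  sht_core <- list(w_l = w_b, w_h = w_b, beta_stay = beta_b, theta = unit,
                   lambda = unit)
  sht_value_pars <- c(sht_core, list(eta = unit, decay = unit,
                                     beta_switch = beta_b))
  mk <- function(bounds, log_scale, loglik, simulate, default_par,
                 recovery_ranges = NULL) {
    list(par_names = names(bounds),
         lower = vapply(bounds, `[`, numeric(1), 1L),
         upper = vapply(bounds, `[`, numeric(1), 2L),
         log_scale = names(bounds) %in% log_scale,
         loglik = loglik, simulate = simulate, default_par = default_par,
         recovery_ranges = recovery_ranges)
  }
  sht_ll <- function(model) {
    force(model)
    function(session, par, games = NULL) {
      sht_session_loglik(session, .sht_par_to_params(model, par), games)
    }
  }
  sht_sim <- function(model) {
    force(model)
    function(spec, par) sht_simulate_game(spec, .sht_par_to_params(model, par))
  }
  sht_defaults <- c(w_l = 0.15, w_h = 0.15, beta_stay = 10, theta = 0.45,
                    lambda = 0.12)
  sht_value_defaults <- c(sht_defaults, eta = 0.35, decay = 0.6,
                          beta_switch = 6)
  list(
    rl = mk(
      list(beta = beta_b, eta_s = unit, eta_r = unit, decay = unit),
      log_scale = "beta",
      loglik = function(session, par, games = NULL) {
        rl_session_loglik(session, rl_params(par[["beta"]], par[["eta_s"]],
                                             par[["eta_r"]],
                                             par[["decay"]]), games)
      },
      simulate = function(spec, par) {
        rl_simulate_game(spec, rl_params(par[["beta"]], par[["eta_s"]],
                                         par[["eta_r"]], par[["decay"]]))
      },
      default_par = c(beta = 8, eta_s = 0.4, eta_r = 0.2, decay = 0.6),
      recovery_ranges = list(beta = c(2, 20), eta_s = c(0.1, 0.6),
                             eta_r = c(0.05, 0.4), decay = c(0.3, 0.8))),
    bayes = mk(
      list(beta = beta_b),
      log_scale = "beta",
      loglik = function(session, par, games = NULL) {
        bayes_session_loglik(session, bayes_params(par[["beta"]]), games)
      },
      simulate = function(spec, par) {
        bayes_simulate_game(spec, bayes_params(par[["beta"]]))
      },
      default_par = c(beta = 8),
      recovery_ranges = list(beta = c(2, 20))),
    sht_random = mk(
      sht_core, log_scale = "beta_stay",
      loglik = sht_ll("sht_random"), simulate = sht_sim("sht_random"),
      default_par = sht_defaults,
      recovery_ranges = list(w_l = c(0.05, 0.5), w_h = c(0.05, 0.5),
                             beta_stay = c(3, 20), theta = c(0.3, 0.7),
                             lambda = c(0.05, 0.3))),
    sht_value = mk(
      sht_value_pars, log_scale = c("beta_stay", "beta_switch"),
      loglik = sht_ll("sht_value"), simulate = sht_sim("sht_value"),
      default_par = sht_value_defaults,
      recovery_ranges = list(w_l = c(0.05, 0.5), w_h = c(0.05, 0.5),
                             beta_stay = c(3, 20), theta = c(0.3, 0.7),
                             lambda = c(0.05, 0.3), eta = c(0.1, 0.6),
                             decay = c(0.3, 0.8), beta_switch = c(2, 15))),
    sht_value_gate = mk(
      c(sht_value_pars, list(beta_test = beta_b, theta_test = unit)),
      log_scale = c("beta_stay", "beta_switch", "beta_test"),
      loglik = sht_ll("sht_value_gate"),
      simulate = sht_sim("sht_value_gate"),
      default_par = c(sht_value_defaults, beta_test = 5, theta_test = 0.3)),
    sht_value_rp = mk(
      c(sht_core[setdiff(names(sht_core), "theta")],
        list(eta = unit, decay = unit, beta_switch = beta_b,
             delta = c(-0.5, 0.5))),
      log_scale = c("beta_stay", "beta_switch"),
      loglik = sht_ll("sht_value_rp"),
      simulate = sht_sim("sht_value_rp"),
      default_par = c(sht_defaults[setdiff(names(sht_defaults), "theta")],
                      eta = 0.35, decay = 0.6, beta_switch = 6,
                      delta = -0.1)),
    sht_value_superset = mk(
      c(sht_value_pars, list(k = c(-5, 5))),
      log_scale = c("beta_stay", "beta_switch"),
      loglik = sht_ll("sht_value_superset"),
      simulate = sht_sim("sht_value_superset"),
      default_par = c(sht_value_defaults, k = 1)),
    sht_value_full = mk(
      c(sht_value_pars, list(beta_test = beta_b, theta_test = unit,
                             k = c(-5, 5))),
      log_scale = c("beta_stay", "beta_switch", "beta_test"),
      loglik = sht_ll("sht_value_full"),
      simulate = sht_sim("sht_value_full"),
      default_par = c(sht_value_defaults, beta_test = 5, theta_test = 0.3,
                      k = 1))
  )
}

#' Names of the implemented models
#'
#' The four main models are `"rl"` (feature RL with decay), `"bayes"`
#' (Bayesian rule learning), `"sht_random"` (random-switch serial hypothesis
#' testing) and `"sht_value"` (value-based SHT, the hybrid model);
#' `"sht_value_gate"`, `"sht_value_rp"`, `"sht_value_superset"` and
#' `"sht_value_full"` are the published variants of the hybrid model.
#'
#' @return Character vector of model identifiers.
#' @export
mdprl_models <- function() names(.registry())

#' Model metadata: parameters, bounds, likelihood and simulator
#'
#' @param model A model identifier from [mdprl_models()].
#' @return List with `par_names`, `lower`, `upper`, `log_scale` (parameters
#'   fitted on a log scale), `loglik(session, par, games)`,
#'   `simulate(spec, par)`, `default_par` (documented reference values used
#'   as generating parameters in model-recovery studies) and
#'   `recovery_ranges` (documented sampling ranges for parameter recovery;
#'   `NULL` for variant models).
#' @export
model_info <- function(model) {
  reg <- .cache_get("registry", .registry)
  if (!model %in% names(reg)) {
    stop("unknown model: ", model, "; see mdprl_models()", call. = FALSE)
  }
  reg[[model]]
}

#' Session log-likelihood of any registered model
#'
#' @param model A model identifier from [mdprl_models()].
#' @param session A [new_session()] object.
#' @param par Named parameter vector (see `model_info(model)$par_names`).
#' @param games Indices of games to include (default all).
#' @return List with `total`, `by_game`, `n_trials`.
#' @export
model_loglik <- function(model, session, par, games = NULL) {
  model_info(model)$loglik(session, par, games)
}
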