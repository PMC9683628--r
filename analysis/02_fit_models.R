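#!/usr/bin/env Rscript

# Maximum-likelihood fits of the four main models to the value-based SHT
# (hybrid) cohort simulated by 01_simulate_cohorts.R. Writes the fitted
# parameters and total log-likelihoods per session.

suppressPackageStartupMessages(library(mdprl))

seed <- 20260929L
cohort <- read_sessions_csv("results/cohorts/sht_value.csv")
n_fit <- min(5L, length(cohort))  # fits are reported for the first sessions
models <- c("rl", "bayes", "sht_random", "sht_value")

rows <- list()
for (i in seq_len(n_fit)) {
  for (m in models) {
    fit <- fit_mle(cohort[[i]], m, n_restarts = 5L, seed = seed + 10L * i)
    rows[[length(rows) + 1L]] <- data.frame(
      session = cohort[[i]]$id, model = m, loglik = fit$loglik,
      loglik_per_trial = fit$loglik / sum(fit$n_trials),
      parameter = names(fit$par), estimate = unname(fit$par))
    cat(sprintf("session %s | %-11s loglik %.1f\n", cohort[[i]]$id, m,
                fit$loglik))
  }
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/fits_hybrid_cohort.csv", row.names = FALSE)
cat("wrote results/fits_hybrid_cohort.csv\n")
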