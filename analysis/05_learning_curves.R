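#!/usr/bin/env Rscript

# Learning-curve summaries of the simulated cohorts: expected reward
# probability and number of features selected by game type and trial,
# with figures.

suppressPackageStartupMessages({
  library(mdprl)
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

plot_curve <- function(tab, ylab, ref = NULL) {
  tab$complexity <- factor(paste0(tab$complexity, "D-relevant"))
  p <- ggplot(tab, aes(trial, mean, color = knowledge, fill = knowledge)) +
    geom_ribbon(aes(ymin = mean - sem, ymax = mean + sem), alpha = 0.25,
                color = NA) +
    geom_line() +
    facet_wrap(~complexity) +
    labs(x = "trial", y = ylab, color = NULL, fill = NULL) +
    theme_minimal()
  if (!is.null(ref)) p <- p + geom_hline(yintercept = ref,
                                         linetype = "dashed")
  p
}

for (m in c("sht_value", "rl", "chance")) {
  path <- file.path("results/cohorts", paste0(m, ".csv"))
  if (!file.exists(path)) next
  cohort <- read_sessions_csv(path)
  rc <- reward_prob_curve(cohort)
  fc <- features_selected_curve(cohort)
  write.csv(rc, sprintf("results/reward_curve_%s.csv", m),
            row.names = FALSE)
  write.csv(fc, sprintf("results/features_curve_%s.csv", m),
            row.names = FALSE)
  ggsave(sprintf("results/figures/reward_curve_%s.png", m),
         plot_curve(rc, "expected reward probability", ref = c(0.4, 0.8)),
         width = 8, height = 3, dpi = 120)
  ggsave(sprintf("results/figures/features_curve_%s.png", m),
         plot_curve(fc, "features selected"),
         width = 8, height = 3, dpi = 120)
  late <- rc[rc$trial > 20, ]
  cat(sprintf("%-9s late-game reward prob by complexity: %s\n", m,
              paste(sprintf("%dD %.3f", 1:3, vapply(1:3, function(D) {
                mean(late$mean[late$complexity == D])
              }, numeric(1))), collapse = ", ")))
}
cat("wrote results/*_curve_*.csv and results/figures/*.png\n")
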