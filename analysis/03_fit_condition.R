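#!/usr/bin/env Rscript
# Stage 3 — Model 1: hierarchical fit with the binary Stress/Control
# indicator, plus the male-only sensitivity refit and the Day-1
# payment-change correlations.
#
# Fits here use the desk-scale sampler settings (4 chains x 500 warmup x
# 500 kept); pass --full for the study-scale 4 x 3000 x 3000 configuration.

suppressPackageStartupMessages(library(stressrisk))
seed <- 20160923L
mc <- if ("--full" %in% commandArgs(TRUE)) mcmc_config() else
  mcmc_config_desk()

st <- read_study("results/study")
fit <- fit_hierarchical(st, "condition", mcmc = mc, seed = seed)
rep <- fit_report(fit)
print(rep)

fit_m <- subset_fit(st, gender = "male", variant = "condition", mcmc = mc,
                    seed = seed + 1L)
cat("\n-- male-only refit (", fit_m$meta$n_subjects, "subjects ) --\n")
print(fit_report(fit_m))

# Day-1 payment change vs posterior-mean day effects
d1 <- st$sessions[st$sessions$day == 0, ]
pay <- setNames(d1$adjusted_endowment - 30, d1$subject_id)
em <- subject_effect_means(fit, "day")
corr <- effect_correlations(pay[rownames(em)], em)
cat("\n-- Day-1 payment-change correlations with day effects --\n")
print(corr)

dir.create("results/model1", showWarnings = FALSE, recursive = TRUE)
write.csv(corr, "results/model1/payment_correlations.csv",
          row.names = FALSE)
report_path <- "results/model1/report.json"
jsonlite::write_json(list(
  recovered = lapply(rep$recovered, unclass),
  effect_CIs = lapply(rep$effect_CIs, function(ci) apply(ci, 1, as.list)),
  rhat_group_mean = rep$rhat_group_mean,
  male_only = lapply(fit_report(fit_m)$recovered, unclass)),
  report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("report written to", report_path, "\n")
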