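#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study bundle.
#
# The target design: 120 participants, fully crossed Stress/Control over two
# days (30 per group, 64 female / 56 male), 150 risky choices per session
# (120 gain-loss, 30 gain-only, unique value triples, random order), four
# salivary cortisol samples per subject-day with group-specific trajectories,
# $30 endowment adjusted by 15 randomly paid trials. No raw data are
# deposited for the original study, so this synthetic cohort — generated at
# the reported group-level parameter values — is the input for every later
# stage.

suppressPackageStartupMessages(library(stressrisk))
seed <- 20160922L

cfg <- study_config()   # defaults: n = 120, task-typical hyperparameters
st <- simulate_study(cfg, seed = seed)
print(st)

dir.create("results", showWarnings = FALSE)
write_study(st, "results/study")

sm <- session_summaries(st)
cat(sprintf("pooled empirical P(gamble): %.3f (stress %.3f, control %.3f)\n",
            mean(sm$p_gamble_empirical),
            mean(sm$p_gamble_empirical[sm$condition == 1]),
            mean(sm$p_gamble_empirical[sm$condition == 0])))
cat(sprintf("mean adjusted endowment: Day 1 $%.2f, Day 2 $%.2f\n",
            mean(sm$adjusted_endowment[sm$day == 0]),
            mean(sm$adjusted_endowment[sm$day == 1])))
write.csv(sm, "results/session_summaries.csv", row.names = FALSE)
cat("study bundle written to results/study\n")
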