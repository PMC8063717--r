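#!/usr/bin/env Rscript
# Simulate the study's behavioral data: ten 195-trial main-task sessions
# plus matched follow-up sessions (internal-only perceptual trials), for a
# no-stimulation condition and a metacognitive-noise ("stimulation")
# condition sharing the same seed stream. Writes the trial logs that all
# later analysis stages read.

suppressPackageStartupMessages(library(prospectmeta))
dir.create("results", showWarnings = FALSE)

seed <- 2026
spec <- simulation_spec(n_sessions = 10, seed = seed)
sim <- simulate_experiment(spec)
write_session_log(sim$main, "results/trials_baseline.tsv")
write_session_log(sim$followup, "results/followup_baseline.tsv")

tms <- simulate_experiment(simulation_spec(n_sessions = 10, seed = seed,
                                           tms_condition = "alpfc"))
write_session_log(tms$main, "results/trials_tms.tsv")
write_session_log(tms$followup, "results/followup_tms.tsv")

fu <- suppressWarnings(followup_table(sim$followup))
write_followup_table(fu, "results/followup_table_baseline.tsv")
write_followup_table(suppressWarnings(followup_table(tms$followup)),
                     "results/followup_table_tms.tsv")

message(sprintf("baseline: %d trials, %.1f%% internal choices, follow-up accuracy %.2f-%.2f",
                nrow(sim$main$trials), 100 * mean(sim$main$trials$chose_internal),
                min(fu$p_correct), max(fu$p_correct)))
message("wrote results/trials_*.tsv, results/followup_*.tsv")
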