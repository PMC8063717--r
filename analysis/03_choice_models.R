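#!/usr/bin/env Rscript
# Logistic models of the metacognitive choice and of second-stage
# performance: the 20-predictor lagged model (current probabilities, three
# previous encounters of each task type with outcome-by-probability
# interactions) and the single-predictor decision-variable model.

suppressPackageStartupMessages(library(prospectmeta))

log <- read_session_log("results/trials_baseline.tsv")
fu <- read_followup_table("results/followup_table_baseline.tsv")

choice <- fit_lagged_model(log, "choice")
perf_int <- fit_lagged_model(log, "performance", side = "internal")
dv <- fit_dv_model(log, fu)

message(sprintf("choice model: beta_internal = %+.2f, beta_external = %+.2f",
                choice$coefficients[["x_int"]], choice$coefficients[["x_ext"]]))
message(sprintf("internal performance model: beta_internal = %+.2f, beta_external = %+.2f",
                perf_int$coefficients[["x_int"]], perf_int$coefficients[["x_ext"]]))
message("the positive external coefficient in the performance model is the")
message("selection effect: internal options kept despite good external offers")
message("are ones the observer sensed it could perform.")
message(sprintf("decision-variable model slope = %+.2f", dv$coefficients[["dv"]]))

tab <- data.frame(term = names(choice$coefficients),
                  choice = round(choice$coefficients, 4),
                  choice_se = round(choice$se, 4),
                  performance_internal = round(perf_int$coefficients, 4))
write.table(tab, "results/choice_models.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
message("wrote results/choice_models.tsv")
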