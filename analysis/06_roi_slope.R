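#!/usr/bin/env Rscript
# ROI beta-timecourse analysis on synthetic timecourses: per-timepoint
# regression of the signal on the chosen- and unchosen-internal-probability
# regressors, slope and magnitude extraction, and the chosen-minus-unchosen
# contrast across sessions.

suppressPackageStartupMessages(library(prospectmeta))
dir.create("results", showWarnings = FALSE)

set.seed(2026)
n_sessions <- 10
bts <- lapply(seq_len(n_sessions), function(i) {
  ev <- simulate_roi_events(195)
  tc <- simulate_roi_timecourse(ev) # faster ramp for chosen, matched peaks
  if (i == 1) write_roi_timecourse(tc, "results/roi_timecourse_example.tsv",
                                   "results/roi_events_example.tsv")
  beta_timecourse(tc)
})
r <- chosen_unchosen_slope_contrast(bts)

message(sprintf("mean slope: chosen %.3f /s, unchosen %.3f /s (contrast %+.3f /s)",
                r$slope_chosen, r$slope_unchosen, r$slope_contrast))
message(sprintf("peak contrast %+.3f (matched peaks by construction)", r$peak_contrast))
message("the slope statistic isolates accumulation speed: it separates the")
message("conditions even though their peak signals are indistinguishable.")

write.table(round(r$per_session, 4), "results/roi_slope_per_session.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
bt <- bts[[1]]
write.table(data.frame(time_s = round(bt$time, 4),
                       beta_chosen = round(bt$beta_chosen, 5),
                       beta_unchosen = round(bt$beta_unchosen, 5)),
            "results/roi_beta_timecourse_example.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/roi_slope_per_session.tsv and example timecourses")
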