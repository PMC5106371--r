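#!/usr/bin/env Rscript
# Step 2: event streams -> labelled inter-movement intervals -> frequency
# statistics.
#
# Converts each fixture stream to pre/stim-labelled intervals (straddling
# intervals discarded, counts logged), then computes per-cell instantaneous
# frequency (1/interval) with SEM, the omnibus OLS ANOVA, and post hoc
# Bonferroni-adjusted pre-vs-stim t tests. Writes the frequency report and a
# violin figure in the style standard for this analysis.

suppressPackageStartupMessages(library(laterace))

fix_dir <- "results/fixtures"
if (!dir.exists(fix_dir)) stop("run analysis/01_simulate.R first")

# treat the swivel fixture as the stimulated manual effector and the null
# fixture as an unstimulated vocal effector of the same synthetic patient:
# the effector-specific design of the experiment
manual <- read_event_stream(file.path(fix_dir, "swivel.csv"))
vocal <- read_event_stream(file.path(fix_dir, "null.csv"))
vocal$effector <- "vocal"

d_manual <- events_to_intervals(manual)
d_vocal <- events_to_intervals(vocal)
for (d in list(d_manual, d_vocal)) {
  log <- attr(d, "discard_log")
  cat(sprintf("%s/%s: %d pre, %d stim, %d discarded of %d pairs\n",
              d$patient[1], d$effector[1], log$n_pre, log$n_stim,
              log$n_discarded, log$n_pairs))
}

both <- bind_intervals(d_manual, d_vocal)
report <- frequency_stats(both)
print(report)

dir.create("results", showWarnings = FALSE)
frequency_report_to_json(report, "results/frequency_report.json")
plot_frequency_violins(both, file = "results/frequency_violins.png")
cat("\nWrote results/frequency_report.json and results/frequency_violins.png\n")
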