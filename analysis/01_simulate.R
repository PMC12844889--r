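#!/usr/bin/env Rscript
# Simulate a small synthetic cohort: two conditions ("vehicle" and a
# "quiet" condition with longer rests and stronger shared drive, the
# direction of an mGluR5 negative modulator), four animals each, one
# session per animal.  Sessions are written in the documented CSV layout
# under results/sessions/<condition>_<animal>/.

suppressPackageStartupMessages(library(minicoact))

out_root <- "results/sessions"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

cohort <- list()
for (a in 1:4) {
  cohort[[sprintf("vehicle_m%02d", a)]] <-
    sim_config(duration = 900, seed = 100 + a)
  cohort[[sprintf("quiet_m%02d", a)]] <-
    sim_config(duration = 900, seed = 200 + a,
               rest_mean_length = 20, bout_mean_length = 4,
               rest_shared_drive = 0.22)
}

for (name in names(cohort)) {
  dir <- file.path(out_root, name)
  sim <- simulate_session(cohort[[name]])
  write_session(sim, dir)
  cat(sprintf("%-14s  %3d cells  %4.0f s  %5d ground-truth events\n",
              name, cohort[[name]]$n_cells, cohort[[name]]$duration,
              sum(lengths(sim$ground_truth$event_times))))
}
cat("sessions written to", out_root, "\n")
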