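#!/usr/bin/env Rscript
# Behavioral segmentation per session: calibrated velocity, 1 s median
# filter, 5 Hz downsampling, rest/movement epochs (0.5 cm/s threshold),
# bouts, and rule-based movement onsets.  Writes epochs.json per session
# and a cohort behavior table.

suppressPackageStartupMessages(library(minicoact))

sessions <- list.dirs("results/sessions", recursive = FALSE)
rows <- list()
for (dir in sessions) {
  loaded <- load_session(dir)
  grid <- align_streams(loaded$session, loaded$tracking)
  raw <- compute_velocity(loaded$tracking)
  loco <- filter_velocity(raw, loaded$tracking, grid)
  ep <- classify_epochs(loco)
  on <- detect_onsets(loaded$tracking)
  jsonlite::write_json(
    list(intervals = ep$intervals, bouts = ep$bouts,
         onsets_s = on$onsets_s,
         fraction_rest = ep$fraction_rest,
         n_bouts = ep$n_bouts, mean_bout_length = ep$mean_bout_length),
    file.path(dir, "epochs.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.frame(time_s = loco$time,
                                velocity = loco$velocity,
                                valid = loco$valid),
                     file.path(dir, "velocity_5hz.csv"))
  rows[[basename(dir)]] <- data.frame(
    session = basename(dir),
    mean_velocity = mean(loco$velocity[loco$valid]),
    fraction_rest = ep$fraction_rest, n_bouts = ep$n_bouts,
    mean_bout_length = ep$mean_bout_length,
    n_onsets = length(on$onsets_s))
  cat(sprintf(
    "%-30s rest %.2f  bouts %3d  mean bout %5.2f s  onsets %3d\n",
    basename(dir), ep$fraction_rest, ep$n_bouts, ep$mean_bout_length,
    length(on$onsets_s)))
}
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(do.call(rbind, rows), "results/tables/behavior.csv")
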