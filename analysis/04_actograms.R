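#!/usr/bin/env Rscript
# Double-plotted actogram matrices (15-min bins, two cycles per row) for one
# representative animal per phenotype, with the light/dark annotation track.
# Written as plain CSV so any plotting front end can render the heatmap.

library(actirhythm)

t0 <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC")
sched <- dd_protocol_schedule(t0, acclimation_days = 3, baseline_days = 3,
                              dd_days = 14, resync_days = 3)
streams <- read_events("results/simulated/events.csv")

dir.create("results", showWarnings = FALSE)
for (id in c("control_01", "dex_01", "mehg_01")) {
  b <- bin_events(streams[[id]], sched, sched$start, sched$end, epoch_seconds = 300)
  mat <- export_actogram(b, sched, bin_minutes = 15)
  write.csv(mat, sprintf("results/actogram_%s.csv", id), row.names = TRUE)
  write.csv(attr(mat, "light"), sprintf("results/actogram_%s_light.csv", id),
            row.names = FALSE)
  cat(sprintf("%s: %d double-plotted rows x %d bins\n", id, nrow(mat), ncol(mat)))
}
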