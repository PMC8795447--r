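#!/usr/bin/env Rscript
# Reduce every plate written by 01_simulate.R to delta net BRET fold changes
# and the reference-normalized baseline/stimulated bar values.

suppressPackageStartupMessages({library(grkselect); library(dplyr)})

inp <- "results/inputs"
out <- "results/reduced"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plate_files <- list.files(inp, pattern = "^plate_.*\\.csv$", full.names = TRUE)
reduced <- bind_rows(lapply(plate_files, function(f) {
  red <- reduce_plate(read_plate_csv(f))
  red$pair <- sub("^plate_(.*)\\.csv$", "\\1", basename(f))
  red
}))
readr::write_tsv(reduced, file.path(out, "net_fold_changes.tsv"))

bars <- bind_rows(lapply(split(reduced, reduced$pair), function(red) {
  b <- baseline_bars(red, grk_conditions()[["reference"]])
  b$summary$pair <- red$pair[1]
  b$summary
}))
readr::write_tsv(bars, file.path(out, "baseline_bars.tsv"))

sat <- reduced |>
  filter(role == "sample") |>
  group_by(pair, condition) |>
  filter(concentration_M == max(concentration_M)) |>
  summarise(mean_net_fold = mean(net_fold_change),
            sem_net_fold = sem(net_fold_change), .groups = "drop")
message("saturating-concentration net fold changes (mean +- SEM):")
for (i in seq_len(nrow(sat))) {
  message(sprintf("  %-28s %-14s %.3f +- %.3f", sat$pair[i], sat$condition[i],
                  sat$mean_net_fold[i], sat$sem_net_fold[i]))
}
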