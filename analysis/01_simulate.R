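#!/usr/bin/env Rscript
# Simulate the synthetic study inputs: one BRET plate per GPCR-arrestin pair
# of the demonstration screen, a receptor-segment set with planted PXPP
# motifs, and DMR traces. Everything downstream (02-06) consumes only the
# files written here.

suppressPackageStartupMessages(library(grkselect))

seed <- 1L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plates <- demo_screen_plates(seed)
for (pair in names(plates)) {
  write_plate_csv(plates[[pair]],
                  file.path(out, paste0("plate_", gsub("/", "-", pair), ".csv")))
}
message("wrote ", length(plates), " plates (",
        paste(names(plates), collapse = ", "), ")")

segments <- simulate_segment_set(
  groups = c("GRK2/3", "GRK2/3/5/6"), n_per_group = 20,
  placement = c("GRK2/3" = "central", "GRK2/3/5/6" = "peripheral"),
  receptor_class = c("GRK2/3" = "A", "GRK2/3/5/6" = "B"),
  seed = seed
)
write_segments_fasta(segments, file.path(out, "segments_synthetic.fasta"))
jsonlite::write_json(attr(segments, "truth"),
                     file.path(out, "segment_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", nrow(segments), " synthetic segments with planted PXPP motifs")

dmr <- simulate_dmr_traces(10^seq(-10, -6, by = 0.5), top_pm = 300,
                           log_ec50 = -8, noise_cv = 0.05, seed = seed)
readr::write_csv(dmr, file.path(out, "dmr_traces.csv"))
message("wrote DMR traces for ", length(unique(dmr$concentration_M[dmr$role == "sample"])),
        " concentrations (planted log EC50 = -8)")
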