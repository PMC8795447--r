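#!/usr/bin/env Rscript
# Gate every pair x condition for functional recruitment and fit
# concentration-response curves (per-experiment three-parameter logistic,
# Hill slope 1) to the gated conditions.

suppressPackageStartupMessages({library(grkselect); library(dplyr)})

reduced <- readr::read_tsv("results/reduced/net_fold_changes.tsv",
                           show_col_types = FALSE)
out <- "results/fits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fits <- bind_rows(lapply(split(reduced, list(reduced$pair, reduced$condition),
                               drop = TRUE), function(sub) {
  gate <- gate_functional_recruitment(
    sub$net_fold_change[sub$concentration_M == max(sub$concentration_M)],
    sub$net_fold_change[sub$role == "vehicle"]
  )
  series <- tibble::tibble(concentration_M = sub$concentration_M,
                           replicate = sub$replicate,
                           response = sub$net_fold_change)
  fit <- fit_concentration_response(series, gate = gate)
  fit$pair <- sub$pair[1]
  fit$condition <- sub$condition[1]
  fit$gate_p <- gate$p_value
  fit
}))
readr::write_tsv(fits, file.path(out, "concentration_response_fits.tsv"))
jsonlite::write_json(fits, file.path(out, "concentration_response_fits.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

fun <- fits |> filter(functional)
message(sum(!fits$functional), " of ", nrow(fits),
        " pair x condition series gated out as non-functional")
message("fitted log EC50 (mean over experiments +- SEM) for functional conditions:")
for (i in seq_len(nrow(fun))) {
  message(sprintf("  %-28s %-14s %.2f +- %.2f", fun$pair[i], fun$condition[i],
                  fun$log_ec50[i], fun$log_ec50_sem[i]))
}
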