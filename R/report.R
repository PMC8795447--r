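#' Ground truths of the bundled demonstration screen
#'
#' Four synthetic GPCR-arrestin pairs covering the phenotypes the selectivity
#' screen distinguishes: a pair recruited through any GRK
#' (`GRK2/3/5/6-regulated`), a pair recruited through the GRK2/3 family only,
#' a GRK-independent pair (`unclassified`) and a pre-coupled pair whose
#' baseline is elevated and whose dynamic response is dampened.
#'
#' @param noise_cv well noise CV.
#' @return named list: per pair, a named list of [condition_truth()] objects
#'   for the six standard conditions.
#' @export
demo_screen_truths <- function(noise_cv = 0.05) {
  conds <- grk_conditions()
  make <- function(tops, pre = setNames(rep(1, 6), names(conds)),
                   top_on = "baseline") {
    truths <- lapply(names(conds), function(nm) {
      condition_truth(top_fold = tops[[nm]], precoupling_factor = pre[[nm]],
                      noise_cv = noise_cv, log_ec50 = -7, top_on = top_on)
    })
    stats::setNames(truths, unname(conds))
  }
  ones <- stats::setNames(rep(1, 6), names(conds))
  list(
    "PTH1R-barr2" = make(c(control = 1.6, reference = 1, GRK2 = 1.5,
                           GRK3 = 1.5, GRK5 = 1.5, GRK6 = 1.5)),
    "M5R-barr2" = make(c(control = 1.6, reference = 1, GRK2 = 1.5,
                         GRK3 = 1.5, GRK5 = 1, GRK6 = 1)),
    "M3R-barr1" = make(c(control = 1.3, reference = 1, GRK2 = 1, GRK3 = 1,
                         GRK5 = 1, GRK6 = 1)),
    "V2R-barr2" = make(c(control = 1.6, reference = 1, GRK2 = 1.5,
                         GRK3 = 1.5, GRK5 = 1.5, GRK6 = 1.5),
                       pre = c(control = 1.3, reference = 1, GRK2 = 1.5,
                               GRK3 = 1.5, GRK5 = 1.5, GRK6 = 1.5),
                       top_on = "basal")
  )
}

#' Simulate the demonstration screen
#'
#' One synthetic plate per pair of [demo_screen_truths()], under a single
#' master seed.
#'
#' @param seed integer master seed.
#' @param concentrations ligand concentrations in mol/L.
#' @param n_replicates independent experiments per condition.
#' @param noise_cv well noise CV.
#' @return named list of plate tibbles.
#' @export
demo_screen_plates <- function(seed,
                               concentrations = 10^seq(-10, -4),
                               n_replicates = 3L,
                               noise_cv = 0.05) {
  truths <- demo_screen_truths(noise_cv = noise_cv)
  design <- assay_design(unname(grk_conditions()),
                         concentrations = concentrations,
                         n_replicates = n_replicates)
  plates <- list()
  for (i in seq_along(truths)) {
    pair <- names(truths)[i]
    d <- design
    d$conditions$receptor <- sub("-.*", "", pair)
    d$conditions$arrestin <- sub(".*-", "", pair)
    d$conditions$grk_label <- names(grk_conditions())
    plates[[pair]] <- simulate_bret_plate(d, truths[[pair]],
                                          seed = seed + i)
  }
  plates
}

#' Run the full analysis chain on the demonstration screen
#'
#' Chains simulate, reduce, gate + fit, classify and pre-coupling detection
#' on the bundled synthetic screen and writes one artifact bundle under
#' `out_dir`: `reduced.tsv`, `fits.json`, `comparisons.tsv`, `heatmap.tsv`,
#' `dendrogram.nwk`, `calls.json`, `precoupling.tsv` and `run_log.json`
#' (seed, effective configuration, versions). All randomness flows from
#' `seed`; repeated runs with the same seed produce byte-identical files.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if absent).
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_report <- function(seed, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plates <- demo_screen_plates(seed)

  reduced_all <- list()
  fits <- list()
  matrix_rows <- list()
  precoup <- list()
  for (pair in names(plates)) {
    red <- reduce_plate(plates[[pair]], mock_mode = config$mock_mode,
                        baseline_duration = config$baseline_duration,
                        stim_duration = config$stim_duration)
    red$pair <- pair
    reduced_all[[pair]] <- red
    for (cond in unique(red$condition)) {
      sub <- red[red$condition == cond, ]
      top_c <- max(sub$concentration_M)
      gate <- gate_functional_recruitment(
        sub$net_fold_change[sub$concentration_M == top_c],
        sub$net_fold_change[sub$role == "vehicle"],
        alpha = config$alpha
      )
      series <- tibble::tibble(concentration_M = sub$concentration_M,
                               replicate = sub$replicate,
                               response = sub$net_fold_change)
      fit <- fit_concentration_response(series, mode = config$fit_mode,
                                        hill = config$hill,
                                        hill_value = config$hill_value,
                                        gate = gate)
      fits[[paste(pair, cond, sep = " | ")]] <- c(
        list(pair = pair, condition = cond,
             functional = gate$is_functional, gate_p = gate$p_value),
        as.list(fit)
      )
    }
    sat <- red[red$role == "sample", ]
    sat <- sat[sat$concentration_M == max(sat$concentration_M), ]
    matrix_rows[[pair]] <- tibble::tibble(pair = pair,
                                          condition = sat$condition,
                                          replicate = sat$replicate,
                                          value = sat$net_fold_change)
    bars <- baseline_bars(red, grk_conditions()[["reference"]])
    pc <- call_precoupling(bars$replicates, grk_conditions()[["reference"]],
                           alpha = config$alpha)
    pc$pair <- pair
    precoup[[pair]] <- pc
  }
  reduced <- dplyr::bind_rows(reduced_all)
  cond_matrix <- dplyr::bind_rows(matrix_rows)
  classification <- classify_pairs(cond_matrix, alpha = config$alpha,
                                   linkage = config$linkage,
                                   cap = config$heatmap_cap)
  precoupling <- dplyr::bind_rows(precoup)

  readr::write_tsv(reduced, file.path(out_dir, "reduced.tsv"))
  jsonlite::write_json(unname(fits), file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(classification$comparisons,
                   file.path(out_dir, "comparisons.tsv"))
  heat <- tibble::as_tibble(classification$heatmap, rownames = "pair")
  readr::write_tsv(heat, file.path(out_dir, "heatmap.tsv"))
  writeLines(classification$clustering$newick,
             file.path(out_dir, "dendrogram.nwk"))
  jsonlite::write_json(classification$calls, file.path(out_dir, "calls.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(precoupling, file.path(out_dir, "precoupling.tsv"))
  jsonlite::write_json(
    list(seed = seed, config = config,
         versions = list(grkselect = as.character(utils::packageVersion("grkselect")),
                         R = R.version.string)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(list(reduced = reduced, fits = fits,
                 classification = classification,
                 precoupling = precoupling, out_dir = out_dir))
}
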