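#' Simulate dynamic mass redistribution (DMR) traces
#'
#' Generates label-free DMR wavelength-shift traces (picometres) for a ligand
#' concentration series: per concentration, `n_replicates` technical-replicate
#' sample traces rising mono-exponentially to a Hill-shaped plateau, plus
#' matched empty-vector reference traces used for correction. Deterministic
#' for a fixed seed.
#'
#' @param concentrations ligand concentrations in mol/L (> 0).
#' @param top_pm maximal plateau shift in pm.
#' @param log_ec50 log10 EC50 in mol/L.
#' @param hill_slope Hill coefficient.
#' @param tau rise time constant in seconds.
#' @param ev_plateau_pm plateau of the empty-vector (reference) response.
#' @param noise_cv multiplicative log-normal noise CV per trace point.
#' @param duration trace length in seconds; must cover the 0-1800 s AUC
#'   window.
#' @param interval sampling interval in seconds.
#' @param n_replicates technical replicates per concentration.
#' @param seed integer seed.
#' @return tibble with columns `role` (`"sample"`/`"reference"`),
#'   `concentration_M`, `replicate`, `time_s`, `shift_pm`; attribute `truth`
#'   holds the generating parameters.
#' @export
simulate_dmr_traces <- function(concentrations,
                                top_pm = 300,
                                log_ec50 = -8,
                                hill_slope = 1,
                                tau = 300,
                                ev_plateau_pm = 40,
                                noise_cv = 0.05,
                                duration = 3600,
                                interval = 15,
                                n_replicates = 3L,
                                seed = 1L) {
  if (duration < 1800) {
    stop_config("trace duration must cover the 0-1800 s AUC window")
  }
  if (any(concentrations <= 0)) stop_config("concentrations must be > 0")
  time_s <- seq(0, duration, by = interval)
  rise <- 1 - exp(-time_s / tau)

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    rows <- list()
    for (conc in sort(concentrations)) {
      plateau <- ev_plateau_pm +
        top_pm * hill_occupancy(conc, log_ec50, hill_slope)
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          role = "sample", concentration_M = conc, replicate = r,
          time_s = time_s,
          shift_pm = plateau * rise * lnoise(length(time_s), noise_cv)
        )
      }
    }
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        role = "reference", concentration_M = 0, replicate = r,
        time_s = time_s,
        shift_pm = ev_plateau_pm * rise * lnoise(length(time_s), noise_cv)
      )
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(top_pm = top_pm, log_ec50 = log_ec50,
                               hill_slope = hill_slope, tau = tau,
                               ev_plateau_pm = ev_plateau_pm)
    out
  })
}
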