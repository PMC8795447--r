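#' Describe a BRET plate layout
#'
#' An assay design holds the plate-level structure of a GRK-selective
#' recruitment experiment: which genotype/transfection conditions are present,
#' the ligand concentration series, the replicate count (independent
#' experiments) and the acquisition windows. The defaults mirror the standard
#' protocol: a 3-min baseline read, ligand addition, then 5 min of
#' post-stimulation reads.
#'
#' @param conditions character vector of condition labels (e.g.
#'   `"Control+EV"`, `"dQ-GRK+GRK2"`), or a data frame with columns
#'   `condition` and optionally `receptor`, `arrestin`, `grk_label`.
#' @param concentrations numeric ligand concentrations in mol/L, strictly
#'   increasing; a leading 0 (vehicle) is allowed and is generated anyway.
#' @param n_replicates number of independent experiments per condition.
#' @param baseline_duration,stim_duration acquisition windows in seconds.
#' @param sampling_interval seconds between reads.
#' @param include_mock generate matched mock-labelling wells (no acceptor
#'   label) for every condition x replicate.
#' @param n_mock_wells mock wells per condition x replicate.
#' @return an `assay_design` list.
#' @export
assay_design <- function(conditions,
                         concentrations,
                         n_replicates = 3L,
                         baseline_duration = 180,
                         stim_duration = 300,
                         sampling_interval = 10,
                         include_mock = TRUE,
                         n_mock_wells = 2L) {
  if (is.character(conditions)) {
    conditions <- tibble::tibble(condition = conditions)
  }
  conditions <- tibble::as_tibble(conditions)
  if (!"condition" %in% names(conditions) || nrow(conditions) == 0L) {
    stop_config("`conditions` must provide at least one `condition` label")
  }
  for (col in c("receptor", "arrestin", "grk_label")) {
    if (!col %in% names(conditions)) conditions[[col]] <- NA_character_
  }
  if (baseline_duration <= 0 || stim_duration <= 0 || sampling_interval <= 0) {
    stop_config("durations and sampling interval must be positive")
  }
  if (n_replicates < 1L) stop_config("`n_replicates` must be >= 1")
  concentrations <- sort(unique(as.numeric(concentrations)))
  if (any(concentrations < 0)) stop_config("concentrations must be non-negative")
  doses <- concentrations[concentrations > 0]
  if (length(doses) == 0L) stop_config("at least one non-zero concentration is required")
  structure(
    list(
      conditions = conditions,
      concentrations = doses,
      n_replicates = as.integer(n_replicates),
      baseline_duration = baseline_duration,
      stim_duration = stim_duration,
      sampling_interval = sampling_interval,
      include_mock = isTRUE(include_mock),
      n_mock_wells = as.integer(n_mock_wells)
    ),
    class = "assay_design"
  )
}

#' Ground truth for one synthetic condition
#'
#' Parameterizes the generative model behind one condition of a synthetic BRET
#' plate. The measured acceptor/donor ratio is modelled as acceptor
#' bleed-through (`mock_ratio`) plus a label-specific signal whose baseline is
#' `(basal_ratio - mock_ratio) * precoupling_factor` and whose stimulated
#' plateau follows a Hill occupancy curve, approached mono-exponentially with
#' time constant `response_tau` after ligand addition.
#'
#' @param basal_ratio total basal acceptor/donor ratio (must exceed
#'   `mock_ratio`).
#' @param precoupling_factor multiplicative, ligand-independent elevation of
#'   the baseline specific signal (>= 1; 1 = no pre-coupling).
#' @param top_fold maximal stimulated/baseline fold change (>= 1).
#' @param log_ec50 log10 of the EC50 in mol/L.
#' @param hill_slope Hill coefficient.
#' @param mock_ratio acceptor/donor ratio of mock-labelled wells
#'   (bleed-through without acceptor label).
#' @param noise_cv coefficient of variation of multiplicative log-normal well
#'   noise, applied independently to donor and acceptor channels.
#' @param response_tau seconds; 0 gives an instantaneous step to plateau.
#' @param top_on `"baseline"` anchors the stimulated plateau on the
#'   (possibly pre-coupling-elevated) baseline, so the fold change equals
#'   `top_fold` regardless of pre-coupling; `"basal"` anchors it on the
#'   non-pre-coupled basal signal, so pre-coupling dampens the dynamic fold
#'   change (the V2R/AT1R phenomenology).
#' @return a `condition_truth` list.
#' @export
condition_truth <- function(basal_ratio = 0.5,
                            precoupling_factor = 1,
                            top_fold = 1.5,
                            log_ec50 = -7,
                            hill_slope = 1,
                            mock_ratio = 0.1,
                            noise_cv = 0.05,
                            response_tau = 30,
                            top_on = c("baseline", "basal")) {
  top_on <- match.arg(top_on)
  if (!(basal_ratio > mock_ratio) || mock_ratio < 0) {
    stop_config("`basal_ratio` must exceed `mock_ratio` and `mock_ratio` must be >= 0")
  }
  if (top_fold < 1) stop_config("`top_fold` must be >= 1")
  if (precoupling_factor < 1) stop_config("`precoupling_factor` must be >= 1")
  if (noise_cv < 0) stop_config("`noise_cv` must be >= 0")
  if (response_tau < 0) stop_config("`response_tau` must be >= 0")
  structure(
    list(
      basal_ratio = basal_ratio, precoupling_factor = precoupling_factor,
      top_fold = top_fold, log_ec50 = log_ec50, hill_slope = hill_slope,
      mock_ratio = mock_ratio, noise_cv = noise_cv,
      response_tau = response_tau, top_on = top_on
    ),
    class = "condition_truth"
  )
}

# fractional receptor occupancy at concentration c (mol/L)
hill_occupancy <- function(c, log_ec50, hill_slope = 1) {
  ifelse(c <= 0, 0,
         1 / (1 + 10^((log_ec50 - log10(c)) * hill_slope)))
}

# multiplicative log-normal noise with mean exactly 1 and CV = cv
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a BRET plate with known ground truth
#'
#' Generates a long-format plate table of dual-channel well time series for
#' every condition x concentration x replicate of `design`, plus one vehicle
#' well (concentration 0) and, if requested, matched mock-labelling wells per
#' condition x replicate. Deterministic for a fixed seed (wells are generated
#' in a fixed order from a single RNG stream).
#'
#' @param design an [assay_design()].
#' @param truths named list of [condition_truth()] objects, one per condition
#'   label in the design.
#' @param seed integer seed.
#' @param donor_level expected donor intensity in counts.
#' @return a tibble with columns `well_id, condition, receptor, arrestin,
#'   grk_label, role, concentration_M, replicate, time_s, donor, acceptor` and
#'   attributes `stimulation_time_s`, `baseline_duration_s`, `stim_duration_s`
#'   and `truths`.
#' @export
simulate_bret_plate <- function(design, truths, seed, donor_level = 5e5) {
  stopifnot(inherits(design, "assay_design"))
  missing <- setdiff(design$conditions$condition, names(truths))
  if (length(missing) > 0L) {
    stop_config(paste0("no ground truth supplied for condition(s): ",
                       paste(missing, collapse = ", ")))
  }
  t_stim <- design$baseline_duration
  time_s <- seq(0, design$baseline_duration + design$stim_duration,
                by = design$sampling_interval)
  nt <- length(time_s)
  post <- pmax(time_s - t_stim, 0)

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    rows <- list()
    widx <- 0L
    for (ci in seq_len(nrow(design$conditions))) {
      cond <- design$conditions[ci, ]
      tr <- truths[[cond$condition]]
      stopifnot(inherits(tr, "condition_truth"))
      s_basal <- (tr$basal_ratio - tr$mock_ratio)        # specific basal signal
      s0 <- s_basal * tr$precoupling_factor              # (pre-coupled) baseline
      anchor <- if (tr$top_on == "baseline") s0 else s_basal
      for (rep_i in seq_len(design$n_replicates)) {
        concs <- c(0, design$concentrations)             # vehicle first
        for (conc in concs) {
          occ <- hill_occupancy(conc, tr$log_ec50, tr$hill_slope)
          plateau <- s0 + anchor * (tr$top_fold - 1) * occ
          kin <- if (tr$response_tau == 0) as.numeric(post > 0) else
            1 - exp(-post / tr$response_tau)
          kin[post == 0] <- 0
          specific <- s0 + (plateau - s0) * kin
          ratio_true <- tr$mock_ratio + specific
          donor <- donor_level * lnoise(nt, tr$noise_cv)
          acceptor <- donor * ratio_true * lnoise(nt, tr$noise_cv)
          widx <- widx + 1L
          rows[[widx]] <- tibble::tibble(
            well_id = sprintf("W%04d", widx),
            condition = cond$condition,
            receptor = cond$receptor, arrestin = cond$arrestin,
            grk_label = cond$grk_label,
            role = if (conc == 0) "vehicle" else "sample",
            concentration_M = conc, replicate = rep_i,
            time_s = time_s, donor = donor, acceptor = acceptor
          )
        }
        if (design$include_mock) {
          for (m in seq_len(design$n_mock_wells)) {
            donor <- donor_level * lnoise(nt, tr$noise_cv)
            acceptor <- donor * tr$mock_ratio * lnoise(nt, tr$noise_cv)
            widx <- widx + 1L
            rows[[widx]] <- tibble::tibble(
              well_id = sprintf("W%04d", widx),
              condition = cond$condition,
              receptor = cond$receptor, arrestin = cond$arrestin,
              grk_label = cond$grk_label,
              role = "mock", concentration_M = 0, replicate = rep_i,
              time_s = time_s, donor = donor, acceptor = acceptor
            )
          }
        }
      }
    }
    plate <- dplyr::bind_rows(rows)
    attr(plate, "stimulation_time_s") <- t_stim
    attr(plate, "baseline_duration_s") <- design$baseline_duration
    attr(plate, "stim_duration_s") <- design$stim_duration
    attr(plate, "truths") <- truths
    plate
  })
}
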