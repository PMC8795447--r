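#' Per-timepoint BRET ratio
#'
#' @param donor,acceptor numeric intensity series of equal length; donor must
#'   be strictly positive.
#' @param well_id optional label used in error messages.
#' @return numeric ratio series `acceptor / donor`.
#' @export
bret_ratio <- function(donor, acceptor, well_id = NULL) {
  if (length(donor) != length(acceptor)) {
    stop_data("donor and acceptor series differ in length")
  }
  if (any(!is.finite(donor)) || any(donor <= 0)) {
    stop_data(paste0("non-positive donor signal",
                     if (!is.null(well_id)) paste0(" in well ", well_id)))
  }
  acceptor / donor
}

#' Correct a ratio series for labelling efficiency with mock wells
#'
#' Subtracts the mock-labelling signal (acceptor bleed-through without
#' acceptor label) from a sample ratio series. By default the per-timepoint
#' mean across mock wells is subtracted; `mode = "scalar"` subtracts one
#' scalar, the grand mean of all mock ratios.
#'
#' @param sample_ratio numeric ratio series.
#' @param mock_ratios list of mock ratio series (or a single numeric series),
#'   all on the same time base as `sample_ratio`.
#' @param mode `"per_timepoint"` (default) or `"scalar"`.
#' @return corrected ratio series.
#' @export
mock_correct <- function(sample_ratio, mock_ratios,
                         mode = c("per_timepoint", "scalar")) {
  mode <- match.arg(mode)
  if (is.numeric(mock_ratios)) mock_ratios <- list(mock_ratios)
  if (length(mock_ratios) == 0L) {
    stop_config("mock correction requires at least one mock well")
  }
  n <- length(sample_ratio)
  if (any(vapply(mock_ratios, length, 1L) != n)) {
    stop_data("mock wells are not on the sample's time base")
  }
  mock_mat <- do.call(rbind, mock_ratios)
  if (mode == "per_timepoint") {
    sample_ratio - colMeans(mock_mat)
  } else {
    sample_ratio - mean(mock_mat)
  }
}

#' Baseline and stimulated window means of a corrected ratio series
#'
#' Averages the corrected ratio over the baseline window
#' `[stimulation_time - baseline_duration, stimulation_time)` and the
#' stimulated window `(stimulation_time, stimulation_time + stim_duration]`;
#' the reading at `stimulation_time` itself is excluded from both windows
#' (injection artefact). The fold change is the stimulated mean divided by
#' the baseline mean.
#'
#' @param time_s numeric time vector (seconds), increasing.
#' @param corrected corrected ratio series, same length.
#' @param stimulation_time ligand-addition time in seconds.
#' @param baseline_duration,stim_duration window lengths in seconds.
#' @return list with `baseline_mean`, `stimulated_mean`, `fold_change`.
#' @export
window_means <- function(time_s, corrected, stimulation_time,
                         baseline_duration = 180, stim_duration = 300) {
  if (length(time_s) != length(corrected)) {
    stop_data("time and ratio series differ in length")
  }
  in_base <- time_s >= stimulation_time - baseline_duration &
    time_s < stimulation_time
  in_stim <- time_s > stimulation_time &
    time_s <= stimulation_time + stim_duration
  if (sum(in_base) < 2L || sum(in_stim) < 2L) {
    stop_data("fewer than 2 readings in the baseline or stimulated window")
  }
  baseline_mean <- mean(corrected[in_base])
  stimulated_mean <- mean(corrected[in_stim])
  if (!is.finite(baseline_mean) || baseline_mean <= 0) {
    stop_data("degenerate well: corrected baseline mean is not positive")
  }
  list(baseline_mean = baseline_mean, stimulated_mean = stimulated_mean,
       fold_change = stimulated_mean / baseline_mean)
}

#' Vehicle-normalized (delta net) BRET fold change
#'
#' Divides a sample well's fold change by the mean fold change of the matched
#' vehicle wells of the same condition and experiment, yielding the dynamic
#' delta net BRET fold change (a vehicle well normalized against its own set
#' gives exactly 1).
#'
#' @param sample_fold scalar fold change (or the list from [window_means()]).
#' @param vehicle_folds numeric vector of vehicle fold changes.
#' @return scalar delta net BRET fold change.
#' @export
net_fold_change <- function(sample_fold, vehicle_folds) {
  if (is.list(sample_fold)) sample_fold <- sample_fold$fold_change
  if (length(vehicle_folds) == 0L) {
    stop_config("vehicle normalization requires at least one vehicle well")
  }
  v <- mean(vehicle_folds)
  if (!is.finite(v) || v <= 0) stop_data("vehicle mean fold change is not positive")
  sample_fold / v
}

#' Delta net BRET change in per cent
#'
#' @param net delta net BRET fold change(s).
#' @return `(net - 1) * 100`.
#' @export
percent_change <- function(net) (net - 1) * 100

#' Reduce a long-format BRET plate to delta net BRET fold changes
#'
#' Runs the full well-level reduction: acceptor/donor ratio, mock correction
#' (per condition x experiment), baseline/stimulated window means, fold
#' change, and vehicle normalization within the same condition and
#' experiment.
#'
#' @param plate long-format plate tibble as produced by
#'   [simulate_bret_plate()] or [read_plate_csv()] (columns `well_id,
#'   condition, role, concentration_M, replicate, time_s, donor, acceptor`;
#'   attribute or argument `stimulation_time_s`).
#' @param stimulation_time,baseline_duration,stim_duration seconds; taken
#'   from the plate attributes when `NULL`.
#' @param mock_mode passed to [mock_correct()].
#' @return tidy tibble, one row per sample/vehicle well, with
#'   `baseline_mean`, `stimulated_mean`, `fold_change`, `net_fold_change` and
#'   `pct_change`.
#' @export
reduce_plate <- function(plate, stimulation_time = NULL,
                         baseline_duration = NULL, stim_duration = NULL,
                         mock_mode = c("per_timepoint", "scalar")) {
  mock_mode <- match.arg(mock_mode)
  stimulation_time <- stimulation_time %||% attr(plate, "stimulation_time_s")
  baseline_duration <- baseline_duration %||%
    attr(plate, "baseline_duration_s") %||% 180
  stim_duration <- stim_duration %||% attr(plate, "stim_duration_s") %||% 300
  if (is.null(stimulation_time)) {
    stop_config("`stimulation_time` is neither given nor carried by the plate")
  }
  have_mock <- any(plate$role == "mock")

  sessions <- dplyr::distinct(plate, .data$condition, .data$replicate)
  out <- vector("list", nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    sess <- dplyr::filter(plate, .data$condition == sessions$condition[i],
                          .data$replicate == sessions$replicate[i])
    wells <- split(sess, sess$well_id)
    tref <- wells[[1]]$time_s
    for (w in wells) {
      if (!isTRUE(all.equal(w$time_s, tref))) {
        stop_data(paste0("wells of condition '", sessions$condition[i],
                         "', experiment ", sessions$replicate[i],
                         " are not on a common time base"))
      }
    }
    mock_series <- lapply(wells[vapply(wells, function(w) w$role[1] == "mock",
                                       TRUE)],
                          function(w) bret_ratio(w$donor, w$acceptor, w$well_id[1]))
    if (have_mock && length(mock_series) == 0L) {
      stop_config(paste0("no mock wells for condition '", sessions$condition[i],
                         "', experiment ", sessions$replicate[i]))
    }
    meas <- lapply(wells[vapply(wells, function(w) w$role[1] != "mock", TRUE)],
                   function(w) {
      ratio <- bret_ratio(w$donor, w$acceptor, w$well_id[1])
      corrected <- if (length(mock_series)) {
        mock_correct(ratio, mock_series, mode = mock_mode)
      } else ratio
      wm <- window_means(w$time_s, corrected, stimulation_time,
                         baseline_duration, stim_duration)
      tibble::tibble(
        well_id = w$well_id[1], condition = w$condition[1],
        receptor = w$receptor[1] %||% NA_character_,
        arrestin = w$arrestin[1] %||% NA_character_,
        grk_label = w$grk_label[1] %||% NA_character_,
        role = w$role[1], concentration_M = w$concentration_M[1],
        replicate = w$replicate[1],
        baseline_mean = wm$baseline_mean, stimulated_mean = wm$stimulated_mean,
        fold_change = wm$fold_change
      )
    })
    meas <- dplyr::bind_rows(meas)
    veh <- meas$fold_change[meas$role == "vehicle"]
    if (length(veh) == 0L) {
      stop_config(paste0("no vehicle wells for condition '",
                         sessions$condition[i], "', experiment ",
                         sessions$replicate[i]))
    }
    meas$net_fold_change <- vapply(meas$fold_change, net_fold_change, 1,
                                   vehicle_folds = veh)
    out[[i]] <- meas
  }
  out <- dplyr::bind_rows(out)
  out$pct_change <- percent_change(out$net_fold_change)
  out
}

#' Baseline and stimulated bars normalized to a reference condition
#'
#' For each condition, takes the baseline and stimulated window means at the
#' saturating (highest) ligand concentration and divides them by the mean
#' baseline of `reference_condition` (so the reference baseline maps to 1 by
#' construction). This is the representation used to detect ligand-
#' independent pre-coupling as an elevated baseline over the GRK-null
#' reference.
#'
#' @param reduced output of [reduce_plate()].
#' @param reference_condition condition label of the normalization reference
#'   (typically the GRK-null + empty-vector condition).
#' @return list with `replicates` (per condition x experiment normalized
#'   baseline/stimulated values) and `summary` (per condition mean and SEM).
#' @export
baseline_bars <- function(reduced, reference_condition) {
  if (!reference_condition %in% reduced$condition) {
    stop_config(paste0("reference condition '", reference_condition,
                       "' is absent"))
  }
  sat <- reduced |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::group_by(.data$condition) |>
    dplyr::filter(.data$concentration_M == max(.data$concentration_M)) |>
    dplyr::ungroup()
  ref_base <- mean(sat$baseline_mean[sat$condition == reference_condition])
  if (!is.finite(ref_base) || ref_base <= 0) {
    stop_data("reference baseline mean is not positive")
  }
  replicates <- sat |>
    dplyr::transmute(.data$condition, .data$replicate,
                     baseline_norm = .data$baseline_mean / ref_base,
                     stimulated_norm = .data$stimulated_mean / ref_base,
                     net_fold_change = .data$net_fold_change)
  summary <- replicates |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      baseline_mean = mean(.data$baseline_norm),
      baseline_sem = sem(.data$baseline_norm),
      stimulated_mean = mean(.data$stimulated_norm),
      stimulated_sem = sem(.data$stimulated_norm),
      .groups = "drop"
    )
  list(replicates = replicates, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
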