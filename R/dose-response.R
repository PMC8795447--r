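#' Gate a condition for functional recruitment
#'
#' A condition is only interpreted as functional beta-arrestin recruitment —
#' and only then passed on to concentration-response fitting — when the
#' response at the highest tested ligand concentration shows a significant
#' increase over vehicle addition. The default test is a one-sided two-sample
#' Student t-test (pooled variance), which holds its nominal size exactly at
#' the small replicate numbers typical of these experiments; a Welch variant
#' is available but is conservative at n = 3.
#'
#' @param top_dose replicate responses at the highest ligand concentration.
#' @param vehicle replicate vehicle responses.
#' @param alpha significance level.
#' @param var_equal pool the variances (Student, default) or not (Welch).
#' @return list with `is_functional`, `p_value`, `test_label`.
#' @export
gate_functional_recruitment <- function(top_dose, vehicle, alpha = 0.05,
                                        var_equal = TRUE) {
  if (length(top_dose) < 2L || length(vehicle) < 2L) {
    stop_data("gating requires at least 2 replicates per group")
  }
  if (stats::var(top_dose) == 0 && stats::var(vehicle) == 0) {
    d <- mean(top_dose) - mean(vehicle)
    p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
  } else {
    p <- stats::t.test(top_dose, vehicle, alternative = "greater",
                       var.equal = var_equal)$p.value
  }
  list(is_functional = p < alpha && mean(top_dose) > mean(vehicle),
       p_value = p,
       test_label = paste0("one-sided ",
                           if (var_equal) "Student" else "Welch",
                           " t (top dose > vehicle)"))
}

# single logistic fit on one concentration series (vehicle rows excluded)
# response = bottom + (top - bottom) / (1 + 10^((log_ec50 - log10 c) * h))
fit_logistic_once <- function(conc, resp, hill = c("fixed", "free"),
                              hill_value = 1, fix_bottom = NULL) {
  hill <- match.arg(hill)
  keep <- conc > 0 & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  lc <- log10(conc)
  if (length(unique(conc)) < 4L) {
    stop_data("fitting requires >= 4 distinct non-zero concentrations")
  }
  means <- tapply(resp, lc, mean)
  if (diff(range(means)) <= 1e-9 * max(1, abs(mean(means)))) {
    stop_data("degenerate fit: responses are flat across concentrations")
  }
  b0 <- if (is.null(fix_bottom)) min(means) else fix_bottom
  t0 <- max(means)
  mid <- (b0 + t0) / 2
  le0 <- as.numeric(names(means)[which.min(abs(means - mid))])
  dat <- data.frame(lc = lc, resp = resp)
  hv <- hill_value
  fb <- fix_bottom
  form <- if (is.null(fix_bottom)) {
    if (hill == "fixed") {
      resp ~ bottom + (top - bottom) / (1 + 10^((log_ec50 - lc) * hv))
    } else {
      resp ~ bottom + (top - bottom) / (1 + 10^((log_ec50 - lc) * h))
    }
  } else {
    if (hill == "fixed") {
      resp ~ fb + (top - fb) / (1 + 10^((log_ec50 - lc) * hv))
    } else {
      resp ~ fb + (top - fb) / (1 + 10^((log_ec50 - lc) * h))
    }
  }
  start <- list(top = t0, log_ec50 = le0)
  if (is.null(fix_bottom)) start$bottom <- b0
  if (hill == "free") start$h <- hill_value
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble::tibble(bottom = NA_real_, top = NA_real_,
                          log_ec50 = NA_real_, log_ec50_sem = NA_real_,
                          hill_slope = if (hill == "fixed") hill_value else NA_real_,
                          converged = FALSE, extrapolated = NA))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["log_ec50"]],
                 error = function(e) NA_real_)
  le <- unname(cf[["log_ec50"]])
  tibble::tibble(
    bottom = if (is.null(fix_bottom)) unname(cf[["bottom"]]) else fix_bottom,
    top = unname(cf[["top"]]),
    log_ec50 = le,
    log_ec50_sem = se,
    hill_slope = if (hill == "fixed") hill_value else unname(cf[["h"]]),
    converged = TRUE,
    extrapolated = le < min(lc) || le > max(lc)
  )
}

#' Fit a concentration-response curve
#'
#' Least-squares fit of the logistic
#' `response = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 c) * h))`
#' with the Hill slope fixed at 1 by default (three-parameter model).
#' Concentrations are log10-transformed internally; vehicle entries
#' (concentration 0) are excluded from fitting. In `"per_experiment"` mode
#' (default) each independent experiment is fitted separately and the
#' reported log EC50 is the across-experiment mean with its SEM; `"pooled"`
#' fits all points at once and reports the asymptotic standard error.
#'
#' @param series tibble with columns `concentration_M`, `replicate` and
#'   `response` (delta net BRET fold changes, per-cent changes or normalized
#'   AUC values).
#' @param mode `"per_experiment"` or `"pooled"`.
#' @param hill `"fixed"` (at `hill_value`) or `"free"`.
#' @param hill_value Hill slope used/started with.
#' @param fix_bottom fix the bottom asymptote at this value (e.g. 0 for DMR
#'   concentration-effect fits); `NULL` fits it.
#' @param gate optional result of [gate_functional_recruitment()]; when
#'   supplied and not functional the fit is refused and a flagged,
#'   non-converged result with `functional = FALSE` is returned.
#' @return one-row tibble: `bottom, top, log_ec50, log_ec50_sem, hill_slope,
#'   converged, extrapolated, functional, n_experiments`.
#' @export
fit_concentration_response <- function(series,
                                       mode = c("per_experiment", "pooled"),
                                       hill = c("fixed", "free"),
                                       hill_value = 1,
                                       fix_bottom = NULL,
                                       gate = NULL) {
  mode <- match.arg(mode); hill <- match.arg(hill)
  if (!is.null(gate) && !isTRUE(gate$is_functional)) {
    return(tibble::tibble(bottom = NA_real_, top = NA_real_,
                          log_ec50 = NA_real_, log_ec50_sem = NA_real_,
                          hill_slope = NA_real_, converged = FALSE,
                          extrapolated = NA, functional = FALSE,
                          n_experiments = length(unique(series$replicate))))
  }
  if (mode == "pooled") {
    out <- fit_logistic_once(series$concentration_M, series$response,
                             hill = hill, hill_value = hill_value,
                             fix_bottom = fix_bottom)
    out$functional <- TRUE
    out$n_experiments <- length(unique(series$replicate))
    return(out)
  }
  fits <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(~ fit_logistic_once(.x$concentration_M, .x$response,
                                         hill = hill, hill_value = hill_value,
                                         fix_bottom = fix_bottom)) |>
    dplyr::bind_rows()
  ok <- fits$converged
  tibble::tibble(
    bottom = mean(fits$bottom[ok]), top = mean(fits$top[ok]),
    log_ec50 = mean(fits$log_ec50[ok]),
    log_ec50_sem = sem(fits$log_ec50[ok]),
    hill_slope = mean(fits$hill_slope[ok]),
    converged = any(ok), extrapolated = any(fits$extrapolated[ok]),
    functional = TRUE, n_experiments = sum(ok)
  )
}

#' Normalize a concentration series to its own maximum
#'
#' Divides every replicate response by the condition's maximal per-
#' concentration mean response and multiplies by 100, so the condition's own
#' maximum mean maps to 100%.
#'
#' @param series tibble with `concentration_M` and `response`.
#' @return the series with `response` rescaled to per cent of maximum.
#' @export
normalize_to_max <- function(series) {
  means <- tapply(series$response, series$concentration_M, mean)
  m <- max(means)
  if (!is.finite(m) || m <= 0) {
    stop_data("maximum mean response is not positive; cannot normalize")
  }
  series$response <- series$response / m * 100
  series
}

#' Compare potencies (log EC50) against a reference condition
#'
#' One-way ANOVA on per-experiment log EC50 values followed by two-sided
#' Dunnett many-to-one comparisons against the reference condition.
#'
#' @param fits tibble with columns `condition` and `log_ec50` (one row per
#'   independent experiment).
#' @param reference_condition label of the control condition.
#' @return tibble of Dunnett comparisons (see [dunnett_test()]) with the
#'   one-way ANOVA F and p attached as attributes `anova_F` / `anova_p`.
#' @export
compare_potency <- function(fits, reference_condition) {
  if (!reference_condition %in% fits$condition) {
    stop_config(paste0("reference condition '", reference_condition,
                       "' is absent"))
  }
  groups <- split(fits$log_ec50, fits$condition)
  av <- anova_oneway(groups)
  dn <- dunnett_test(groups, control = reference_condition,
                     sidedness = "two.sided")
  attr(dn, "anova_F") <- av$F
  attr(dn, "anova_p") <- av$p
  dn
}

#' Area under a DMR trace over the 0-1800 s window
#'
#' Trapezoidal integral of an (empty-vector-corrected) wavelength-shift trace
#' over `[0, 1800]` s; window endpoints are linearly interpolated when not
#' sampled exactly.
#'
#' @param time_s time vector in seconds; must cover the window.
#' @param shift_pm corrected wavelength shift in picometres.
#' @param window integration window in seconds.
#' @return AUC in pm·s.
#' @export
dmr_auc <- function(time_s, shift_pm, window = c(0, 1800)) {
  if (min(time_s) > window[1] || max(time_s) < window[2]) {
    stop_data("trace does not cover the AUC window")
  }
  keep <- time_s >= window[1] & time_s <= window[2]
  t <- time_s[keep]; y <- shift_pm[keep]
  for (edge in window) {
    if (!edge %in% t) {
      ye <- stats::approx(time_s, shift_pm, xout = edge)$y
      t <- c(t, edge); y <- c(y, ye)
    }
  }
  o <- order(t); t <- t[o]; y <- y[o]
  sum(diff(t) * (head(y, -1) + y[-1]) / 2)
}

#' Correct DMR sample traces by the empty-vector reference
#'
#' Subtracts the per-timepoint mean of the reference (empty-vector) traces
#' from every sample trace.
#'
#' @param traces tibble as from [simulate_dmr_traces()].
#' @return the sample rows with `shift_pm` replaced by the corrected shift.
#' @export
dmr_correct <- function(traces) {
  ref <- dplyr::filter(traces, .data$role == "reference")
  if (nrow(ref) == 0L) stop_config("no reference (empty-vector) traces present")
  ref_mean <- ref |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(ref_pm = mean(.data$shift_pm), .groups = "drop")
  traces |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::left_join(ref_mean, by = "time_s") |>
    dplyr::mutate(shift_pm = .data$shift_pm - .data$ref_pm) |>
    dplyr::select(-"ref_pm")
}

#' DMR concentration-effect analysis from AUC values
#'
#' Normalizes per-concentration AUC values to a reference AUC (100%) and fits
#' a logistic concentration-effect curve with the bottom constrained to zero.
#'
#' @param aucs tibble with `concentration_M`, `replicate`, `auc`.
#' @param reference_auc positive scalar AUC defining 100% effect.
#' @param mode,hill,hill_value passed to [fit_concentration_response()].
#' @return list with `effects` (the normalized series) and `fit` (the
#'   bottom-constrained fit result; `bottom` is exactly 0).
#' @export
dmr_concentration_effect <- function(aucs, reference_auc,
                                     mode = "pooled",
                                     hill = "fixed", hill_value = 1) {
  if (!is.finite(reference_auc) || reference_auc <= 0) {
    stop_data("reference AUC must be positive")
  }
  effects <- aucs |>
    dplyr::mutate(response = 100 * .data$auc / reference_auc)
  fit <- fit_concentration_response(effects, mode = mode, hill = hill,
                                    hill_value = hill_value, fix_bottom = 0)
  list(effects = effects, fit = fit)
}
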