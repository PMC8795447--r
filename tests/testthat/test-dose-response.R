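test_that("the functional-recruitment gate matches closed-form t statistics", {
  top <- c(1.5, 1.6, 1.4); veh <- c(1.0, 1.0, 1.0)
  # default: pooled-variance Student t, written out by hand
  g <- gate_functional_recruitment(top, veh)
  sp2 <- (2 * var(top) + 2 * var(veh)) / 4
  tstat <- (mean(top) - mean(veh)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(g$p_value, pt(tstat, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(g$is_functional)

  # Welch variant, closed form with the Satterthwaite df
  gw <- gate_functional_recruitment(top, veh, var_equal = FALSE)
  se <- sqrt(var(top) / 3 + var(veh) / 3)
  tw <- (mean(top) - mean(veh)) / se
  dfw <- (var(top) / 3 + var(veh) / 3)^2 /
    ((var(top) / 3)^2 / 2 + (var(veh) / 3)^2 / 2)
  expect_equal(gw$p_value, pt(tw, dfw, lower.tail = FALSE), tolerance = 1e-12)

  # identical samples: no evidence of an increase
  g0 <- gate_functional_recruitment(c(1, 1, 1), c(1, 1, 1))
  expect_equal(g0$p_value, 0.5)
  expect_false(g0$is_functional)
  expect_error(gate_functional_recruitment(1.5, c(1, 1)),
               class = "grk_data_error")
})

test_that("gate power is monotone non-decreasing in the planted effect size", {
  set.seed(99)
  power_at <- function(delta, n_runs = 800) {
    mean(replicate(n_runs, {
      gate_functional_recruitment(rnorm(3, 1 + delta, 0.05),
                                  rnorm(3, 1, 0.05))$is_functional
    }))
  }
  pows <- sapply(c(0.02, 0.05, 0.1), power_at)
  expect_true(all(diff(pows) >= -0.02))  # allow Monte-Carlo jitter
  expect_gt(pows[3], pows[1] + 0.3)      # power rises clearly with effect
})

test_that("noise-free logistic data are recovered exactly", {
  lc <- seq(-10, -4)
  conc <- 10^lc
  resp <- 1 + (2 - 1) / (1 + 10^((-7 - lc) * 1))
  series <- tibble::tibble(concentration_M = rep(conc, 3),
                           replicate = rep(1:3, each = length(conc)),
                           response = rep(resp, 3))
  fit <- fit_concentration_response(series)
  expect_true(fit$converged)
  expect_equal(fit$log_ec50, -7, tolerance = 1e-6)
  expect_equal(fit$bottom, 1, tolerance = 1e-6)
  expect_equal(fit$top, 2, tolerance = 1e-6)
  expect_false(fit$extrapolated)

  flat <- series; flat$response <- 1.3
  expect_error(fit_concentration_response(flat), class = "grk_data_error")
})

test_that("a failed gate refuses the fit but returns a flagged record", {
  series <- tibble::tibble(concentration_M = rep(10^seq(-10, -4), 3),
                           replicate = rep(1:3, each = 7),
                           response = rnorm(21, 1, 0.01))
  gate <- list(is_functional = FALSE, p_value = 0.4, test_label = "x")
  fit <- fit_concentration_response(series, gate = gate)
  expect_false(fit$functional)
  expect_false(fit$converged)
  expect_true(is.na(fit$log_ec50))
})

test_that("normalization to the maximal mean response is idempotent and scale-free", {
  series <- tibble::tibble(concentration_M = rep(c(1e-8, 1e-7, 1e-6), 2),
                           replicate = rep(1:2, each = 3),
                           response = c(1, 2, 4, 1, 2, 4))
  norm <- normalize_to_max(series)
  expect_equal(unique(norm$response), c(25, 50, 100))
  expect_equal(normalize_to_max(norm)$response, norm$response)
  scaled <- series; scaled$response <- scaled$response * 7
  expect_equal(normalize_to_max(scaled)$response, norm$response)
  bad <- series; bad$response <- -bad$response
  expect_error(normalize_to_max(bad), class = "grk_data_error")
})

test_that("fitted log EC50 is invariant under affine rescaling of responses", {
  set.seed(8)
  lc <- seq(-10, -4)
  series <- tibble::tibble(
    concentration_M = rep(10^lc, 3), replicate = rep(1:3, each = length(lc)),
    response = rep(1 + 1 / (1 + 10^((-7 - lc))), 3) * rnorm(21, 1, 0.03)
  )
  f1 <- fit_concentration_response(series)
  scaled <- series
  scaled$response <- 40 + 250 * scaled$response
  f2 <- fit_concentration_response(scaled)
  expect_equal(f2$log_ec50, f1$log_ec50, tolerance = 1e-6)
})

test_that("potency comparison of a reference against itself is null", {
  set.seed(21)
  fits <- tibble::tibble(
    condition = rep(c("Control", "Ref2"), each = 3),
    log_ec50 = c(rnorm(3, -7, 0.05), rnorm(3, -7, 0.05))
  )
  # duplicate the control values as a pseudo-condition: estimate exactly 0
  fits2 <- tibble::tibble(condition = rep(c("Control", "Copy"), each = 3),
                          log_ec50 = rep(fits$log_ec50[1:3], 2))
  dn <- compare_potency(fits2, "Control")
  expect_equal(dn$estimate, 0)
  expect_gt(dn$p_adjusted, 0.99)
  expect_error(compare_potency(fits, "absent"), class = "grk_config_error")
})

test_that("DMR AUC matches closed forms on piecewise-linear traces", {
  t <- seq(0, 3600, by = 15)
  expect_equal(dmr_auc(t, rep(100, length(t))), 180000)
  expect_equal(dmr_auc(t, rep(0, length(t))), 0)
  ramp <- ifelse(t <= 1800, t / 18, 100)
  expect_equal(dmr_auc(t, ramp), 90000)
  # window endpoints interpolated when not sampled
  t2 <- c(0, 700, 2000)
  y2 <- c(0, 70, 200)   # slope 0.1 pm/s throughout
  expect_equal(dmr_auc(t2, y2), 0.5 * 1800 * 180)
  expect_error(dmr_auc(seq(0, 1000), rep(1, 1001)), class = "grk_data_error")
})

test_that("noise-free DMR concentration-effect analysis recovers the planted potency", {
  conc <- 10^seq(-10, -6, by = 0.5)
  tr <- simulate_dmr_traces(conc, top_pm = 300, log_ec50 = -8, noise_cv = 0,
                            seed = 1)
  corr <- dmr_correct(tr)
  aucs <- corr |>
    dplyr::group_by(concentration_M, replicate) |>
    dplyr::summarise(auc = dmr_auc(time_s, shift_pm), .groups = "drop")
  ref <- max(tapply(aucs$auc, aucs$concentration_M, mean))
  res <- dmr_concentration_effect(aucs, reference_auc = ref)
  expect_equal(res$fit$bottom, 0)
  expect_equal(res$fit$log_ec50, -8, tolerance = 1e-6)
  expect_equal(max(res$effects$response), 100, tolerance = 1e-9)
  expect_error(dmr_concentration_effect(aucs, 0), class = "grk_data_error")
})
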