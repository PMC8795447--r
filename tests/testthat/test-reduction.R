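test_that("bret_ratio divides acceptor by donor and guards the donor channel", {
  expect_equal(bret_ratio(rep(1000, 5), rep(500, 5)), rep(0.5, 5))
  expect_equal(bret_ratio(rep(1000, 5), rep(0, 5)), rep(0, 5))
  # scale invariance of the ratio
  d <- runif(10, 1e4, 1e6); a <- runif(10, 1e3, 1e5)
  expect_equal(bret_ratio(3.7 * d, 3.7 * a), bret_ratio(d, a))
  expect_error(bret_ratio(c(1, 0, 1), c(1, 1, 1), well_id = "W1"),
               class = "grk_data_error")
})

test_that("mock correction subtracts the across-mock mean per timepoint", {
  expect_equal(mock_correct(rep(0.6, 4), list(rep(0.1, 4))), rep(0.5, 4))
  expect_equal(mock_correct(rep(0.6, 4), list(rep(0.08, 4), rep(0.12, 4))),
               rep(0.5, 4))
  expect_equal(mock_correct(rep(0.1, 4), list(rep(0.1, 4))), rep(0, 4))
  expect_error(mock_correct(rep(0.6, 4), list()), class = "grk_config_error")
  expect_error(mock_correct(rep(0.6, 4), list(rep(0.1, 3))),
               class = "grk_data_error")
})

test_that("window means exclude the stimulation timepoint and guard degenerate wells", {
  t <- seq(0, 480, by = 20)
  flat <- rep(0.5, length(t))
  wm <- window_means(t, flat, 180)
  expect_equal(wm$fold_change, 1)
  step <- ifelse(t <= 180, 0.5, 0.55)
  wm <- window_means(t, step, 180)
  expect_equal(wm$fold_change, 1.1)
  # the reading at the stimulation time must not enter either window
  poisoned <- step
  poisoned[t == 180] <- 1e6
  expect_equal(window_means(t, poisoned, 180)$fold_change, 1.1)
  expect_error(window_means(t, rep(0, length(t)), 180),
               class = "grk_data_error")
  expect_error(window_means(t, flat, 5), class = "grk_data_error")
})

test_that("vehicle normalization gives the net fold change and the vehicle identity", {
  expect_equal(net_fold_change(1.10, 1.00), 1.10)
  expect_equal(net_fold_change(1.07, c(1.05, 1.09)), 1.07 / 1.07)
  expect_error(net_fold_change(1.1, numeric(0)), class = "grk_config_error")
  expect_error(net_fold_change(1.1, c(0, 0)), class = "grk_data_error")
})

test_that("percent change maps fold changes onto the percent scale", {
  expect_equal(percent_change(c(1, 1.25, 0.9)), c(0, 25, -10))
})

test_that("the vehicle condition's net fold change is exactly 1 on any plate", {
  d <- tiny_design()
  tr <- list("Control+EV" = condition_truth(noise_cv = 0.08))
  red <- reduce_plate(simulate_bret_plate(d, tr, seed = 9))
  expect_identical(unique(red$net_fold_change[red$role == "vehicle"]), 1)
})

test_that("net fold changes are invariant under a common channel rescaling", {
  d <- tiny_design()
  tr <- list("Control+EV" = condition_truth(noise_cv = 0.05))
  plate <- simulate_bret_plate(d, tr, seed = 4)
  scaled <- plate
  scaled$donor <- scaled$donor * 5.3
  scaled$acceptor <- scaled$acceptor * 5.3
  expect_equal(reduce_plate(scaled)$net_fold_change,
               reduce_plate(plate)$net_fold_change, tolerance = 1e-12)
})

test_that("an acceptor offset shared by sample and mock wells cancels when donors match", {
  t <- seq(0, 480, by = 20)
  donor <- rep(2e5, length(t))
  mk_well <- function(id, role, acc) tibble::tibble(
    well_id = id, condition = "C", receptor = NA, arrestin = NA,
    grk_label = NA, role = role, concentration_M = ifelse(role == "sample", 1e-6, 0),
    replicate = 1L, time_s = t, donor = donor, acceptor = acc
  )
  acc_s <- donor * ifelse(t <= 180, 0.5, 0.6)
  acc_m <- donor * 0.1
  acc_v <- donor * 0.5
  plate <- dplyr::bind_rows(mk_well("s", "sample", acc_s),
                            mk_well("m", "mock", acc_m),
                            mk_well("v", "vehicle", acc_v))
  shifted <- plate
  shifted$acceptor <- shifted$acceptor + 0.07 * donor
  r1 <- reduce_plate(plate, stimulation_time = 180)
  r2 <- reduce_plate(shifted, stimulation_time = 180)
  expect_equal(r2$net_fold_change, r1$net_fold_change, tolerance = 1e-12)
})

test_that("baseline bars normalize to the reference baseline and recover planted pre-coupling", {
  d <- tiny_design(conditions = c("dQ-GRK+EV", "dQ-GRK+GRK2"))
  tr <- list(
    "dQ-GRK+EV" = condition_truth(noise_cv = 0, top_fold = 1),
    "dQ-GRK+GRK2" = condition_truth(noise_cv = 0, top_fold = 1.5,
                                    precoupling_factor = 1.5)
  )
  red <- reduce_plate(simulate_bret_plate(d, tr, seed = 1))
  bars <- baseline_bars(red, "dQ-GRK+EV")
  s <- bars$summary
  expect_equal(s$baseline_mean[s$condition == "dQ-GRK+EV"], 1, tolerance = 1e-9)
  expect_equal(s$baseline_mean[s$condition == "dQ-GRK+GRK2"], 1.5,
               tolerance = 1e-9)
  # normalization by a common positive constant preserves ordering
  expect_true(all(bars$replicates$stimulated_norm >=
                    bars$replicates$baseline_norm - 1e-9))
  expect_error(baseline_bars(red, "absent"), class = "grk_config_error")
})

test_that("the reduction agrees with a flat per-timepoint oracle", {
  d <- tiny_design(conditions = c("Control+EV", "dQ-GRK+GRK2"),
                   n_replicates = 2L, concentrations = 10^seq(-9, -5))
  tr <- list(
    "Control+EV" = condition_truth(noise_cv = 0.1),
    "dQ-GRK+GRK2" = condition_truth(noise_cv = 0.1, precoupling_factor = 1.2)
  )
  plate <- simulate_bret_plate(d, tr, seed = 31)
  red <- reduce_plate(plate)
  samples <- red$well_id[red$role == "sample"]
  for (wid in samples) {
    expect_equal(red$net_fold_change[red$well_id == wid],
                 oracle_net_fold(plate, wid, 180, 180, 300),
                 tolerance = 1e-10)
  }
})
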