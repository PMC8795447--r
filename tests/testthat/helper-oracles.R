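# Independent brute-force oracles used by the equivalence tests. These are
# deliberately plain, loop-based recomputations with no shared code paths
# with the package internals.

# flat per-timepoint recomputation of one sample well's net BRET fold change
oracle_net_fold <- function(plate, wid, t_stim, bd, sd_) {
  w <- as.data.frame(plate[plate$well_id == wid, ])
  sess <- as.data.frame(plate[plate$condition == w$condition[1] &
                                plate$replicate == w$replicate[1], ])
  times <- sort(unique(w$time_s))
  mock_ids <- unique(sess$well_id[sess$role == "mock"])
  fold_of <- function(id) {
    ww <- sess[sess$well_id == id, ]
    ww <- ww[order(ww$time_s), ]
    base_vals <- c(); stim_vals <- c()
    for (i in seq_along(times)) {
      t <- times[i]
      ratio <- ww$acceptor[i] / ww$donor[i]
      mock_sum <- 0; mock_n <- 0
      for (mid in mock_ids) {
        mw <- sess[sess$well_id == mid, ]
        mw <- mw[order(mw$time_s), ]
        mock_sum <- mock_sum + mw$acceptor[i] / mw$donor[i]
        mock_n <- mock_n + 1
      }
      corr <- if (mock_n > 0) ratio - mock_sum / mock_n else ratio
      if (t >= t_stim - bd && t < t_stim) base_vals <- c(base_vals, corr)
      if (t > t_stim && t <= t_stim + sd_) stim_vals <- c(stim_vals, corr)
    }
    (sum(stim_vals) / length(stim_vals)) / (sum(base_vals) / length(base_vals))
  }
  veh_ids <- unique(sess$well_id[sess$role == "vehicle"])
  veh_folds <- sapply(veh_ids, fold_of)
  fold_of(wid) / (sum(veh_folds) / length(veh_folds))
}

# nested-loop motif scanner over a character vector
oracle_scan <- function(seq_chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  L <- length(seq_chars); pl <- length(pat)
  starts <- integer(0)
  if (L < pl) return(starts)
  for (s in 1:(L - pl + 1)) {
    ok <- TRUE
    for (j in 1:pl) {
      ch <- seq_chars[s + j - 1]
      if (pat[j] == "P" &&
          !(ch == "S" || ch == "T" || ch == "D" || ch == "E")) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# full-enumeration two-sided Fisher p over all tables with the observed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; N <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  p_obs <- prob(a)
  total <- 0
  for (x in max(0, c1 - r2):min(r1, c1)) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# scalar-loop Canberra distance
oracle_canberra <- function(u, v) {
  total <- 0
  for (i in seq_along(u)) {
    den <- abs(u[i]) + abs(v[i])
    if (den != 0) total <- total + abs(u[i] - v[i]) / den
  }
  total
}

# small single-condition design used across tests
tiny_design <- function(concentrations = 10^seq(-10, -4),
                        n_replicates = 3L, conditions = "Control+EV",
                        ...) {
  assay_design(conditions, concentrations = concentrations,
               n_replicates = n_replicates, sampling_interval = 20, ...)
}
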