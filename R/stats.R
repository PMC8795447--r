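#' One-way fixed-effects ANOVA on replicate groups
#'
#' @param groups named list of numeric replicate vectors, each of length >= 2.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  ns <- vapply(groups, length, 1L)
  if (length(groups) < 2L) stop_config("ANOVA requires at least 2 groups")
  if (any(ns < 2L)) stop_data("every ANOVA group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  if (stats::var(y) == 0) {
    return(list(F = 0, p = 1, df1 = length(groups) - 1L,
                df2 = length(y) - length(groups)))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]))
}

# pooled residual variance and df across a list of groups
pooled_error <- function(groups) {
  ns <- vapply(groups, length, 1L)
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  df <- sum(ns) - length(groups)
  list(s2 = ss / df, df = df)
}

#' Bonferroni-adjusted pairwise contrasts of one condition row
#'
#' Computes the specified two-sided contrasts between condition means and
#' applies the Bonferroni correction with the family size equal to the number
#' of contrasts supplied. By default the error variance is pooled across all
#' groups of the row (the "ANOVA followed by Bonferroni's test" procedure,
#' with the ANOVA residual degrees of freedom); `pool_variance = FALSE` uses
#' a plain pooled two-sample t per contrast instead.
#'
#' @param groups named list of replicate vectors (one entry per condition).
#' @param contrasts list of length-2 character vectors `c(a, b)`, testing
#'   `a - b`.
#' @param pool_variance pool the error variance across all groups.
#' @return tibble with one row per contrast: `contrast, condition_a,
#'   condition_b, direction, estimate, t, df, p_unadjusted, p_adjusted,
#'   method`.
#' @export
pairwise_bonferroni <- function(groups, contrasts, pool_variance = TRUE) {
  conds <- unlist(contrasts)
  unknown <- setdiff(conds, names(groups))
  if (length(unknown) > 0L) {
    stop_config(paste0("contrast references unknown condition(s): ",
                       paste(unique(unknown), collapse = ", ")))
  }
  m <- length(contrasts)
  pe <- pooled_error(groups)
  rows <- lapply(contrasts, function(ct) {
    a <- groups[[ct[1]]]; b <- groups[[ct[2]]]
    est <- mean(a) - mean(b)
    if (pool_variance) {
      s2 <- pe$s2; df <- pe$df
    } else {
      pe2 <- pooled_error(groups[ct])
      s2 <- pe2$s2; df <- pe2$df
    }
    se <- sqrt(s2 * (1 / length(a) + 1 / length(b)))
    tstat <- if (se == 0) 0 else est / se
    p <- 2 * stats::pt(-abs(tstat), df)
    tibble::tibble(
      contrast = paste(ct[1], "vs", ct[2]),
      condition_a = ct[1], condition_b = ct[2],
      direction = sign(est), estimate = est, t = tstat, df = df,
      p_unadjusted = p, p_adjusted = min(1, m * p),
      method = paste0("two-sided t (",
                      if (pool_variance) "ANOVA-pooled" else "per-contrast",
                      " variance), Bonferroni m = ", m)
    )
  })
  dplyr::bind_rows(rows)
}

#' Dunnett many-to-one comparisons
#'
#' Compares every treatment group against a control with multiplicity
#' adjustment via the multivariate-t reference distribution of the joint
#' contrast statistics (correlation \eqn{\rho_{ij} = \lambda_i \lambda_j}
#' with \eqn{\lambda_i = \sqrt{n_0 / (n_0 + n_i)}}, pooled error variance,
#' residual degrees of freedom). The multivariate-t probabilities are
#' evaluated by the Genz-Bretz quasi-Monte-Carlo algorithm with a fixed
#' internal seed, so results are deterministic to the stated tolerance and
#' unbalanced group sizes and one-sided alternatives are handled uniformly.
#'
#' @param groups named list of replicate vectors, control included.
#' @param control name of the control group.
#' @param sidedness `"two.sided"`, `"greater"` (treatment > control) or
#'   `"less"`.
#' @param abseps absolute tolerance of the multivariate-t evaluation.
#' @param maxpts maximum integrand evaluations.
#' @param internal_seed seed for the quasi-Monte-Carlo evaluation.
#' @return tibble with one row per treatment group: `condition, estimate, t,
#'   df, p_unadjusted, p_adjusted, sidedness`.
#' @export
dunnett_test <- function(groups, control,
                         sidedness = c("two.sided", "greater", "less"),
                         abseps = 1e-4, maxpts = 1e5,
                         internal_seed = 20211207L) {
  sidedness <- match.arg(sidedness)
  if (!control %in% names(groups)) {
    stop_config(paste0("control group '", control, "' is absent"))
  }
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L)) stop_data("every group needs n >= 2")
  trt <- setdiff(names(groups), control)
  if (length(trt) == 0L) stop_config("no treatment groups to compare")
  pe <- pooled_error(groups)
  n0 <- length(groups[[control]])
  m0 <- mean(groups[[control]])
  lambda <- sqrt((1 / n0) / (1 / n0 + 1 / ns[trt]))
  k <- length(trt)
  corr <- tcrossprod(lambda)
  diag(corr) <- 1
  alg <- mvtnorm::GenzBretz(maxpts = maxpts, abseps = abseps)

  rows <- lapply(seq_along(trt), function(i) {
    g <- trt[i]
    est <- mean(groups[[g]]) - m0
    se <- sqrt(pe$s2 * (1 / ns[[g]] + 1 / n0))
    tstat <- if (se == 0) 0 else est / se
    p_un <- switch(sidedness,
      two.sided = 2 * stats::pt(-abs(tstat), pe$df),
      greater = stats::pt(tstat, pe$df, lower.tail = FALSE),
      less = stats::pt(tstat, pe$df)
    )
    p_adj <- withr::with_seed(internal_seed, {
      pr <- switch(sidedness,
        two.sided = mvtnorm::pmvt(lower = rep(-abs(tstat), k),
                                  upper = rep(abs(tstat), k),
                                  df = pe$df, corr = corr, algorithm = alg),
        greater = mvtnorm::pmvt(lower = rep(-Inf, k),
                                upper = rep(tstat, k),
                                df = pe$df, corr = corr, algorithm = alg),
        less = mvtnorm::pmvt(lower = rep(tstat, k),
                             upper = rep(Inf, k),
                             df = pe$df, corr = corr, algorithm = alg)
      )
      min(1, max(0, 1 - as.numeric(pr)))
    })
    tibble::tibble(condition = g, estimate = est, t = tstat, df = pe$df,
                   p_unadjusted = p_un, p_adjusted = max(p_adj, p_un),
                   sidedness = sidedness)
  })
  dplyr::bind_rows(rows)
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range-based all-pairs comparisons after a one-way ANOVA
#' (wraps [stats::TukeyHSD()]).
#'
#' @param groups named list of replicate vectors (>= 2 groups, n >= 2 each).
#' @return tibble with `contrast, estimate, p_adjusted`.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2L) stop_config("Tukey HSD requires at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop_data("every group needs n >= 2")
  }
  ns <- vapply(groups, length, 1L)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (stats::var(y) == 0) {
    cmb <- utils::combn(names(groups), 2)
    return(tibble::tibble(contrast = paste(cmb[2, ], "-", cmb[1, ]),
                          estimate = 0, p_adjusted = 1))
  }
  th <- stats::TukeyHSD(stats::aov(y ~ g))$g
  tibble::tibble(contrast = rownames(th), estimate = th[, "diff"],
                 p_adjusted = th[, "p adj"])
}
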