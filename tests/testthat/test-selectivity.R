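test_that("the heatmap transform is the signed, capped -log10 of unadjusted p", {
  cmp <- tibble::tibble(
    pair = rep("P1", 3),
    contrast = c("a", "b", "c"),
    direction = c(1, -1, 1),
    p_unadjusted = c(0.01, 1, 1e-30)
  )
  m <- transform_p_matrix(cmp)
  expect_equal(unname(m["P1", c("a", "b", "c")]), c(2, 0, 16))
  # p = 0 capped as well
  cmp$p_unadjusted[1] <- 0
  expect_equal(unname(transform_p_matrix(cmp)["P1", "a"]), 16)
  # mismatched contrast sets rejected
  bad <- dplyr::bind_rows(cmp, tibble::tibble(pair = "P2", contrast = "a",
                                              direction = 1,
                                              p_unadjusted = 0.5))
  expect_error(transform_p_matrix(bad), class = "grk_data_error")
})

test_that("Canberra distance follows the |u|+|v| convention", {
  expect_equal(canberra_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(canberra_distance(c(1, 0), c(0, 1)), 2)
  # opposite signs: denominator is |u| + |v|, not |u + v|
  expect_equal(canberra_distance(1, -1), 1)
  expect_error(canberra_distance(1:3, 1:2), class = "grk_data_error")
})

test_that("Canberra distance matches the scalar-loop oracle and is symmetric", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    u <- rnorm(n) * sample(c(0, 1), n, replace = TRUE)
    v <- rnorm(n) * sample(c(0, 1), n, replace = TRUE)
    expect_equal(canberra_distance(u, v), oracle_canberra(u, v),
                 tolerance = 1e-12)
    expect_equal(canberra_distance(u, v), canberra_distance(v, u))
    expect_identical(canberra_distance(u, u), 0)
  }
})

test_that("clustering merges identical rows first and is deterministic", {
  m <- rbind(P1 = c(4, 4, 0, 0), P2 = c(4, 4, 0, 0), P3 = c(-4, 0, 3, 3))
  cl <- hierarchical_cluster(m)
  # the duplicate pair merges at height 0
  expect_equal(cl$hclust$height[1], 0)
  first <- cl$hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))
  expect_identical(cl$leaf_order, hierarchical_cluster(m)$leaf_order)
  expect_true(grepl("P1", cl$newick))
  one <- hierarchical_cluster(m[1, , drop = FALSE])
  expect_null(one$hclust)
  expect_equal(one$leaf_order, "P1")
})

fake_results <- function(p_by_grk, dir_by_grk = c(GRK2 = 1, GRK3 = 1,
                                                  GRK5 = 1, GRK6 = 1)) {
  tibble::tibble(
    condition_a = paste0("dQ-GRK+", names(p_by_grk)),
    condition_b = "dQ-GRK+EV",
    direction = unname(dir_by_grk[names(p_by_grk)]),
    p_adjusted = unname(p_by_grk)
  )
}

test_that("the selectivity rule distinguishes the three groups", {
  all_sig <- fake_results(c(GRK2 = 0.001, GRK3 = 0.002, GRK5 = 0.01,
                            GRK6 = 0.01))
  expect_equal(call_selectivity(all_sig), "GRK2/3/5/6-regulated")
  only23 <- fake_results(c(GRK2 = 0.001, GRK3 = 0.002, GRK5 = 0.4,
                           GRK6 = 0.8))
  expect_equal(call_selectivity(only23), "GRK2/3-regulated")
  none <- fake_results(c(GRK2 = 0.2, GRK3 = 0.4, GRK5 = 0.4, GRK6 = 0.8))
  expect_equal(call_selectivity(none), "unclassified")
  # a significant negative contrast is not a positive recruitment signal
  neg <- fake_results(c(GRK2 = 0.001, GRK3 = 0.5, GRK5 = 0.001, GRK6 = 0.9),
                      dir_by_grk = c(GRK2 = 1, GRK3 = 1, GRK5 = -1, GRK6 = 1))
  expect_equal(call_selectivity(neg), "GRK2/3-regulated")
  # GRK5/6 support alone is not enough for either regulated group
  only56 <- fake_results(c(GRK2 = 0.5, GRK3 = 0.5, GRK5 = 0.001,
                           GRK6 = 0.001))
  expect_equal(call_selectivity(only56), "unclassified")
})

test_that("the selectivity call is invariant to contrast order", {
  res <- fake_results(c(GRK2 = 0.001, GRK3 = 0.3, GRK5 = 0.01, GRK6 = 0.6))
  expect_equal(call_selectivity(res), call_selectivity(res[c(3, 1, 4, 2), ]))
  expect_error(call_selectivity(res[1:3, ]), class = "grk_config_error")
})

test_that("classify_pairs recovers a clean planted structure end to end", {
  set.seed(33)
  conds <- unname(grk_conditions())
  mk_pair <- function(pair, effects) {
    do.call(rbind, lapply(conds, function(cn) {
      mu <- 1 + ifelse(cn %in% effects, 0.5, 0)
      tibble::tibble(pair = pair, condition = cn, replicate = 1:3,
                     value = rnorm(3, mu, 0.03))
    }))
  }
  cm <- dplyr::bind_rows(
    mk_pair("A", c("Control+EV", paste0("dQ-GRK+GRK", c(2, 3, 5, 6)))),
    mk_pair("B", c("Control+EV", "dQ-GRK+GRK2", "dQ-GRK+GRK3")),
    mk_pair("C", "Control+EV")
  )
  out <- classify_pairs(cm)
  calls <- setNames(out$calls$group, out$calls$pair)
  expect_equal(unname(calls["A"]), "GRK2/3/5/6-regulated")
  expect_equal(unname(calls["B"]), "GRK2/3-regulated")
  expect_equal(unname(calls["C"]), "unclassified")
  expect_equal(sort(out$clustering$leaf_order), c("A", "B", "C"))
  expect_equal(ncol(out$heatmap), 9)
})

test_that("pre-coupling detection flags elevated baselines, not the reference", {
  set.seed(44)
  mk <- function(cond, mu) tibble::tibble(condition = cond, replicate = 1:3,
                                          baseline_norm = rnorm(3, mu, 0.05),
                                          net_fold_change = rnorm(3, 1, 0.02))
  bl <- dplyr::bind_rows(mk("dQ-GRK+EV", 1), mk("dQ-GRK+GRK2", 1.6),
                         mk("dQ-GRK+GRK5", 1))
  pc <- call_precoupling(bl, "dQ-GRK+EV")
  expect_true(pc$precoupled[pc$condition == "dQ-GRK+GRK2"])
  expect_false("dQ-GRK+EV" %in% pc$condition)  # reference is not self-tested
  expect_error(call_precoupling(bl, "missing"), class = "grk_config_error")
})
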