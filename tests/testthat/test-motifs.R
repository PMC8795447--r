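test_that("Ser/Thr site scanning excludes Asp/Glu and names bad residues", {
  expect_equal(scan_sites("ADES"), 4L)       # D and E are not sites
  expect_equal(scan_sites("KKKK"), integer(0))
  expect_equal(scan_sites("STST"), 1:4)
  err <- tryCatch(scan_sites("AXB", id = "R1"), error = identity)
  expect_s3_class(err, "grk_data_error")
  expect_match(conditionMessage(err), "position 2")
})

test_that("motif grammars match P/X windows with overlaps", {
  h <- scan_motifs("SATT", "PXPP")
  expect_equal(h$start, 1L)
  h <- scan_motifs("SSSS", "PPP")
  expect_equal(h$start, c(1L, 2L))           # overlapping matches counted
  h <- scan_motifs("SSSS", "PPP", overlap = FALSE)
  expect_equal(h$start, 1L)                  # greedy non-overlap mode
  expect_equal(nrow(scan_motifs("KKKKK", "PXPP")), 0L)
  expect_error(scan_motifs("SATT", "QQQ"), class = "grk_config_error")
})

test_that("the scanner agrees with the nested-loop oracle on random sequences", {
  set.seed(14)
  grams <- motif_grammars()
  for (i in 1:50) {
    sq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                       replace = TRUE), collapse = "")
    chars <- strsplit(sq, "")[[1]]
    for (g in setdiff(names(grams), "ST-site")) {
      expect_identical(scan_motifs(sq, g)$start, oracle_scan(chars, grams[[g]]))
    }
  }
})

test_that("hit counts never increase when a P residue is mutated away", {
  set.seed(15)
  for (i in 1:20) {
    chars <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80,
                    replace = TRUE)
    sq <- paste(chars, collapse = "")
    p_pos <- which(chars %in% c("S", "T", "D", "E"))
    if (length(p_pos) == 0) next
    mutated <- chars
    mutated[sample(p_pos, 1)] <- "A"
    sq2 <- paste(mutated, collapse = "")
    for (g in c("PPP", "PXPP", "PXPXXP")) {
      expect_lte(nrow(scan_motifs(sq2, g)), nrow(scan_motifs(sq, g)))
    }
  }
})

test_that("relative positions span [0, 1] from N- to C-terminus", {
  expect_equal(relative_position(1L, 50L), 0)
  expect_equal(relative_position(50L, 50L), 1)
  expect_equal(relative_position(6L, 10L), 5 / 9)
  expect_equal(relative_position(1L, 1L), 0)
  expect_equal(relative_position(5L, 10L, convention = "over_L"), 0.5)
  expect_error(relative_position(11L, 10L), class = "grk_logic_error")
})

test_that("positions dichotomize at the 0.25/0.75 breakpoints, boundaries central", {
  expect_equal(categorize_position(0.5), "central")
  expect_equal(categorize_position(0.1), "peripheral")
  expect_equal(categorize_position(c(0.25, 0.75)), c("central", "central"))
  expect_equal(categorize_position(0.76), "peripheral")
  expect_error(categorize_position(1.2), class = "grk_logic_error")
})

test_that("every hit is either central or peripheral", {
  s <- simulate_segment_set(n_per_group = 8, n_motifs = 2, seed = 6)
  hits <- scan_segment_set(s)
  expect_true(all(hits$category %in% c("central", "peripheral")))
  tab <- table(hits$category)
  expect_equal(sum(tab), nrow(hits))
})

test_that("contingency tables count pooled occurrences by category and group", {
  hits <- tibble::tibble(
    motif = "PXPP",
    group_label = rep(c("G1", "G2"), each = 4),
    category = c("central", "central", "central", "peripheral",
                 "central", "peripheral", "peripheral", "peripheral"),
    receptor_id = paste0("R", 1:8), segment_kind = "Cterm",
    receptor_class = "A", start = 1L, relative_position = 0.5
  )
  tab <- build_contingency(hits, "PXPP", c("G1", "G2"))
  expect_equal(unname(tab), matrix(c(3, 1, 1, 3), 2))
  expect_error(build_contingency(hits, "PPP", c("G1", "G2")),
               class = "grk_data_error")
  expect_error(build_contingency(hits, "PXPP", c("G1", "G3")),
               class = "grk_data_error")
})

test_that("Fisher's exact test matches hand-derived values and conventions", {
  bal <- fisher_exact(matrix(c(1, 1, 1, 1), 2))
  expect_equal(bal$p_two_sided, 1)
  expect_equal(bal$odds_ratio, 1)
  # margins (2,2)/(2,2): point probabilities 1/6, 4/6, 1/6
  diag2 <- fisher_exact(matrix(c(2, 0, 0, 2), 2))
  expect_equal(diag2$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_equal(diag2$odds_ratio, Inf)
  expect_error(fisher_exact(matrix(c(1, -1, 1, 1), 2)),
               class = "grk_data_error")
  expect_error(fisher_exact(matrix(c(0, 0, 1, 1), 2)),
               class = "grk_data_error")
})

test_that("fisher_exact is symmetric under simultaneous row and column swaps", {
  set.seed(16)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    sw <- tab[2:1, 2:1]
    a <- fisher_exact(tab); b <- fisher_exact(sw)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
    expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
    expect_gt(a$p_two_sided, 0)
    expect_lte(a$p_two_sided, 1)
  }
})

test_that("group summaries report medians and pie fractions from the truth", {
  s <- simulate_segment_set(
    groups = c("GRK2/3", "GRK2/3/5/6"), n_per_group = 6,
    placement = c("GRK2/3" = "central", "GRK2/3/5/6" = "peripheral"),
    receptor_class = c("GRK2/3" = "A", "GRK2/3/5/6" = "B"), seed = 8
  )
  hits <- scan_segment_set(s, motifs = "PXPP")
  gs <- group_summary(hits, s)
  bg <- gs$by_group
  med23 <- bg$median_relative_position[bg$group_label == "GRK2/3"]
  expect_true(med23 >= 0.25 && med23 <= 0.75)
  expect_equal(sum(gs$pies$fraction[gs$pies$receptor_class == "A"]), 1)
  # single receptor, single hit: median is that hit's position
  one <- hits[hits$receptor_id == hits$receptor_id[1], ][1, ]
  gs1 <- group_summary(one, s[s$receptor_id == one$receptor_id, ])
  expect_equal(gs1$by_group$median_relative_position, one$relative_position)
  expect_equal(median(c(0.1, 0.5, 0.9)), 0.5)
})
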