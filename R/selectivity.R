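#' Standard condition labels of the GRK-selectivity screen
#'
#' The six transfection conditions compared for every GPCR-arrestin pair:
#' parental cells plus empty vector, quadruple-GRK-knockout cells plus empty
#' vector (the GRK-null reference), and the knockout cells rescued with one
#' GRK isoform each.
#'
#' @return named character vector with entries `control`, `reference`,
#'   `GRK2`, `GRK3`, `GRK5`, `GRK6`.
#' @export
grk_conditions <- function() {
  c(control = "Control+EV", reference = "dQ-GRK+EV",
    GRK2 = "dQ-GRK+GRK2", GRK3 = "dQ-GRK+GRK3",
    GRK5 = "dQ-GRK+GRK5", GRK6 = "dQ-GRK+GRK6")
}

#' Contrast families for selectivity calling and the comparison heatmap
#'
#' `selectivity_contrasts()` is the decision family: each GRK-rescue
#' condition against the GRK-null reference (m = 4).
#' `heatmap_contrasts()` is the display family: the rescue conditions against
#' both the GRK-null reference and the parental control, plus reference vs
#' control (m = 9).
#'
#' @param conditions named condition vector as from [grk_conditions()].
#' @return list of length-2 character contrasts.
#' @export
selectivity_contrasts <- function(conditions = grk_conditions()) {
  lapply(c("GRK2", "GRK3", "GRK5", "GRK6"), function(g) {
    c(conditions[[g]], conditions[["reference"]])
  })
}

#' @rdname selectivity_contrasts
#' @export
heatmap_contrasts <- function(conditions = grk_conditions()) {
  grks <- c("GRK2", "GRK3", "GRK5", "GRK6")
  c(
    lapply(grks, function(g) c(conditions[[g]], conditions[["reference"]])),
    lapply(grks, function(g) c(conditions[[g]], conditions[["control"]])),
    list(c(conditions[["reference"]], conditions[["control"]]))
  )
}

#' Signed -log10 transform of unadjusted p values for the heatmap
#'
#' Builds the heatmap matrix from per-pair comparison results: each entry is
#' `sign(direction) * min(-log10(p_unadjusted), cap)`. The sign encodes the
#' direction of the mean difference so that loss-of-recruitment contrasts are
#' distinguishable from gains; missing contrasts are 0.
#'
#' @param comparisons tibble with columns `pair, contrast, direction,
#'   p_unadjusted` (rows for all pairs; every pair must carry the same
#'   contrast set).
#' @param cap magnitude cap (default 16; p = 0 maps to the cap).
#' @return numeric matrix, rows = pairs, columns = contrasts.
#' @export
transform_p_matrix <- function(comparisons, cap = 16) {
  csets <- split(comparisons$contrast, comparisons$pair)
  ref <- csets[[1]]
  if (!all(vapply(csets, function(x) setequal(x, ref), TRUE))) {
    stop_data("pairs do not share a common contrast set")
  }
  val <- ifelse(comparisons$p_unadjusted <= 0, cap,
                pmin(-log10(comparisons$p_unadjusted), cap))
  comparisons$._h <- sign(comparisons$direction) * val
  wide <- comparisons |>
    dplyr::select("pair", "contrast", "._h") |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "._h",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$pair
  m
}

#' Canberra distance
#'
#' `sum_i |u_i - v_i| / (|u_i| + |v_i|)`, with terms where both entries are
#' zero contributing 0. Note this differs from [stats::dist()]'s Canberra
#' variant, which uses `|u_i + v_i|` in the denominator.
#'
#' @param u,v numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
canberra_distance <- function(u, v) {
  if (length(u) != length(v)) stop_data("vectors differ in length")
  den <- abs(u) + abs(v)
  num <- abs(u - v)
  sum(ifelse(den == 0, 0, num / den))
}

# all-pairs Canberra distance object for a row matrix
canberra_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- canberra_distance(mat[i, ], mat[j, ])
    }
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of heatmap rows by Canberra distance
#'
#' Agglomerative clustering (complete linkage by default) on the pairwise
#' Canberra distances between heatmap rows. Leaf order is deterministic:
#' [stats::hclust()] breaks ties by input order.
#'
#' @param mat numeric matrix with row names (e.g. from
#'   [transform_p_matrix()]).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `hclust` (or `NULL` for a single row), `leaf_order`
#'   (row labels in dendrogram order) and `newick` (Newick string).
#' @export
hierarchical_cluster <- function(mat, linkage = "complete") {
  if (nrow(mat) < 2L) {
    return(list(hclust = NULL, leaf_order = rownames(mat),
                newick = if (nrow(mat) == 1L)
                  paste0(rownames(mat), ";") else ""))
  }
  hc <- stats::hclust(canberra_dist(mat), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Call the GRK-selectivity group of one GPCR-arrestin pair
#'
#' Applies the grouping rule to the many-to-one comparison results of one
#' pair (each GRK-rescue condition vs the GRK-null reference). A contrast is
#' "significant-positive" when its adjusted p is below `alpha` and the rescue
#' mean exceeds the reference mean. The pair is `GRK2/3/5/6-regulated` when
#' \{GRK2 or GRK3\} and \{GRK5 or GRK6\} are each significant-positive,
#' `GRK2/3-regulated` when only the \{GRK2 or GRK3\} side is, and
#' `unclassified` otherwise. The call is invariant to the order in which
#' contrasts are supplied.
#'
#' @param results tibble from [pairwise_bonferroni()] for the
#'   [selectivity_contrasts()] family (columns `condition_a, direction,
#'   p_adjusted`).
#' @param alpha decision level on adjusted p.
#' @return character scalar group label.
#' @export
call_selectivity <- function(results, alpha = 0.05) {
  results$grk <- vapply(results$condition_a, function(x) {
    m <- regmatches(x, regexpr("GRK[2356]$", x))
    if (length(m)) m else NA_character_
  }, "")
  needed <- c("GRK2", "GRK3", "GRK5", "GRK6")
  if (!all(needed %in% results$grk)) {
    stop_config("results must contain one contrast per GRK2/3/5/6 vs reference")
  }
  sig_pos <- function(g) {
    r <- results[results$grk == g, ][1, ]
    r$p_adjusted < alpha && r$direction > 0
  }
  side23 <- sig_pos("GRK2") || sig_pos("GRK3")
  side56 <- sig_pos("GRK5") || sig_pos("GRK6")
  if (side23 && side56) "GRK2/3/5/6-regulated"
  else if (side23 && !side56) "GRK2/3-regulated"
  else "unclassified"
}

#' Classify all GPCR-arrestin pairs of a condition matrix
#'
#' End-to-end selectivity analysis: for every pair, ANOVA-pooled Bonferroni
#' contrasts for the decision family ([selectivity_contrasts()]) and the
#' display family ([heatmap_contrasts()]), the selectivity call, the signed
#' -log10 heatmap matrix, and Canberra/complete-linkage clustering of its
#' rows.
#'
#' @param cond_matrix tibble with columns `pair, condition, replicate, value`
#'   (replicate-level saturating-concentration net fold changes; >= 3
#'   replicates per cell).
#' @param alpha decision level.
#' @param conditions named condition vector as from [grk_conditions()].
#' @param linkage clustering linkage.
#' @param cap heatmap transform cap.
#' @return list with `calls` (pair, group, cluster position), `comparisons`
#'   (all display-family contrasts), `decision_comparisons`, `heatmap`,
#'   `clustering` (see [hierarchical_cluster()]).
#' @export
classify_pairs <- function(cond_matrix, alpha = 0.05,
                           conditions = grk_conditions(),
                           linkage = "complete", cap = 16) {
  need <- unname(conditions)
  pairs <- unique(cond_matrix$pair)
  dec_all <- list(); disp_all <- list(); calls <- list()
  for (p in pairs) {
    sub <- cond_matrix[cond_matrix$pair == p, ]
    groups <- split(sub$value, sub$condition)
    missing <- setdiff(need, names(groups))
    if (length(missing) > 0L) {
      stop_config(paste0("pair '", p, "' lacks condition(s): ",
                         paste(missing, collapse = ", ")))
    }
    if (any(vapply(groups[need], length, 1L) < 3L)) {
      stop_data(paste0("pair '", p, "' has cells with fewer than 3 replicates"))
    }
    dec <- pairwise_bonferroni(groups, selectivity_contrasts(conditions))
    disp <- pairwise_bonferroni(groups, heatmap_contrasts(conditions))
    dec$pair <- p; disp$pair <- p
    dec_all[[p]] <- dec; disp_all[[p]] <- disp
    calls[[p]] <- tibble::tibble(pair = p,
                                 group = call_selectivity(dec, alpha = alpha))
  }
  comparisons <- dplyr::bind_rows(disp_all)
  heat <- transform_p_matrix(comparisons, cap = cap)
  clustering <- hierarchical_cluster(heat, linkage = linkage)
  calls <- dplyr::bind_rows(calls)
  calls$cluster_position <- match(calls$pair, clustering$leaf_order)
  list(calls = calls, comparisons = comparisons,
       decision_comparisons = dplyr::bind_rows(dec_all),
       heatmap = heat, clustering = clustering)
}

#' Detect ligand-independent pre-coupling from baseline elevations
#'
#' Tests whether each condition's normalized baseline BRET ratio is
#' significantly elevated over the GRK-null reference (one-way ANOVA pooled
#' error, one-sided Dunnett many-to-one comparisons). When replicate-level
#' dynamic net fold changes are supplied, conditions whose dynamic response
#' does not exceed the reference mean are additionally flagged as
#' `dampened_dynamic` — together with an elevated baseline this is the
#' pre-coupling signature.
#'
#' @param baselines tibble with `condition, replicate, baseline_norm`
#'   (e.g. `baseline_bars(...)$replicates`); may also carry
#'   `net_fold_change`.
#' @param reference condition label of the GRK-null reference.
#' @param alpha significance level.
#' @return tibble with `condition, baseline_estimate, p_adjusted, precoupled,
#'   dampened_dynamic`.
#' @export
call_precoupling <- function(baselines, reference, alpha = 0.05) {
  if (!reference %in% baselines$condition) {
    stop_config(paste0("reference condition '", reference, "' is absent"))
  }
  groups <- split(baselines$baseline_norm, baselines$condition)
  dn <- dunnett_test(groups, control = reference, sidedness = "greater")
  out <- tibble::tibble(
    condition = dn$condition,
    baseline_estimate = dn$estimate,
    p_adjusted = dn$p_adjusted,
    precoupled = dn$p_adjusted < alpha
  )
  if ("net_fold_change" %in% names(baselines)) {
    nf <- tapply(baselines$net_fold_change, baselines$condition, mean)
    out$dampened_dynamic <- as.logical(nf[out$condition] <= nf[[reference]])
  } else {
    out$dampened_dynamic <- NA
  }
  out
}
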