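AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Phospho-motif grammars
#'
#' The motif grammars scanned in receptor intracellular segments. In a
#' pattern, `P` matches a phospho-acceptor or phospho-mimicking residue
#' \{Ser, Thr, Asp, Glu\} and `X` matches any amino acid. `ST-site` is the
#' single putative phosphorylation site \{Ser, Thr\} (Asp/Glu are motif
#' constituents, not sites).
#'
#' @return named character vector of patterns.
#' @export
motif_grammars <- function() {
  c("ST-site" = "s", PPP = "PPP", PXPP = "PXPP",
    PXPXXP = "PXPXXP", PXXPXXP = "PXXPXXP")
}

grammar_regex <- function(pattern) {
  if (pattern == "s") return("[ST]")
  paste(vapply(strsplit(pattern, "")[[1]],
               function(ch) if (ch == "P") "[STDE]" else ".", ""),
        collapse = "")
}

validate_sequence <- function(sequence, id = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L) {
    stop_data(paste0("invalid residue '", chars[bad[1]], "' at position ",
                     bad[1], if (!is.null(id)) paste0(" of ", id)))
  }
  invisible(chars)
}

#' Scan a segment for putative Ser/Thr phosphorylation sites
#'
#' @param sequence upper-case amino-acid string.
#' @param id optional identifier for error messages.
#' @return integer vector of 1-based positions whose residue is S or T.
#' @export
scan_sites <- function(sequence, id = NULL) {
  chars <- validate_sequence(sequence, id)
  which(chars %in% c("S", "T"))
}

#' Scan a segment for matches of one motif grammar
#'
#' Sliding-window match at every start; overlapping matches are all reported
#' by default (`overlap = FALSE` gives greedy non-overlapping matches for
#' sensitivity analysis). Starts are 1-based.
#'
#' @param sequence upper-case amino-acid string.
#' @param grammar a name from [motif_grammars()].
#' @param overlap count overlapping matches.
#' @param id optional identifier for error messages.
#' @return tibble with `motif, start, end`.
#' @export
scan_motifs <- function(sequence, grammar, overlap = TRUE, id = NULL) {
  grammars <- motif_grammars()
  if (!grammar %in% names(grammars)) {
    stop_config(paste0("unknown motif grammar: ", grammar))
  }
  validate_sequence(sequence, id)
  rx <- grammar_regex(grammars[[grammar]])
  plen <- if (grammars[[grammar]] == "s") 1L else nchar(grammars[[grammar]])
  starts <- if (overlap) {
    m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  } else {
    m <- gregexpr(rx, sequence)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  starts <- starts[starts + plen - 1L <= nchar(sequence)]
  tibble::tibble(motif = rep(grammar, length(starts)),
                 start = starts, end = starts + plen - 1L)
}

#' Relative position of a motif start within its segment
#'
#' Position of the match's first residue relative to the full segment
#' length, so 0 is the N-terminal end and 1 the C-terminal end. With the
#' default convention a 1-based start maps to `(start - 1) / (L - 1)`
#' (equivalently, the 0-based index over `L - 1`); `convention = "over_L"`
#' uses `start / L` instead.
#'
#' @param start 1-based start index.
#' @param segment_len segment length `L` (>= 1).
#' @param convention `"first_over_Lm1"` (default) or `"over_L"`.
#' @return value in `[0, 1]`.
#' @export
relative_position <- function(start, segment_len,
                              convention = c("first_over_Lm1", "over_L")) {
  convention <- match.arg(convention)
  if (any(start < 1L) || any(start > segment_len)) {
    abort("motif start outside the segment", class = "grk_logic_error")
  }
  if (convention == "first_over_Lm1") {
    if (segment_len == 1L) return(rep(0, length(start)))
    (start - 1) / (segment_len - 1)
  } else {
    start / segment_len
  }
}

#' Categorize a relative position as central or peripheral
#'
#' Relative positions within `[lower, upper]` (default 0.25-0.75, boundary
#' values inclusive, i.e. central) are `"central"`; the flanks are
#' `"peripheral"`.
#'
#' @param relpos relative position(s) in `[0, 1]`.
#' @param lower,upper breakpoints.
#' @return character vector `"central"`/`"peripheral"`.
#' @export
categorize_position <- function(relpos, lower = 0.25, upper = 0.75) {
  if (any(relpos < 0 | relpos > 1)) {
    abort("relative position outside [0, 1]", class = "grk_logic_error")
  }
  ifelse(relpos >= lower & relpos <= upper, "central", "peripheral")
}

#' Scan a segment set for all motif grammars
#'
#' @param segments segment tibble (`receptor_id, segment_kind, sequence,
#'   group_label, receptor_class`), e.g. from [simulate_segment_set()] or
#'   [read_segments_fasta()].
#' @param motifs grammar names to scan.
#' @param overlap count overlapping matches.
#' @param exclude receptor ids to drop before scanning (e.g. an
#'   unphysiological chimaera).
#' @param convention,lower,upper positional conventions, see
#'   [relative_position()] and [categorize_position()].
#' @return tibble of hits with segment metadata, `start`,
#'   `relative_position` and `category`.
#' @export
scan_segment_set <- function(segments, motifs = names(motif_grammars()),
                             overlap = TRUE, exclude = character(),
                             convention = "first_over_Lm1",
                             lower = 0.25, upper = 0.75) {
  segments <- segments[!segments$receptor_id %in% exclude, ]
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    L <- nchar(seg$sequence)
    for (m in motifs) {
      hits <- scan_motifs(seg$sequence, m, overlap = overlap,
                          id = seg$receptor_id)
      if (nrow(hits) == 0L) next
      rp <- relative_position(hits$start, L, convention = convention)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        receptor_id = seg$receptor_id, segment_kind = seg$segment_kind,
        group_label = seg$group_label, receptor_class = seg$receptor_class,
        motif = m, start = hits$start, relative_position = rp,
        category = categorize_position(rp, lower, upper)
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(receptor_id = character(), segment_kind = character(),
                          group_label = character(),
                          receptor_class = character(), motif = character(),
                          start = integer(), relative_position = numeric(),
                          category = character()))
  }
  dplyr::bind_rows(rows)
}

#' 2x2 central/peripheral by group contingency table of motif hits
#'
#' Pools motif occurrences across receptors: rows are position categories
#' (central, peripheral), columns the two groups being compared.
#'
#' @param hits hit tibble from [scan_segment_set()].
#' @param motif grammar name to tabulate.
#' @param group_pair length-2 character vector of values of `by` to compare.
#' @param by grouping column, `"group_label"` (default) or
#'   `"receptor_class"`.
#' @return 2x2 integer matrix.
#' @export
build_contingency <- function(hits, motif, group_pair, by = "group_label") {
  h <- hits[hits$motif == motif & hits[[by]] %in% group_pair, ]
  if (nrow(h) == 0L || !all(group_pair %in% h[[by]])) {
    stop_data("no motif hits in one or both groups; contingency table is empty")
  }
  tab <- table(factor(h$category, levels = c("central", "peripheral")),
               factor(h[[by]], levels = group_pair))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("central", "peripheral"), group_pair))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p value conditional on fixed margins (sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table) and the sample odds ratio `(a*d)/(b*c)` (infinite when `b*c = 0`
#' and `a*d > 0`).
#'
#' @param table 2x2 matrix of non-negative integer counts with both margins
#'   positive.
#' @return list with `contingency`, `odds_ratio`, `p_two_sided`, `conf_int`
#'   (95% CI of the odds ratio from the conditional likelihood).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_data("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table))) {
    stop_data("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_data("both margins of the table must be positive")
  }
  ft <- stats::fisher.test(table)
  ad <- table[1, 1] * table[2, 2]
  bc <- table[1, 2] * table[2, 1]
  or <- if (bc == 0) {
    if (ad == 0) NA_real_ else Inf
  } else ad / bc
  list(contingency = table, odds_ratio = or,
       p_two_sided = unname(ft$p.value), conf_int = unname(ft$conf.int))
}

#' Summarize motif hits by selectivity group and receptor class
#'
#' Dot-plot-ready summaries: per (motif, group) and per (motif, class) the
#' number of receptors, occurrence counts and the median relative position;
#' plus the per-class pie fractions of group membership.
#'
#' @param hits hit tibble from [scan_segment_set()].
#' @param segments the scanned segment tibble.
#' @return list with `by_group`, `by_class` and `pies`.
#' @export
group_summary <- function(hits, segments) {
  summarize_by <- function(col) {
    hits |>
      dplyr::group_by(.data$motif, .data[[col]]) |>
      dplyr::summarise(
        n_receptors = dplyr::n_distinct(.data$receptor_id),
        n_hits = dplyr::n(),
        hits_per_receptor = .data$n_hits / .data$n_receptors,
        median_relative_position = stats::median(.data$relative_position),
        .groups = "drop"
      )
  }
  pies <- segments |>
    dplyr::distinct(.data$receptor_id, .data$receptor_class,
                    .data$group_label) |>
    dplyr::count(.data$receptor_class, .data$group_label, name = "n") |>
    dplyr::group_by(.data$receptor_class) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(by_group = summarize_by("group_label"),
       by_class = summarize_by("receptor_class"),
       pies = pies)
}
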