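#' Simulate receptor intracellular segments with planted phospho-motifs
#'
#' Builds a set of synthetic IL3 / C-terminal segment sequences with known
#' motif content. Background residues are drawn from the 16 amino acids
#' outside \{S, T, D, E\} so that the only matches of the target grammar are
#' the planted ones; each planted motif instantiates its P positions from
#' \{S, T\} and its X positions from the background alphabet. After assembly
#' the sequence is re-scanned with [scan_motifs()] and regenerated on any
#' collision, so the returned truth table lists exactly the hits the scanner
#' must find.
#'
#' @param groups character vector of group labels (e.g. `"GRK2/3"`,
#'   `"GRK2/3/5/6"`).
#' @param n_per_group receptors per group (scalar or named by group).
#' @param length_range integer range of segment lengths.
#' @param motif grammar name to plant, one of `names(motif_grammars())`
#'   except `"ST-site"`.
#' @param placement per-group placement rule, named character vector with
#'   values `"central"` (relative position in \[0.35, 0.65\]), `"peripheral"`
#'   (in \[0, 0.15\] or \[0.85, 1\]) or `"random"`; unnamed scalar recycles.
#' @param n_motifs planted motifs per segment (scalar or named by group; 0
#'   plants none).
#' @param segment_kind `"IL3"` or `"Cterm"`.
#' @param receptor_class `"A"` or `"B"` (scalar or named by group).
#' @param seed integer seed.
#' @return tibble of segment records (`receptor_id, segment_kind, sequence,
#'   group_label, receptor_class`) with attribute `truth`: a tibble of planted
#'   hits (`receptor_id, motif, start` with 1-based starts).
#' @export
simulate_segment_set <- function(groups = c("GRK2/3", "GRK2/3/5/6"),
                                 n_per_group = 20L,
                                 length_range = c(40L, 80L),
                                 motif = "PXPP",
                                 placement = "random",
                                 n_motifs = 1L,
                                 segment_kind = "Cterm",
                                 receptor_class = "A",
                                 seed = 1L) {
  grammars <- motif_grammars()
  if (!motif %in% setdiff(names(grammars), "ST-site")) {
    stop_config(paste0("unknown motif grammar: ", motif))
  }
  pattern <- grammars[[motif]]
  plen <- nchar(pattern)
  if (min(length_range) < plen) {
    stop_config("segments shorter than the motif cannot carry a planted motif")
  }
  per_group <- function(x, g, default) {
    if (is.null(names(x))) rep(x, length.out = length(groups))[match(g, groups)]
    else if (g %in% names(x)) x[[g]] else default
  }
  background <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        c("S", "T", "D", "E"))

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    records <- list()
    truth <- list()
    idx <- 0L
    for (g in groups) {
      ng <- per_group(n_per_group, g, 20L)
      place <- per_group(placement, g, "random")
      nm <- per_group(n_motifs, g, 1L)
      cls <- per_group(receptor_class, g, "A")
      for (i in seq_len(ng)) {
        idx <- idx + 1L
        rid <- sprintf("R%03d", idx)
        for (attempt in 1:100) {
          L <- sample(seq(length_range[1], length_range[2]), 1L)
          seq_chars <- sample(background, L, replace = TRUE)
          starts <- integer(0)
          if (nm > 0L) {
            starts <- draw_starts(nm, L, plen, place)
            if (is.null(starts)) next
            for (s in starts) {
              pat <- strsplit(pattern, "")[[1]]
              inst <- ifelse(pat == "P",
                             sample(c("S", "T"), plen, replace = TRUE),
                             sample(background, plen, replace = TRUE))
              seq_chars[s:(s + plen - 1L)] <- inst
            }
          }
          sq <- paste(seq_chars, collapse = "")
          found <- scan_motifs(sq, motif)$start
          if (setequal(found, starts) && length(found) == length(starts)) {
            records[[idx]] <- tibble::tibble(
              receptor_id = rid, segment_kind = segment_kind, sequence = sq,
              group_label = g, receptor_class = cls
            )
            if (length(starts) > 0L) {
              truth[[length(truth) + 1L]] <- tibble::tibble(
                receptor_id = rid, motif = motif, start = sort(starts)
              )
            }
            break
          }
          if (attempt == 100L) {
            stop_config("could not plant motifs without collisions; relax the design")
          }
        }
      }
    }
    out <- dplyr::bind_rows(records)
    attr(out, "truth") <- if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(receptor_id = character(), motif = character(),
                     start = integer())
    out
  })
}

# sample nm non-overlapping 1-based starts for a motif of length plen in a
# segment of length L, under a placement rule on relative position
draw_starts <- function(nm, L, plen, place) {
  if (L < plen) return(NULL)
  all_starts <- seq_len(L - plen + 1L)
  relpos <- if (L > 1L) (all_starts - 1L) / (L - 1L) else rep(0, length(all_starts))
  allowed <- switch(place,
    central = all_starts[relpos >= 0.35 & relpos <= 0.65],
    peripheral = all_starts[relpos <= 0.15 | relpos >= 0.85],
    random = all_starts,
    stop_config(paste0("unknown placement rule: ", place))
  )
  starts <- integer(0)
  pool <- allowed
  for (j in seq_len(nm)) {
    if (length(pool) == 0L) return(NULL)
    s <- if (length(pool) == 1L) pool else sample(pool, 1L)
    starts <- c(starts, s)
    pool <- pool[abs(pool - s) >= plen]   # keep plantings non-overlapping
  }
  starts
}
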