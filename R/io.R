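PLATE_COLUMNS <- c("well_id", "condition", "receptor", "arrestin",
                   "grk_label", "role", "concentration_M", "replicate",
                   "time_s", "donor", "acceptor")

#' Default run configuration
#'
#' All tunable analysis settings with their documented defaults: acquisition
#' windows, decision alpha, gate test, fit mode, mock-correction mode,
#' heatmap transform cap, clustering linkage and motif conventions.
#'
#' @param ... named overrides of individual defaults.
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    baseline_duration = 180, stim_duration = 300,
    alpha = 0.05,
    gate_test = "student_one_sided",
    fit_mode = "per_experiment", hill = "fixed", hill_value = 1,
    mock_mode = "per_timepoint",
    heatmap_cap = 16, linkage = "complete",
    motif_overlap = TRUE, position_convention = "first_over_Lm1",
    central_lower = 0.25, central_upper = 0.75,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop_config(paste0("unknown configuration field(s): ",
                       paste(unknown, collapse = ", ")))
  }
  utils::modifyList(cfg, over)
}

#' Write / read a long-format plate CSV
#'
#' The plate schema is a long/tidy CSV (one row per well and timepoint) with
#' a `#`-prefixed header block declaring the stimulation time and window
#' durations. `write_plate_csv()` and `read_plate_csv()` round-trip the
#' table and its timing attributes exactly.
#'
#' @param plate plate tibble (see [simulate_bret_plate()]).
#' @param path file path.
#' @return `read_plate_csv()` returns the validated plate tibble with timing
#'   attributes; `write_plate_csv()` returns `path` invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  hdr <- c("# grkselect plate v1",
           paste0("# stimulation_time_s: ", attr(plate, "stimulation_time_s")),
           paste0("# baseline_duration_s: ", attr(plate, "baseline_duration_s")),
           paste0("# stim_duration_s: ", attr(plate, "stim_duration_s")))
  writeLines(hdr, path)
  readr::write_csv(plate[, PLATE_COLUMNS], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such file: ", path))
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    as.numeric(sub(".*:\\s*", "", m[1]))
  }
  tab <- readr::read_csv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tab) == 0L) stop_data(paste0("empty plate file: ", path))
  missing <- setdiff(PLATE_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    stop_data(paste0("plate file lacks column(s): ",
                     paste(missing, collapse = ", ")))
  }
  tab <- tab[, PLATE_COLUMNS]
  for (col in c("concentration_M", "time_s", "donor", "acceptor")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0L) {
      stop_data(paste0("non-numeric '", col, "' in data row(s) ",
                       paste(utils::head(bad, 5), collapse = ", ")))
    }
    tab[[col]] <- v
  }
  tab$replicate <- as.integer(tab$replicate)
  dup <- duplicated(tab[, c("well_id", "time_s")])
  if (any(dup)) {
    stop_data(paste0("duplicate (well_id, time_s) in data row(s) ",
                     paste(utils::head(which(dup), 5), collapse = ", ")))
  }
  role_per_well <- tapply(tab$role, tab$well_id,
                          function(x) length(unique(x)))
  if (any(role_per_well > 1L)) {
    stop_data("wells with inconsistent roles across timepoints")
  }
  if (!all(tab$role %in% c("sample", "mock", "vehicle"))) {
    stop_data("role must be one of sample, mock, vehicle")
  }
  out <- tibble::as_tibble(tab)
  attr(out, "stimulation_time_s") <- get_num("stimulation_time_s")
  attr(out, "baseline_duration_s") <- get_num("baseline_duration_s")
  attr(out, "stim_duration_s") <- get_num("stim_duration_s")
  out
}

KNOWN_GROUPS <- c("GRK2/3", "GRK2/3/5/6", "unclassified", "pre-coupling")

#' Write / read receptor segment sets as FASTA
#'
#' FASTA headers follow `receptorID|segment|group|class`. On reading,
#' lower-case sequences are upper-cased with a warning and unknown group
#' labels are mapped to `"unclassified"` with a warning.
#'
#' @param segments segment tibble (`receptor_id, segment_kind, sequence,
#'   group_label, receptor_class`).
#' @param path file path.
#' @return `read_segments_fasta()` returns the segment tibble;
#'   `write_segments_fasta()` returns `path` invisibly.
#' @export
write_segments_fasta <- function(segments, path) {
  seqs <- Biostrings::AAStringSet(segments$sequence)
  names(seqs) <- paste(segments$receptor_id, segments$segment_kind,
                       segments$group_label, segments$receptor_class,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_segments_fasta
#' @export
read_segments_fasta <- function(path) {
  if (!file.exists(path)) stop_data(paste0("no such file: ", path))
  seqs <- Biostrings::readBStringSet(path)   # BString keeps the original case
  if (length(seqs) == 0L) stop_data(paste0("empty FASTA: ", path))
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad) > 0L) {
    stop_data(paste0("malformed FASTA header (need receptorID|segment|group|class): ",
                     names(seqs)[bad[1]]))
  }
  hdr <- do.call(rbind, fields)
  sequence <- unname(as.character(seqs))
  if (any(grepl("[a-z]", sequence))) {
    warn("lower-case residues found; sequences were upper-cased")
    sequence <- toupper(sequence)
  }
  group <- hdr[, 3]
  unknown <- !group %in% KNOWN_GROUPS
  if (any(unknown)) {
    warn(paste0("unknown group label(s) mapped to 'unclassified': ",
                paste(unique(group[unknown]), collapse = ", ")))
    group[unknown] <- "unclassified"
  }
  out <- tibble::tibble(receptor_id = hdr[, 1], segment_kind = hdr[, 2],
                        sequence = sequence, group_label = group,
                        receptor_class = hdr[, 4])
  for (i in seq_len(nrow(out))) {
    validate_sequence(out$sequence[i], out$receptor_id[i])
  }
  out
}
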