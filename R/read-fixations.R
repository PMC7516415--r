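#' Default column-name schema for fixation exports
#'
#' Maps the logical fields the pipeline needs to the column names used in
#' the delimited export. Override individual entries to adapt to a
#' tracker's naming.
#'
#' @return Named character vector (logical name -> file column name).
#' @export
fixation_schema <- function(participant = "participant",
                            scenario = "scenario",
                            alignment = "alignment",
                            start_ms = "fixation_start_ms",
                            duration_ms = "fixation_duration_ms",
                            end_ms = "fixation_end_ms",
                            pos_x = "position_x",
                            pos_y = "position_y") {
  c(participant = participant, scenario = scenario, alignment = alignment,
    start_ms = start_ms, duration_ms = duration_ms, end_ms = end_ms,
    pos_x = pos_x, pos_y = pos_y)
}

#' Read a fixation table from delimited text
#'
#' Reads a comma- or tab-delimited export with one row per fixation,
#' carrying start (ms), duration (ms), end (ms), 2-D position, and the
#' participant / scenario / alignment trial labels. Records are validated
#' (positive duration, `end = start + duration`, strict time ordering and
#' no overlap within a trial) and sorted by
#' (participant, scenario, alignment, start).
#'
#' @param path Path to the delimited file. The delimiter (comma or tab) is
#'   inferred from the header line.
#' @param schema Column-name map from [fixation_schema()].
#' @param drop_invalid If `TRUE`, rows failing row-level validation are
#'   dropped with a warning listing their line numbers instead of aborting.
#'   Trial-level ordering/overlap violations always abort.
#' @return Tibble with columns `participant`, `scenario`, `alignment`,
#'   `start_ms`, `duration_ms`, `end_ms`, `pos_x`, `pos_y`.
#' @export
read_fixations <- function(path, schema = fixation_schema(),
                           drop_invalid = FALSE) {
  if (!file.exists(path)) stop("fixation file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0) {
    stop("fixation file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- tibble::tibble(
    participant = raw[[schema[["participant"]]]],
    scenario    = raw[[schema[["scenario"]]]],
    alignment   = raw[[schema[["alignment"]]]],
    start_ms    = suppressWarnings(as.numeric(raw[[schema[["start_ms"]]]])),
    duration_ms = suppressWarnings(as.numeric(raw[[schema[["duration_ms"]]]])),
    end_ms      = suppressWarnings(as.numeric(raw[[schema[["end_ms"]]]])),
    pos_x       = suppressWarnings(as.numeric(raw[[schema[["pos_x"]]]])),
    pos_y       = suppressWarnings(as.numeric(raw[[schema[["pos_y"]]]]))
  )
  if (nrow(dat) == 0) {
    warning("fixation file contains a header but no rows: ", path,
            call. = FALSE)
    return(.finalize_fixations(dat))
  }
  line <- seq_len(nrow(dat)) + 1L  # header is line 1
  bad_numeric <- !stats::complete.cases(
    dat[, c("start_ms", "duration_ms", "end_ms", "pos_x", "pos_y")])
  bad_duration <- !bad_numeric & dat$duration_ms <= 0
  bad_end <- !bad_numeric &
    abs(dat$end_ms - (dat$start_ms + dat$duration_ms)) > 1e-9
  bad <- bad_numeric | bad_duration | bad_end
  if (any(bad)) {
    msgs <- c(
      if (any(bad_numeric)) paste0("non-numeric timing/position at line(s) ",
                                   paste(line[bad_numeric], collapse = ", ")),
      if (any(bad_duration)) paste0("non-positive duration at line(s) ",
                                    paste(line[bad_duration], collapse = ", ")),
      if (any(bad_end)) paste0("end_ms != start_ms + duration_ms at line(s) ",
                               paste(line[bad_end], collapse = ", "))
    )
    if (drop_invalid) {
      warning("dropping ", sum(bad), " invalid fixation row(s): ",
              paste(msgs, collapse = "; "), call. = FALSE)
      dat <- dat[!bad, , drop = FALSE]
    } else {
      stop("invalid fixation row(s): ", paste(msgs, collapse = "; "),
           call. = FALSE)
    }
  }
  dat <- .finalize_fixations(dat)
  .check_trial_ordering(dat)
  dat
}

.finalize_fixations <- function(dat) {
  bad_scen <- setdiff(unique(dat$scenario), .scenario_levels)
  if (length(bad_scen) > 0) {
    stop("unknown scenario label(s): ", paste(bad_scen, collapse = ", "),
         " (expected ", paste(.scenario_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_align <- setdiff(unique(dat$alignment), .alignment_levels)
  if (length(bad_align) > 0) {
    stop("unknown alignment label(s): ", paste(bad_align, collapse = ", "),
         " (expected ", paste(.alignment_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  dat$scenario <- factor(dat$scenario, levels = .scenario_levels)
  dat$alignment <- factor(dat$alignment, levels = .alignment_levels)
  dplyr::arrange(dat, .data$participant, .data$scenario, .data$alignment,
                 .data$start_ms)
}

# strict ordering and no overlap within each trial (after sorting)
.check_trial_ordering <- function(dat) {
  bad <- dat |>
    dplyr::group_by(.data$participant, .data$scenario, .data$alignment) |>
    dplyr::summarise(
      ok = dplyr::n() < 2 ||
        (all(diff(.data$start_ms) > 0) &&
           all(head(.data$end_ms, -1) <= tail(.data$start_ms, -1))),
      .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    trials <- paste(bad$participant, bad$scenario, bad$alignment, sep = "/")
    stop("overlapping or non-increasing fixations in trial(s): ",
         paste(trials, collapse = "; "), call. = FALSE)
  }
  invisible(dat)
}

.fixation_cols <- c("participant", "scenario", "alignment", "start_ms",
                    "duration_ms", "end_ms", "pos_x", "pos_y")

.check_fixation_cols <- function(dat, labelled = FALSE) {
  need <- c(.fixation_cols, if (labelled) "aoi_label")
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0) {
    stop("fixation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(dat)
}

#' Write and re-read a labelled fixation table
#'
#' Round-trip helpers: the written file reproduces identical records when
#' read back with [read_labeled_table()].
#'
#' @param table Labelled fixation tibble from [label_table()].
#' @param path Output path (tab-delimited).
#' @export
write_labeled_table <- function(table, path) {
  .check_fixation_cols(table, labelled = TRUE)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_labeled_table
#' @export
read_labeled_table <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    participant = readr::col_character(),
    scenario = readr::col_character(),
    alignment = readr::col_character(),
    start_ms = readr::col_double(),
    duration_ms = readr::col_double(),
    end_ms = readr::col_double(),
    pos_x = readr::col_double(),
    pos_y = readr::col_double(),
    aoi_label = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  dat$scenario <- factor(dat$scenario, levels = .scenario_levels)
  dat$alignment <- factor(dat$alignment, levels = .alignment_levels)
  dat$aoi_label <- factor(dat$aoi_label, levels = aoi_areas)
  dat
}
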