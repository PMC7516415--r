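#' Per-area fixation durations and dwell proportions
#'
#' For every trial (participant x scenario x alignment) sums fixation
#' durations per area, `T_s = sum_i t_i`, over all six areas (the five AOIs
#' plus white space), and computes the dwell proportion
#' `beta_s = T_s / T_total`. Unlike the entropy stage, white space counts
#' here: the six proportions sum to one.
#'
#' Durations are integer milliseconds and the per-area totals are exact
#' integer sums; only the proportions are fractional.
#'
#' @param table Labelled fixation tibble from [label_table()].
#' @return Long tibble with one row per trial x area: `participant`,
#'   `scenario`, `alignment`, `area`, `T_ms`, `T_total_ms`, `beta`.
#'   Areas never visited in a trial get `T_ms = 0`, `beta = 0`.
#' @export
area_durations <- function(table) {
  .check_fixation_cols(table, labelled = TRUE)
  if (nrow(table) == 0) {
    warning("empty fixation table; returning empty dwell summary",
            call. = FALSE)
    return(tibble::tibble(participant = character(), scenario = factor(),
                          alignment = factor(),
                          area = factor(levels = aoi_areas),
                          T_ms = numeric(), T_total_ms = numeric(),
                          beta = numeric()))
  }
  out <- table |>
    dplyr::group_by(.data$participant, .data$scenario, .data$alignment,
                    area = factor(.data$aoi_label, levels = aoi_areas)) |>
    dplyr::summarise(T_ms = sum(.data$duration_ms), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("participant"), !!rlang::sym("scenario"),
                     !!rlang::sym("alignment")),
      area = factor(aoi_areas, levels = aoi_areas),
      fill = list(T_ms = 0)) |>
    dplyr::group_by(.data$participant, .data$scenario, .data$alignment) |>
    dplyr::mutate(T_total_ms = sum(.data$T_ms),
                  beta = ifelse(.data$T_total_ms > 0,
                                .data$T_ms / .data$T_total_ms, NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant, .data$scenario, .data$alignment,
                   .data$area)
  zero <- dplyr::filter(out, .data$T_total_ms == 0)
  if (nrow(zero) > 0) {
    warning("trial(s) with zero total fixation time: proportions undefined",
            call. = FALSE)
  }
  out
}

#' Write a dwell-proportion report
#'
#' Writes the long-format dwell table to tab-delimited text, with the
#' proportion also rendered as a percentage string (one decimal place).
#'
#' @param summaries Dwell tibble from [area_durations()].
#' @param path Output file path; `NULL` to skip writing.
#' @return The report tibble, invisibly.
#' @export
dwell_report <- function(summaries, path = NULL) {
  if (nrow(summaries) == 0) {
    warning("no dwell summaries to report", call. = FALSE)
    report <- summaries
  } else {
    report <- dplyr::mutate(
      summaries,
      beta = round(.data$beta, 3),
      percent = ifelse(is.na(.data$beta), NA_character_,
                       sprintf("%.1f%%", 100 * .data$beta)))
  }
  if (!is.null(path)) readr::write_tsv(report, path, progress = FALSE)
  invisible(report)
}

#' Ring chart of dwell proportions per condition
#'
#' Optional visual summary: one stacked ring per participant, facetted by
#' scenario x alignment. Requires ggplot2.
#'
#' @param summaries Dwell tibble from [area_durations()].
#' @return A ggplot object.
#' @export
dwell_plot <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("dwell_plot() requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$participant, y = .data$beta,
                               fill = .data$area)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$scenario),
                        cols = ggplot2::vars(.data$alignment)) +
    ggplot2::labs(x = NULL, y = "dwell proportion", fill = "area")
}
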