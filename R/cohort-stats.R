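#' Two-way fixed-effects ANOVA on an entropy table
#'
#' Fits `value ~ scenario * alignment` on the per-trial entropies, treating
#' every trial as an independent observation (all 189 observations of a
#' full 21 x 3 x 3 cohort enter one between-style two-way ANOVA; the design
#' being balanced, Type I/II/III sums of squares coincide). Although each
#' participant contributes to all nine cells, participant is deliberately
#' not a factor: the comparison model of record uses residual df
#' `N - ab` (180 for the full cohort). Partial eta squared is
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param table Entropy tibble from [trial_entropy()] or
#'   [read_entropy_table()]. Flagged trials are excluded first.
#' @param variable Dependent variable: `"Ht"` or `"Hs"`.
#' @return Tibble of class `anova_result` with one row per effect
#'   (`scenario`, `alignment`, `scenario:alignment`, `Residuals`):
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`, `partial_eta_sq`.
#' @export
two_way_anova <- function(table, variable = c("Ht", "Hs")) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_bits")
  if (!col %in% names(table)) {
    stop("entropy table has no column ", col, call. = FALSE)
  }
  if ("flagged" %in% names(table)) {
    table <- table[!table$flagged, , drop = FALSE]
  }
  dat <- data.frame(
    value = table[[col]],
    scenario = factor(table$scenario),
    alignment = factor(table$alignment))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  cells <- table(dat$scenario, dat$alignment)
  if (length(unique(as.vector(cells))) != 1 || any(cells == 0)) {
    stop("unbalanced design: unequal cell counts\n",
         paste(utils::capture.output(print(cells)), collapse = "\n"),
         call. = FALSE)
  }
  if (nrow(dat) <= nlevels(dat$scenario) * nlevels(dat$alignment)) {
    stop("no residual degrees of freedom: need more than one observation ",
         "per cell", call. = FALSE)
  }
  fit <- stats::aov(value ~ scenario * alignment, data = dat)
  tab <- summary(fit)[[1]]
  effects <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  # a constant response leaves only floating-point dust in the SS; report
  # it as the degenerate zero-variance case rather than 0/0 ratios
  if (sum(ss) < 1e-18 * max(1, sum(dat$value^2))) {
    ss <- rep(0, length(ss))
  }
  is_res <- effects == "Residuals"
  ss_res <- ss[is_res]
  df <- tab[["Df"]]
  ms <- ss / df
  Fval <- if (ss_res > 0) ms / (ss_res / df[is_res]) else rep(0, length(ss))
  Fval[is_res] <- NA_real_
  eta <- ifelse(ss + ss_res > 0, ss / (ss + ss_res), 0)
  eta[is_res] <- NA_real_
  p <- tab[["Pr(>F)"]]
  p[is_res] <- NA_real_
  out <- tibble::tibble(effect = effects, df = df, sum_sq = ss,
                        mean_sq = ms, F = Fval, p = p,
                        partial_eta_sq = eta)
  attr(out, "variable") <- variable
  class(out) <- c("anova_result", class(out))
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA on", attr(x, "variable"), "(bits)\n")
  df_res <- x$df[x$effect == "Residuals"]
  for (i in which(x$effect != "Residuals")) {
    cat(sprintf("  %-20s F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                x$effect[i], x$df[i], df_res, x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  }
  cat(sprintf("  %-20s df = %d, MS = %.5f\n", "Residuals", df_res,
              x$mean_sq[x$effect == "Residuals"]))
  invisible(x)
}

#' Pairwise scenario-dominance percentage
#'
#' For one alignment and one entropy variable, the percentage of
#' participants whose value is strictly smaller under the first scenario of
#' `pair` than under the second, rounded to the nearest integer percent.
#' Ties count as "not smaller". Participants missing either arm are
#' excluded with a message.
#'
#' @param table Entropy tibble (flagged trials excluded automatically).
#' @param pair Character vector of two scenario labels, first vs second.
#' @param alignment Alignment label.
#' @param variable `"Ht"` or `"Hs"`.
#' @return One-row tibble: `scenario_small`, `scenario_large`, `alignment`,
#'   `variable`, `n_pairs`, `n_smaller`, `percent`.
#' @export
dominance <- function(table, pair, alignment, variable = c("Ht", "Hs")) {
  variable <- match.arg(variable)
  col <- paste0(variable, "_bits")
  stopifnot(length(pair) == 2)
  if ("flagged" %in% names(table)) {
    table <- table[!table$flagged, , drop = FALSE]
  }
  sub <- table[table$alignment == alignment &
                 table$scenario %in% pair, , drop = FALSE]
  a <- sub[sub$scenario == pair[1], c("participant", col)]
  b <- sub[sub$scenario == pair[2], c("participant", col)]
  names(a)[2] <- "first"; names(b)[2] <- "second"
  merged <- dplyr::inner_join(a, b, by = "participant")
  dropped <- setdiff(union(a$participant, b$participant),
                     merged$participant)
  if (length(dropped) > 0) {
    message("dominance: excluding participant(s) missing one arm: ",
            paste(dropped, collapse = ", "))
  }
  if (nrow(merged) == 0) {
    stop("no paired participants for scenarios ", pair[1], " vs ", pair[2],
         " at alignment ", alignment, call. = FALSE)
  }
  n_smaller <- sum(merged$first < merged$second)
  tibble::tibble(
    scenario_small = pair[1], scenario_large = pair[2],
    alignment = alignment, variable = variable,
    n_pairs = nrow(merged), n_smaller = n_smaller,
    percent = round(100 * n_smaller / nrow(merged)))
}

#' All pairwise dominance summaries of an entropy table
#'
#' Runs [dominance()] for each ordered scenario pair given, each alignment
#' present, and both entropy variables.
#'
#' @param table Entropy tibble.
#' @param pairs List of scenario pairs; defaults to A-B, A-C, B-C.
#' @return Tibble with one row per pair x alignment x variable.
#' @export
dominance_grid <- function(table,
                           pairs = list(c("A", "B"), c("A", "C"),
                                        c("B", "C"))) {
  alignments <- as.character(unique(table$alignment))
  rows <- list()
  for (p in pairs) {
    for (al in alignments) {
      for (v in c("Ht", "Hs")) {
        rows[[length(rows) + 1]] <- dominance(table, p, al, v)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a combined group-statistics report
#'
#' Produces a human-readable text report of the ANOVA results (one
#' `F(dfn,dfd) = ..., p = ..., partial eta^2 = ...` line per effect) and
#' the dominance percentages, plus machine-readable TSVs alongside.
#'
#' @param anovas List of `anova_result` objects.
#' @param dominances Dominance tibble from [dominance_grid()] (or `NULL`).
#' @param path Base path for the text report; `<path>.anova.tsv` and
#'   `<path>.dominance.tsv` are written next to it. `NULL` to skip files.
#' @return Character vector of report lines, invisibly.
#' @export
stats_report <- function(anovas, dominances = NULL, path = NULL) {
  lines <- character()
  if (length(anovas) == 0 &&
      (is.null(dominances) || nrow(dominances) == 0)) {
    warning("no statistics to report", call. = FALSE)
  }
  for (a in anovas) {
    lines <- c(lines, utils::capture.output(print(a)), "")
  }
  if (!is.null(dominances) && nrow(dominances) > 0) {
    lines <- c(lines, "Pairwise scenario dominance (strictly smaller):")
    lines <- c(lines, sprintf(
      "  %s: %d%% of %d participants had smaller %s under scenario %s than %s",
      dominances$alignment, dominances$percent, dominances$n_pairs,
      dominances$variable, dominances$scenario_small,
      dominances$scenario_large))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    if (length(anovas) > 0) {
      tab <- dplyr::bind_rows(lapply(anovas, function(a) {
        dplyr::mutate(tibble::as_tibble(a), variable = attr(a, "variable"),
                      .before = 1)
      }))
      readr::write_tsv(tab, paste0(path, ".anova.tsv"), progress = FALSE)
    }
    if (!is.null(dominances) && nrow(dominances) > 0) {
      readr::write_tsv(dominances, paste0(path, ".dominance.tsv"),
                       progress = FALSE)
    }
  }
  invisible(lines)
}
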