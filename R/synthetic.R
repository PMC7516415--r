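#' Condition templates for the synthetic cohort
#'
#' One template per scenario x alignment cell. Each template is built as
#' `P = (1 - m) I + m 1 q'`: from any AOI the gaze stays put with
#' probability `1 - m` and otherwise redraws from the condition's visit
#' profile `q`. This construction makes `q` exactly the stationary
#' distribution of `P`, so the template's true entropies are closed-form
#' from `q` and `m`.
#'
#' The profiles and switch rates encode the qualitative structure the
#' analysis is meant to detect: scenario A is pavement-dominant with the
#' lowest entropies, B splits attention between pavement and central area,
#' C is central-area/top-wall dominant with the highest entropies; straight
#' sections have higher switch rates and flatter profiles than curves; and
#' the inner wall (LW on left curves, RW on right curves) receives elevated
#' mass. The numeric values are package conventions, chosen to be realistic
#' for tunnel driving, not measurements.
#'
#' @return Named list of 9 `scenario_template` objects, keyed
#'   `"<scenario>_<alignment>"`. Each has fields `scenario`, `alignment`,
#'   `q` (visit profile over [aoi_states]), `switch_rate` and `P`.
#' @export
make_templates <- function() {
  # curve profiles are markedly more concentrated than straight ones (the
  # inner wall anchors gaze on curves), making alignment the strongest
  # effect on both entropies, ahead of the delineator scenarios
  profile <- list(
    A_straight    = c(PA = .60, RW = .07, LW = .07, TW = .08, CA = .18),
    A_left_curve  = c(PA = .70, RW = .03, LW = .12, TW = .04, CA = .11),
    A_right_curve = c(PA = .70, RW = .12, LW = .03, TW = .04, CA = .11),
    B_straight    = c(PA = .42, RW = .08, LW = .08, TW = .10, CA = .32),
    B_left_curve  = c(PA = .52, RW = .04, LW = .14, TW = .06, CA = .24),
    B_right_curve = c(PA = .52, RW = .14, LW = .04, TW = .06, CA = .24),
    C_straight    = c(PA = .16, RW = .09, LW = .09, TW = .30, CA = .36),
    C_left_curve  = c(PA = .10, RW = .03, LW = .15, TW = .38, CA = .34),
    C_right_curve = c(PA = .10, RW = .15, LW = .03, TW = .38, CA = .34))
  switch_rate <- c(
    A_straight = .60, A_left_curve = .38, A_right_curve = .38,
    B_straight = .68, B_left_curve = .46, B_right_curve = .46,
    C_straight = .76, C_left_curve = .54, C_right_curve = .54)
  out <- lapply(names(profile), function(key) {
    parts <- strsplit(key, "_")[[1]]
    q <- profile[[key]][aoi_states]
    m <- switch_rate[[key]]
    P <- (1 - m) * diag(5) + m * matrix(q, 5, 5, byrow = TRUE)
    dimnames(P) <- list(aoi_states, aoi_states)
    structure(
      list(scenario = parts[1],
           alignment = paste(parts[-1], collapse = "_"),
           q = q, switch_rate = m, P = P),
      class = "scenario_template")
  })
  stats::setNames(out, names(profile))
}

#' True entropies of a transition matrix
#'
#' Computes the generator-truth `Ht` and `Hs` of a row-stochastic matrix
#' using its stationary distribution (via [stationary_eigen()]). For a
#' [make_templates()] template this is the value the plug-in estimator
#' converges to as the simulated sequence grows.
#'
#' @param P Row-stochastic matrix, or a `scenario_template`.
#' @return Named numeric vector `c(Ht, Hs)` in bits.
#' @export
true_entropy <- function(P) {
  if (inherits(P, "scenario_template")) P <- P$P
  pi <- stationary_eigen(P)
  c(Ht = transition_entropy(P, pi, tol = 1e-9),
    Hs = stationary_entropy(pi, tol = 1e-9))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the analysis assumes: 21 participants,
#' 3 delineator scenarios x 3 tunnel alignments, about 120 fixations per
#' trial (Poisson-jittered), lognormal fixation durations with a median
#' near 300 ms, a small white-space insertion rate, and Dirichlet
#' row-perturbation of the condition templates for inter-participant
#' spread.
#'
#' @param n_participants Number of participants (default 21).
#' @param n_fix_mean Mean fixations per trial before WS insertion.
#' @param concentration Dirichlet concentration for perturbing template
#'   rows: row' ~ Dirichlet(concentration * row). Larger values give less
#'   inter-participant variation; `Inf` disables perturbation.
#' @param ws_prob Probability of inserting a white-space fixation after
#'   each AOI fixation (dashboard glances).
#' @param duration_meanlog,duration_sdlog Lognormal parameters of fixation
#'   duration in ms (defaults: median 300 ms, sdlog 0.4).
#' @param layout AOI layout used to draw fixation positions.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_participants = 21, n_fix_mean = 120,
                          concentration = 200, ws_prob = 0.05,
                          duration_meanlog = log(300), duration_sdlog = 0.4,
                          layout = default_aoi_layout(), seed = 1L) {
  stopifnot(n_participants >= 1, n_fix_mean >= 2,
            concentration > 0, ws_prob >= 0, ws_prob < 1,
            duration_sdlog >= 0, inherits(layout, "aoi_layout"))
  structure(
    list(n_participants = as.integer(n_participants),
         n_fix_mean = n_fix_mean, concentration = concentration,
         ws_prob = ws_prob, duration_meanlog = duration_meanlog,
         duration_sdlog = duration_sdlog, layout = layout,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Dirichlet perturbation of each row of a transition matrix
.perturb_matrix <- function(P, concentration) {
  if (!is.finite(concentration)) return(P)
  out <- t(apply(P, 1, function(row) {
    g <- stats::rgamma(length(row), shape = concentration * row, rate = 1)
    if (sum(g) == 0) row else g / sum(g)
  }))
  dimnames(out) <- dimnames(P)
  out
}

# sample a Markov chain of AOI indices; start from the stationary law of P
.sample_chain <- function(P, n) {
  k <- nrow(P)
  start <- stationary_eigen(P)
  x <- integer(n)
  x[1] <- sample.int(k, 1, prob = start)
  for (t in seq_len(n - 1)) {
    x[t + 1] <- sample.int(k, 1, prob = P[x[t], ])
  }
  x
}

# uniform points inside a polygon by bounding-box rejection
.sample_in_polygon <- function(v, n) {
  if (n == 0) return(cbind(numeric(0), numeric(0)))
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2 * (n - length(xs)), 16)
    cx <- runif(m, xr[1], xr[2]); cy <- runif(m, yr[1], yr[2])
    keep <- pracma::inpolygon(cx, cy, v[, 1], v[, 2], boundary = FALSE)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

# uniform points assigned to WS (outside all five regions)
.sample_in_ws <- function(layout, n) {
  if (n == 0) return(cbind(numeric(0), numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(4 * (n - length(xs)), 32)
    cx <- runif(m, 0, layout$frame_width)
    cy <- runif(m, 0, layout$frame_height)
    keep <- assign_fixation(cx, cy, layout) == "WS"
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Simulate one trial's fixation records
#'
#' Draws an AOI chain of `n_fix` fixations from the template's transition
#' matrix (or a supplied perturbed matrix), starting from its stationary
#' distribution; attaches lognormal integer-ms durations, saccade gaps,
#' and positions drawn uniformly inside each fixation's AOI polygon; and
#' optionally interleaves white-space fixations. Timestamps satisfy
#' `end = start + duration` with positive gaps between fixations.
#'
#' @param template A `scenario_template` from [make_templates()].
#' @param n_fix Number of AOI fixations (>= 2), before WS insertion.
#' @param P Optional perturbed transition matrix to sample from instead of
#'   `template$P`.
#' @param layout AOI layout for position sampling.
#' @param ws_prob Per-fixation probability of a following WS fixation.
#' @param duration_meanlog,duration_sdlog Lognormal duration parameters.
#' @param participant Participant id stamped on the records.
#' @param seed Optional integer seed for this trial.
#' @return Fixation tibble in the [read_fixations()] layout.
#' @export
simulate_trial <- function(template, n_fix = 120, P = NULL,
                           layout = default_aoi_layout(), ws_prob = 0.05,
                           duration_meanlog = log(300),
                           duration_sdlog = 0.4,
                           participant = "P01", seed = NULL) {
  stopifnot(inherits(template, "scenario_template"))
  if (!is.numeric(n_fix) || n_fix < 2) {
    stop("n_fix must be at least 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(P)) P <- template$P
  idx <- .sample_chain(P, n_fix)
  labels <- aoi_states[idx]
  # interleave WS fixations after AOI fixations
  if (ws_prob > 0) {
    ws_after <- runif(n_fix) < ws_prob
    expanded <- character(n_fix + sum(ws_after))
    pos <- 1L
    for (i in seq_len(n_fix)) {
      expanded[pos] <- labels[i]; pos <- pos + 1L
      if (ws_after[i]) { expanded[pos] <- "WS"; pos <- pos + 1L }
    }
    labels <- expanded
  }
  n_all <- length(labels)
  durations <- pmax(1, round(rlnorm(n_all, duration_meanlog, duration_sdlog)))
  gaps <- round(runif(n_all, 20, 80))  # saccade latencies, ms
  starts <- cumsum(c(0, head(durations, -1) + head(gaps, -1)))
  xy <- matrix(NA_real_, n_all, 2)
  for (area in unique(labels)) {
    rows <- which(labels == area)
    xy[rows, ] <- if (area == "WS") {
      .sample_in_ws(layout, length(rows))
    } else {
      .sample_in_polygon(layout$regions[[area]], length(rows))
    }
  }
  tibble::tibble(
    participant = participant,
    scenario = factor(template$scenario, levels = .scenario_levels),
    alignment = factor(template$alignment, levels = .alignment_levels),
    start_ms = starts,
    duration_ms = as.numeric(durations),
    end_ms = starts + durations,
    pos_x = xy[, 1],
    pos_y = xy[, 2])
}

#' Simulate a full synthetic cohort
#'
#' Generates the complete participants x scenarios x alignments fixation
#' dataset in the [read_fixations()] layout, together with a ground-truth
#' sidecar holding each trial's perturbed transition matrix entropies.
#' Per-trial transition structure is the condition template with
#' Dirichlet-perturbed rows (see [cohort_config()]); trial lengths are
#' Poisson-jittered around `n_fix_mean`.
#'
#' @param config A [cohort_config()].
#' @return List of class `gaze_cohort`: `fixations` (tibble),
#'   `truth` (tibble: participant, scenario, alignment, n_fixations,
#'   Ht_true, Hs_true), and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  templates <- make_templates()
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  fix_list <- list(); truth_list <- list()
  for (pid in ids) {
    for (tpl in templates) {
      P <- .perturb_matrix(tpl$P, config$concentration)
      n_fix <- max(10L, rpois(1, config$n_fix_mean))
      trial <- simulate_trial(
        tpl, n_fix = n_fix, P = P, layout = config$layout,
        ws_prob = config$ws_prob,
        duration_meanlog = config$duration_meanlog,
        duration_sdlog = config$duration_sdlog,
        participant = pid)
      te <- true_entropy(P)
      fix_list[[length(fix_list) + 1]] <- trial
      truth_list[[length(truth_list) + 1]] <- tibble::tibble(
        participant = pid, scenario = tpl$scenario,
        alignment = tpl$alignment, n_fixations = n_fix,
        Ht_true = te[["Ht"]], Hs_true = te[["Hs"]])
    }
  }
  structure(
    list(fixations = dplyr::bind_rows(fix_list),
         truth = dplyr::bind_rows(truth_list),
         config = config),
    class = "gaze_cohort")
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("<gaze_cohort> %d participants, %d trials, %d fixations\n",
              x$config$n_participants, nrow(x$truth), nrow(x$fixations)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `fixations.tsv` (the [read_fixations()] dialect) and
#' `truth.tsv` (the ground-truth sidecar) into a directory.
#'
#' @param cohort A `gaze_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- dplyr::rename(cohort$fixations,
                      fixation_start_ms = "start_ms",
                      fixation_duration_ms = "duration_ms",
                      fixation_end_ms = "end_ms",
                      position_x = "pos_x", position_y = "pos_y")
  readr::write_tsv(fx, file.path(dir, "fixations.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
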