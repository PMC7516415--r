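#' Extract one trial's AOI sequence
#'
#' Returns the time-ordered AOI labels of a single trial with white-space
#' fixations removed. Removal splices the sequence: a PA-WS-CA run yields a
#' direct PA -> CA transition. (Set `ws = "break"` to instead cut the
#' sequence at white space so no transition is created across it; the
#' result is then a list of segments.)
#'
#' @param table Labelled fixation tibble from [label_table()].
#' @param participant,scenario,alignment Trial key.
#' @param ws Either `"splice"` (default; drop WS and close the gap) or
#'   `"break"` (split into segments at WS).
#' @return Character vector of labels from [aoi_states] (or a list of such
#'   vectors when `ws = "break"`).
#' @export
build_sequence <- function(table, participant, scenario, alignment,
                           ws = c("splice", "break")) {
  ws <- match.arg(ws)
  .check_fixation_cols(table, labelled = TRUE)
  rows <- table[table$participant == participant &
                  table$scenario == scenario &
                  table$alignment == alignment, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no fixations for trial ", participant, "/", scenario, "/",
         alignment, call. = FALSE)
  }
  rows <- rows[order(rows$start_ms), , drop = FALSE]
  lab <- as.character(rows$aoi_label)
  if (ws == "splice") {
    return(lab[lab != "WS"])
  }
  runs <- split(lab, cumsum(lab == "WS"))
  segs <- lapply(runs, function(s) s[s != "WS"])
  segs[vapply(segs, length, 1L) > 0]
}

#' Count consecutive AOI transitions
#'
#' `n[i, j]` is the number of ordered consecutive pairs (i, j) in the
#' sequence; self-pairs count, so the diagonal is generally nonzero. A
#' sequence of length L contributes `max(L - 1, 0)` pairs.
#'
#' @param seq Character vector of AOI labels.
#' @param states State set defining matrix order (default [aoi_states]).
#' @return Integer matrix `length(states) x length(states)`.
#' @export
transition_counts <- function(seq, states = aoi_states) {
  bad <- setdiff(unique(seq), states)
  if (length(bad) > 0) {
    stop("sequence contains labels outside the state set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  from <- factor(head(seq, -1), levels = states)
  to <- factor(tail(seq, -1), levels = states)
  n <- table(from, to)
  matrix(as.integer(n), nrow = length(states), dimnames = list(states, states))
}

#' Row-normalise a transition count matrix
#'
#' Each row with a positive out-count is divided by its sum (maximum
#' likelihood estimate of the transition probabilities); all-zero rows stay
#' all-zero and are flagged in the `zero_rows` attribute. No pseudocounts
#' are applied.
#'
#' @param n Nonnegative count matrix.
#' @return Row-stochastic matrix with logical attribute `zero_rows`.
#' @export
transition_matrix <- function(n) {
  n <- as.matrix(n)
  if (any(n < 0)) stop("negative transition counts", call. = FALSE)
  rs <- rowSums(n)
  P <- n
  pos <- rs > 0
  P[pos, ] <- n[pos, , drop = FALSE] / rs[pos]
  attr(P, "zero_rows") <- stats::setNames(!pos, rownames(n))
  P
}

#' Empirical visit distribution of an AOI sequence
#'
#' `pi_i` is the fraction of fixations in AOI i over the whole sequence
#' (visit-frequency estimate of the stationary distribution).
#'
#' @inheritParams transition_counts
#' @return Named probability vector over `states`.
#' @export
stationary_empirical <- function(seq, states = aoi_states) {
  if (length(seq) == 0) {
    stop("empty sequence: visit distribution undefined", call. = FALSE)
  }
  bad <- setdiff(unique(seq), states)
  if (length(bad) > 0) {
    stop("sequence contains labels outside the state set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(seq, levels = states))
  stats::setNames(as.numeric(counts) / length(seq), states)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi P = pi` by power iteration on the lazy chain `(I + P) / 2`,
#' which shares the stationary vector of `P` but is aperiodic, so the
#' iteration converges even for periodic chains (e.g. a deterministic
#' cycle). States with all-zero rows (never left) are treated as absent.
#' If the chain restricted to its visited states has more than one closed
#' communicating class the stationary distribution is not unique and an
#' error lists the classes.
#'
#' @param P Row-stochastic matrix (zero rows allowed for unvisited states).
#' @param tol Convergence tolerance on the max-abs change per sweep.
#' @param max_iter Iteration cap.
#' @param row_tol Validation tolerance on row sums; raise it (e.g. to
#'   `0.005`) for matrices transcribed at 3-decimal precision. Rows are
#'   renormalised before iteration.
#' @return Named probability vector over the full state set (zeros on
#'   transient and absent states).
#' @export
stationary_eigen <- function(P, tol = 1e-12, max_iter = 100000L,
                             row_tol = 1e-6) {
  P <- as.matrix(P)
  if (is.null(rownames(P))) {
    rownames(P) <- colnames(P) <- paste0("s", seq_len(nrow(P)))
  }
  rs <- rowSums(P)
  visited <- rs > 0
  if (!any(visited)) stop("all-zero transition matrix", call. = FALSE)
  if (any(abs(rs[visited] - 1) > row_tol)) {
    stop("rows of P must sum to 1 (or be all zero)", call. = FALSE)
  }
  P[visited, ] <- P[visited, , drop = FALSE] / rs[visited]
  Q <- P[visited, visited, drop = FALSE]
  # mass leaking to unvisited columns would make Q substochastic
  if (any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop("transitions lead into states with no outgoing transitions; ",
         "stationary distribution undefined on the visited set",
         call. = FALSE)
  }
  classes <- .closed_classes(Q)
  if (length(classes) > 1) {
    stop("chain is reducible with multiple closed classes: ",
         paste(vapply(classes, paste, "", collapse = ","), collapse = " | "),
         call. = FALSE)
  }
  k <- nrow(Q)
  pi <- rep(1 / k, k)
  lazy <- (diag(k) + Q) / 2
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi %*% lazy)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi)) < tol) {
      pi <- nxt
      break
    }
    pi <- nxt
  }
  out <- stats::setNames(numeric(nrow(P)), rownames(P))
  out[visited] <- pi
  out
}

# closed communicating classes of a stochastic matrix (states = rows of Q)
.closed_classes <- function(Q) {
  g <- igraph::graph_from_adjacency_matrix(Q > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  classes <- split(seq_len(nrow(Q)), comp$membership)
  closed <- Filter(function(cls) {
    all(rowSums(Q[cls, -cls, drop = FALSE]) == 0) || length(cls) == nrow(Q)
  }, classes)
  lapply(closed, function(cls) rownames(Q)[cls])
}

#' Transition entropy of a fitted gaze Markov chain
#'
#' `Ht = -sum_i pi_i sum_j p_ij log2 p_ij`, in bits: the visit-weighted
#' average uncertainty of the next AOI given the current one. The
#' convention `0 * log2 0 = 0` applies, and all-zero rows contribute
#' nothing.
#'
#' @param P Row-stochastic transition matrix (all-zero rows allowed).
#' @param pi Probability vector weighting the rows.
#' @param tol Validation tolerance on row sums and on `sum(pi)`. The
#'   default suits matrices computed at full precision; raise it (e.g. to
#'   `0.005`) for matrices transcribed from 3-decimal printed values.
#' @return Transition entropy in bits.
#' @export
transition_entropy <- function(P, pi, tol = 1e-6) {
  P <- as.matrix(P)
  if (any(P < 0) || any(pi < 0)) {
    stop("negative probabilities", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(rs > 0 & abs(rs - 1) > tol)) {
    stop("P has a row summing to ", max(rs), ", outside 1 ± ", tol,
         call. = FALSE)
  }
  if (abs(sum(pi) - 1) > tol) {
    stop("pi sums to ", sum(pi), ", outside 1 ± ", tol, call. = FALSE)
  }
  row_h <- apply(P, 1, .shannon_bits)
  sum(pi * row_h)
}

#' Stationary entropy of an AOI visit distribution
#'
#' `Hs = -sum_i pi_i log2 pi_i`, in bits: the Shannon entropy of the visit
#' distribution. Higher values mean attention spread over more AOIs.
#'
#' @param pi Probability vector.
#' @param tol Validation tolerance on `sum(pi)`.
#' @return Stationary entropy in bits.
#' @export
stationary_entropy <- function(pi, tol = 1e-6) {
  if (any(pi < 0)) stop("negative probabilities", call. = FALSE)
  if (abs(sum(pi) - 1) > tol) {
    stop("pi sums to ", sum(pi), ", outside 1 ± ", tol, call. = FALSE)
  }
  .shannon_bits(pi)
}

.shannon_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

#' Per-trial transition and stationary entropy
#'
#' Runs the full Markov-entropy chain of operations for every trial in a
#' labelled fixation table: white-space exclusion, transition counts,
#' row-normalisation, visit distribution, and the two entropies. Trials
#' with fewer than two non-WS fixations have undefined entropies; they are
#' flagged (`flagged = TRUE`, entropies `NA`) and should be excluded from
#' group statistics.
#'
#' @param table Labelled fixation tibble from [label_table()].
#' @param pi_mode `"empirical"` (default): `pi` is the visit-frequency
#'   distribution of the sequence. `"eigenvector"`: `pi` solves
#'   `pi P = pi` for the fitted matrix (via [stationary_eigen()]).
#' @return An entropy table: one row per trial with columns `participant`,
#'   `scenario`, `alignment`, `n_fixations` (sequence length after WS
#'   exclusion), `Ht_bits`, `Hs_bits`, `mode`, `flagged`.
#' @export
trial_entropy <- function(table, pi_mode = c("empirical", "eigenvector")) {
  pi_mode <- match.arg(pi_mode)
  .check_fixation_cols(table, labelled = TRUE)
  keys <- dplyr::distinct(table, .data$participant, .data$scenario,
                          .data$alignment)
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    seq_i <- build_sequence(table, keys$participant[i],
                            as.character(keys$scenario[i]),
                            as.character(keys$alignment[i]))
    res[[i]] <- .sequence_entropy(seq_i, pi_mode)
  }
  out <- dplyr::bind_cols(keys, dplyr::bind_rows(res))
  if (any(out$flagged)) {
    warning(sum(out$flagged), " trial(s) with fewer than 2 non-WS ",
            "fixations: entropies undefined (flagged)", call. = FALSE)
  }
  out
}

.sequence_entropy <- function(seq, pi_mode) {
  n_fix <- length(seq)
  if (n_fix < 2) {
    return(tibble::tibble(n_fixations = n_fix, Ht_bits = NA_real_,
                          Hs_bits = NA_real_, mode = pi_mode, flagged = TRUE))
  }
  n <- transition_counts(seq)
  P <- transition_matrix(n)
  pi <- switch(pi_mode,
    empirical = stationary_empirical(seq),
    eigenvector = stationary_eigen(P))
  tibble::tibble(
    n_fixations = n_fix,
    Ht_bits = transition_entropy(P, pi),
    Hs_bits = stationary_entropy(pi),
    mode = pi_mode,
    flagged = FALSE)
}

#' Read a transition matrix or probability vector from delimited text
#'
#' Direct-entry path for precomputed models: a square matrix with state
#' labels as the first column and header, or a two-column (state, prob)
#' vector file. Tab- or comma-delimited.
#'
#' @param path File path.
#' @return Named numeric matrix / vector.
#' @export
read_transition_matrix <- function(path) {
  dat <- .read_delim_auto(path)
  m <- as.matrix(dat[, -1, drop = FALSE])
  rownames(m) <- dat[[1]]
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m))) {
    stop("transition matrix file must be square with matching state labels",
         call. = FALSE)
  }
  m[, rownames(m), drop = FALSE]
}

#' @rdname read_transition_matrix
#' @export
read_stationary_vector <- function(path) {
  dat <- .read_delim_auto(path)
  if (ncol(dat) != 2) {
    stop("stationary vector file must have two columns (state, probability)",
         call. = FALSE)
  }
  stats::setNames(as.numeric(dat[[2]]), dat[[1]])
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  as.data.frame(readr::read_delim(path, delim = delim, progress = FALSE,
                                  show_col_types = FALSE))
}

#' Write an entropy table to delimited text
#'
#' @param table Entropy tibble from [trial_entropy()].
#' @param path Output path (tab-delimited).
#' @export
write_entropy_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read an entropy table written by [write_entropy_table()]
#'
#' Also accepts transcriptions of external per-trial entropy grids laid out
#' with the same columns (`participant, scenario, alignment, Ht_bits,
#' Hs_bits`, optionally `n_fixations, mode, flagged`).
#'
#' @param path File path (tab- or comma-delimited).
#' @return Entropy tibble.
#' @export
read_entropy_table <- function(path) {
  dat <- tibble::as_tibble(.read_delim_auto(path))
  need <- c("participant", "scenario", "alignment", "Ht_bits", "Hs_bits")
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0) {
    stop("entropy table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat$participant <- as.character(dat$participant)
  dat$scenario <- factor(dat$scenario, levels = .scenario_levels)
  dat$alignment <- factor(dat$alignment, levels = .alignment_levels)
  if (!"flagged" %in% names(dat)) dat$flagged <- FALSE
  dat
}
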