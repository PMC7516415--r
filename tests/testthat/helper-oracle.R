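# Independent brute-force oracles, written with plain loops and kept
# deliberately separate from the package's vectorised implementations.

# full Markov-entropy chain of quantities for one label sequence
oracle_model <- function(seq, states) {
  k <- length(states)
  n <- matrix(0L, k, k, dimnames = list(states, states))
  if (length(seq) >= 2) {
    for (t in seq_len(length(seq) - 1)) {
      i <- match(seq[t], states)
      j <- match(seq[t + 1], states)
      n[i, j] <- n[i, j] + 1L
    }
  }
  P <- matrix(0, k, k, dimnames = list(states, states))
  for (i in seq_len(k)) {
    s <- sum(n[i, ])
    if (s > 0) for (j in seq_len(k)) P[i, j] <- n[i, j] / s
  }
  pi <- numeric(k)
  if (length(seq) > 0) {
    for (i in seq_len(k)) pi[i] <- sum(seq == states[i]) / length(seq)
  }
  h <- function(p) {
    tot <- 0
    for (v in p) if (v > 0) tot <- tot - v * log2(v)
    tot
  }
  Ht <- 0
  for (i in seq_len(k)) Ht <- Ht + pi[i] * h(P[i, ])
  list(n = n, P = P, pi = stats::setNames(pi, states), Ht = Ht, Hs = h(pi))
}

# stationary vector by direct eigendecomposition (independent of the
# package's power iteration)
oracle_stationary <- function(P) {
  P <- P / rowSums(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

# balanced two-factor ANOVA by direct sums-of-squares decomposition
oracle_anova2 <- function(y, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  gm <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2, drop = FALSE), mean)
  a <- nlevels(f1); b <- nlevels(f2); N <- length(y); r <- N / (a * b)
  ss1 <- r * b * sum((m1 - gm)^2)
  ss2 <- r * a * sum((m2 - gm)^2)
  fitted_cell <- m12[as.character(interaction(f1, f2))]
  ss_res <- sum((y - fitted_cell)^2)
  ss_tot <- sum((y - gm)^2)
  ss_int <- ss_tot - ss1 - ss2 - ss_res
  df1 <- a - 1; df2 <- b - 1; df_int <- df1 * df2; df_res <- N - a * b
  ms_res <- ss_res / df_res
  Fs <- c(ss1 / df1, ss2 / df2, ss_int / df_int) / ms_res
  list(
    ss = c(scenario = ss1, alignment = ss2, interaction = ss_int,
           residual = ss_res, total = ss_tot),
    df = c(df1, df2, df_int, df_res),
    F = Fs,
    p = stats::pf(Fs, c(df1, df2, df_int), df_res, lower.tail = FALSE),
    eta = c(ss1, ss2, ss_int) / (c(ss1, ss2, ss_int) + ss_res))
}

# every sequence of length 0..max_len over the given symbols
all_sequences <- function(symbols, max_len) {
  out <- list(character(0))
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(symbols), L), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(r) {
      unlist(grid[r, ], use.names = FALSE)
    }))
  }
  out
}

# small labelled fixation table built in code (trial key fixed)
make_labelled <- function(labels, participant = "P01", scenario = "A",
                          alignment = "straight", duration = NULL) {
  n <- length(labels)
  duration <- duration %||% rep(200, n)
  start <- cumsum(c(0, utils::head(duration, -1) + 50))
  tibble::tibble(
    participant = participant,
    scenario = factor(scenario, levels = c("A", "B", "C")),
    alignment = factor(alignment,
                       levels = c("straight", "left_curve", "right_curve")),
    start_ms = start,
    duration_ms = duration,
    end_ms = start + duration,
    pos_x = 0, pos_y = 0,
    aoi_label = factor(labels, levels = gazentropy::aoi_areas))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fixation_file <- function(df, path, delim = ",") {
  names(df)[names(df) == "start_ms"] <- "fixation_start_ms"
  names(df)[names(df) == "duration_ms"] <- "fixation_duration_ms"
  names(df)[names(df) == "end_ms"] <- "fixation_end_ms"
  names(df)[names(df) == "pos_x"] <- "position_x"
  names(df)[names(df) == "pos_y"] <- "position_y"
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  path
}
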