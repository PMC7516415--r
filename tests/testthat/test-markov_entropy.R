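test_that("build_sequence excludes white space by splicing", {
  tab <- make_labelled(c("PA", "WS", "CA"))
  expect_equal(build_sequence(tab, "P01", "A", "straight"), c("PA", "CA"))

  all_ws <- make_labelled(c("WS", "WS"))
  expect_equal(build_sequence(all_ws, "P01", "A", "straight"), character(0))

  reps <- make_labelled(c("PA", "PA", "CA"))
  expect_equal(build_sequence(reps, "P01", "A", "straight"),
               c("PA", "PA", "CA"))

  expect_error(build_sequence(tab, "P99", "A", "straight"), "P99")

  # break mode cuts at WS instead of splicing
  segs <- build_sequence(make_labelled(c("PA", "WS", "CA", "TW")),
                         "P01", "A", "straight", ws = "break")
  expect_equal(unname(lengths(segs)), c(1, 2))
  expect_equal(unname(segs[[2]]), c("CA", "TW"))
})

test_that("transition counts match hand counts, self-pairs included", {
  n <- transition_counts(c("PA", "PA", "CA", "PA"))
  expect_equal(n["PA", "PA"], 1L)
  expect_equal(n["PA", "CA"], 1L)
  expect_equal(n["CA", "PA"], 1L)
  expect_equal(sum(n), 3L)

  expect_equal(sum(transition_counts(character(0))), 0L)
  expect_equal(sum(transition_counts("PA")), 0L)

  n2 <- transition_counts(c("PA", "CA", "PA", "CA"))
  expect_equal(n2["PA", "CA"], 2L)
  expect_equal(n2["CA", "PA"], 1L)
  expect_equal(sum(n2), 3L)

  expect_error(transition_counts(c("PA", "XX")), "XX")
})

test_that("transition_matrix row-normalises and flags zero rows", {
  n <- matrix(c(2, 0, 1, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  P <- transition_matrix(n)
  expect_equal(unname(P), matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_false(any(attr(P, "zero_rows")))

  z <- transition_matrix(matrix(0, 5, 5,
                                dimnames = list(aoi_states, aoi_states)))
  expect_true(all(z == 0))
  expect_true(all(attr(z, "zero_rows")))

  # row of counts normalises to the 3-decimal row of the bundled example
  row <- matrix(c(30, 3, 2, 4, 6), 1)
  expect_equal(round(transition_matrix(row)[1, ], 3),
               c(0.667, 0.067, 0.044, 0.089, 0.133))

  expect_error(transition_matrix(matrix(-1, 2, 2)), "negative")
})

test_that("empirical visit distribution is the fixation frequency", {
  expect_equal(stationary_empirical(c("PA", "PA", "CA", "PA"))[c("PA", "CA")],
               c(PA = 0.75, CA = 0.25))
  expect_equal(unname(stationary_empirical("PA")), c(1, 0, 0, 0, 0))
  expect_equal(unname(stationary_empirical(rep(aoi_states, 3))),
               rep(0.2, 5))
  expect_error(stationary_empirical(character(0)), "empty")
})

test_that("stationary_eigen solves pi P = pi, including periodic chains", {
  P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(unname(stationary_eigen(P2)), c(0.5, 0.5), tolerance = 1e-9)

  # deterministic 5-cycle: uniform despite periodicity
  cyc <- diag(5)[, c(2:5, 1)]
  dimnames(cyc) <- list(aoi_states, aoi_states)
  expect_equal(unname(stationary_eigen(cyc)), rep(0.2, 5),
               tolerance = 1e-9)

  # random chains agree with a direct eigendecomposition oracle
  set.seed(11)
  for (rep in 1:20) {
    P <- matrix(stats::rgamma(25, 1), 5)
    P <- P / rowSums(P)
    expect_equal(unname(stationary_eigen(P)), unname(oracle_stationary(P)),
                 tolerance = 1e-8)
  }

  # fixed point property
  P <- matrix(stats::rgamma(25, 1), 5); P <- P / rowSums(P)
  pi <- stationary_eigen(P)
  expect_equal(as.numeric(pi %*% P), unname(pi), tolerance = 1e-9)

  # two absorbing states: stationary law is ambiguous
  red <- diag(2)
  dimnames(red) <- list(c("a", "b"), c("a", "b"))
  expect_error(stationary_eigen(red), "multiple closed classes")
})

test_that("entropies honour closed forms, conventions and validation", {
  uniform <- matrix(0.2, 5, 5)
  expect_equal(transition_entropy(uniform, rep(0.2, 5)), log2(5))
  # any permutation matrix is deterministic: zero transition entropy
  perm <- diag(5)[, c(3, 1, 5, 2, 4)]
  expect_equal(transition_entropy(perm, rep(0.2, 5)), 0)
  # zero rows contribute nothing
  half <- rbind(c(0.5, 0.5), c(0, 0))
  expect_equal(transition_entropy(half, c(1, 0)), 1)

  expect_equal(stationary_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(stationary_entropy(rep(0.2, 5)), log2(5))

  expect_error(transition_entropy(rbind(c(0.6, 0.6)), 1), "row summing")
  expect_error(transition_entropy(uniform, rep(0.3, 5)), "pi sums")
  expect_error(stationary_entropy(c(0.9, 0.2)), "pi sums")
  expect_error(stationary_entropy(c(1.5, -0.5)), "negative")
})

test_that("counts, P, pi and entropies agree with the brute-force oracle", {
  states3 <- c("PA", "TW", "CA")
  for (seq in all_sequences(states3, 4)) {
    got_n <- transition_counts(seq, states3)
    ora <- oracle_model(seq, states3)
    expect_identical(got_n, ora$n)
    expect_equal(transition_matrix(got_n), ora$P, ignore_attr = TRUE)
    if (length(seq) > 0) {
      pi <- stationary_empirical(seq, states3)
      expect_equal(pi, ora$pi)
      expect_equal(transition_entropy(transition_matrix(got_n), pi),
                   ora$Ht, tolerance = 1e-12)
      expect_equal(stationary_entropy(pi), ora$Hs, tolerance = 1e-12)
    }
  }
})

test_that("relabelling AOIs permutes the model but leaves entropy alone", {
  set.seed(5)
  for (rep in 1:10) {
    seq <- sample(aoi_states, 80, replace = TRUE)
    perm <- sample(aoi_states)
    relabelled <- perm[match(seq, aoi_states)]
    P1 <- transition_matrix(transition_counts(seq))
    P2 <- transition_matrix(transition_counts(relabelled))
    pi1 <- stationary_empirical(seq)
    pi2 <- stationary_empirical(relabelled)
    # model entries move with the permutation
    expect_equal(unname(P2[perm, perm]), unname(P1), ignore_attr = TRUE)
    expect_equal(unname(pi2[perm]), unname(pi1))
    # entropies are invariant
    expect_equal(transition_entropy(P2, pi2), transition_entropy(P1, pi1))
    expect_equal(stationary_entropy(pi2), stationary_entropy(pi1))
  }
})

test_that("trial_entropy runs the whole chain per trial and flags short ones", {
  tab <- dplyr::bind_rows(
    make_labelled(c("PA", "CA", "PA", "TW"), participant = "P01"),
    make_labelled(rep("PA", 6), participant = "P02"),
    make_labelled(c("WS", "PA"), participant = "P03"))
  expect_warning(et <- trial_entropy(tab), "flagged")
  expect_equal(nrow(et), 3)
  # all-PA trial: zero entropies
  expect_equal(et$Ht_bits[et$participant == "P02"], 0)
  expect_equal(et$Hs_bits[et$participant == "P02"], 0)
  # single-fixation survivor is flagged with NA entropies
  expect_true(et$flagged[et$participant == "P03"])
  expect_true(is.na(et$Ht_bits[et$participant == "P03"]))
  # P01 agrees with the oracle
  ora <- oracle_model(c("PA", "CA", "PA", "TW"), aoi_states)
  expect_equal(et$Ht_bits[et$participant == "P01"], ora$Ht)
  expect_equal(et$Hs_bits[et$participant == "P01"], ora$Hs)
})

test_that("entropy tables round-trip through disk", {
  tab <- dplyr::bind_rows(
    make_labelled(c("PA", "CA", "PA", "TW"), participant = "P01"),
    make_labelled(c("TW", "TW", "CA"), participant = "P02"))
  et <- trial_entropy(tab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_entropy_table(et, path)
  back <- read_entropy_table(path)
  expect_equal(back$Ht_bits, et$Ht_bits)
  expect_equal(as.character(back$scenario), as.character(et$scenario))
})

test_that("direct-entry readers recover the bundled reference model", {
  model <- reference_example_model()
  expect_equal(dim(model$P), c(5, 5))
  expect_equal(rownames(model$P), aoi_states)
  expect_equal(sum(model$pi), 1)
  expect_equal(model$P["PA", "CA"], 0.133)
})
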