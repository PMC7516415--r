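# gazentropy

Quantifies how drivers (or any viewers) distribute and switch visual
attention, from plain eye-tracker fixation exports. The package targets
experiments in which each trial is one cell of a participant × scenario ×
alignment design — e.g. a driving simulator crossing three tunnel
delineator configurations (A: wall + pavement delineators, B: pavement
only, C: none) with three road alignments (straight, left curve, right
curve) — but the machinery is generic to any five-AOI partition.

Two complementary per-trial summaries are computed:

* **Dwell proportions.** Each fixation is assigned to one of five areas
  of interest (pavement PA, right wall RW, left wall LW, top wall TW,
  central area CA) or to white space (WS) by polygon containment. With
  `t_i` the i-th fixation duration in area `s`, `T_s = Σ t_i` and
  `β_s = T_s / T_total` over all six areas.

* **Markov-chain gaze entropies.** The AOI sequence (WS excluded) is
  modelled as a first-order Markov chain with maximum-likelihood
  transition matrix `p_ij = n_ij / Σ_j n_ij` and visit distribution
  `π_i`. Transition entropy and stationary entropy, in bits, are

  ```
  Ht = −Σ_i π_i Σ_j p_ij log2 p_ij        Hs = −Σ_i π_i log2 π_i
  ```

  `Ht` measures how unpredictably gaze switches between AOIs; `Hs`
  measures how widely it is spread. Both are bounded by log2 5 ≈ 2.32.

Group-level comparison is a balanced two-way ANOVA (`scenario *
alignment`) with partial eta squared, plus pairwise scenario-dominance
percentages (the share of participants strictly smaller under one
scenario). A seeded synthetic-cohort generator with known ground truth
makes the whole pipeline testable without raw study data.

## Worked example

The package bundles one driver's fitted 5 × 5 transition matrix and
visit vector (straight section, full delineation), transcribed at three
decimals:

```r
library(gazentropy)
run_worked_example()
#> Ht = 1.593 bits (stationary-weighted)
#> Ht = 1.592 bits (visit-vector-weighted)
#> Hs = 2.098 bits
```

The two `Ht` lines differ only through the 3-decimal transcription of
the matrix: weighting row entropies by the matrix's own stationary
vector (the headline) reproduces the full-precision value; weighting by
the transcribed visit vector is 0.001 lower. `Hs` is the entropy of the
visit vector. See the methods vignette for the details.

A full synthetic run, end to end:

```r
cohort <- simulate_cohort(cohort_config(seed = 42))   # 21 × 3 × 3 trials
res <- run_analyze(cohort$fixations, out_dir = "out")
res$anova$Ht
#> Two-way ANOVA on Ht (bits)
#>   scenario             F(2,180) = 230.000, p = 2.62e-50, partial eta^2 = 0.719
#>   alignment            F(2,180) = 147.749, p = 1.074e-38, partial eta^2 = 0.621
#>   scenario:alignment   F(4,180) = 0.180, p = 0.9486, partial eta^2 = 0.004
#>   Residuals            df = 180, MS = 0.02494
```

Both experimental factors move transition entropy strongly (delineators
lower it — scenario A least entropic — and curves lower it relative to
straight sections), with no interaction to speak of. Dominance
summaries make the same point per participant:

```r
subset(res$dominance, variable == "Ht" & alignment == "right_curve")
#>   scenario_small scenario_large   alignment variable n_pairs n_smaller percent
#> 1              A              B right_curve       Ht      21        20      95
#> 2              A              C right_curve       Ht      21        21     100
#> 3              B              C right_curve       Ht      21        16      76
```

i.e. on the right curve 95% of synthetic participants switch less under
full delineation than under pavement-only, etc. `run_analyze()` also
writes `dwell.tsv`, `entropy.tsv`, `stats-report.txt` and a
`manifest.json` recording inputs, checksums and settings.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/gazentropy.R simulate --participants 21 --seed 1 --out cohort/
Rscript inst/cli/gazentropy.R analyze --fixations cohort/fixations.tsv --out results/
Rscript inst/cli/gazentropy.R worked-example
```

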