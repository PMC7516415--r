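---
title: "Markov-chain gaze entropy: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-chain gaze entropy: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

An eye tracker reduces viewing behaviour to an alternating sequence of
fixations and saccades. This package analyses the fixation stream of a
driving-simulator style experiment in which each trial is one cell of a
participant × scenario × alignment design: three delineator scenarios
(A: wall + pavement delineators, B: pavement only, C: none) crossed with
three road alignments (straight, left curve, right curve).

The driver's forward view is partitioned into five areas of interest
(AOIs): pavement area (PA), right wall (RW), left wall (LW), top wall
(TW) and central area (CA). Whatever is not covered by those polygons —
margins and the dashboard strip — is white space (WS).

Two complementary summaries are computed per trial.

**Dwell proportions.** With $t_i$ the duration of the $i$-th fixation in
area $s$, the per-area total is $T_s = \sum_i t_i$ and the dwell
proportion is $\beta_s = T_s / T_{total}$, computed over all **six**
areas including WS. Durations are integer milliseconds and per-area
totals are exact integer sums, so $\sum_s T_s$ equals total fixation time
exactly and $\sum_s \beta_s = 1$.

**Markov-chain entropies.** The scanpath — the ordered AOI sequence — is
modelled as a first-order Markov chain $X_t$ over the **five** AOIs (WS
excluded, see below). From consecutive-pair counts $n_{ij}$ the maximum
likelihood transition matrix is $p_{ij} = n_{ij} / \sum_j n_{ij}$, and
the visit distribution is $\pi_i = p_i / \sum_i p_i$ with $p_i$ the
fixation count in AOI $i$. The two entropies, in bits, are

$$H_t = -\sum_{i \in S} \pi_i \sum_{j \in S} p_{ij} \log_2 p_{ij},
\qquad
H_s = -\sum_{i \in S} \pi_i \log_2 \pi_i,$$

with the convention $0 \log_2 0 = 0$. $H_t$ (transition entropy) is the
average uncertainty of the next AOI given the current one: high values
mean frequent, unpredictable switching. $H_s$ (stationary entropy) is
the Shannon entropy of where gaze rests overall: high values mean
attention spread across many AOIs. Both are bounded by
$\log_2 5 \approx 2.32$ bits.

The first-order Markov assumption — the next AOI depends only on the
current one — is an approximation: real scanpaths carry longer-range
structure (e.g. systematic scan loops). The entropies should be read as
summaries of the fitted first-order model, not of the full process.

## White space, and the two stages' different scopes

The dwell stage keeps WS (its six proportions sum to one); the entropy
stage excludes it, because dashboard glances are driven by speed
monitoring rather than by the guidance facilities under study. Exclusion
is implemented as *deletion-and-splice*: WS fixations are removed and
the survivors become consecutive, so a PA–WS–CA run contributes a
PA→CA transition. This is the simplest reading of "excluded"; the
alternative — cutting the sequence at WS so no transition spans it — is
available via `build_sequence(..., ws = "break")` for sensitivity
checks. At the default WS rates involved (a few percent of fixations)
the difference is small.

Self-transitions (consecutive fixations in the same AOI) are counted,
not merged: the diagonal of a fitted matrix is typically its largest
column, and merging would conflate dwell with switching.

## Two estimates of the stationary distribution

`trial_entropy()` supports two $\pi$ modes:

* `empirical` (default): $\pi$ is the observed visit frequency. This is
  the definition used in the per-trial pipeline, needs no model
  assumptions, and is exact for the data at hand.
* `eigenvector`: $\pi$ solves $\pi P = \pi$ for the fitted matrix. This
  is the model-implied stationary law; under it the inequality
  $H_t \le H_s$ (conditioning reduces entropy) holds exactly.

For long stationary sequences the two converge; for short trials they
can differ noticeably, which is why both are first-class and the mode is
recorded in every output row.

### The bundled worked example

The package ships (in `extdata`) a 3-decimal transcription of one
driver's fitted transition matrix and visit vector on a straight,
fully-delineated section. Transcription at 3 decimals has a visible
consequence: one row sums to 1.001, and the visit-vector-weighted
$H_t$ evaluates to 1.592 bits while weighting by the transcribed
matrix's own stationary vector (which lies within 0.01 per component of
the transcribed visit vector) gives 1.593 bits — the value the
underlying full-precision model yields. `run_worked_example()` therefore
reports the stationary-weighted value as the headline and the
visit-weighted value alongside, and the file readers accept a relaxed
row-sum tolerance (`0.005`) exactly and only for such transcribed
input; internally computed matrices are validated at `1e-6`.

## Numerical choices

* **Power iteration on the lazy chain.** `stationary_eigen()` iterates
  $\pi \leftarrow \pi (I + P)/2$ to a max-abs tolerance of $10^{-12}$.
  The lazy chain has the same stationary vector as $P$ but is aperiodic,
  so the iteration also converges for periodic chains (a deterministic
  5-cycle correctly yields the uniform law). Reducible chains with more
  than one closed communicating class (detected via strongly connected
  components) are rejected as ambiguous rather than silently resolved.
* **Zero rows.** An AOI that appears only as a trial's final fixation
  has no outgoing counts. Its row stays all-zero, is flagged, and
  contributes zero row entropy; no pseudocounts or smoothing are
  applied anywhere.
* **Degenerate trials.** Trials with fewer than two non-WS fixations
  have undefined entropies; they are flagged and excluded from group
  statistics instead of propagating `NaN`.
* **Rounding.** All computation is double precision; rounding (3
  decimals for entropies and proportions) happens only at report time.

## Group statistics

`two_way_anova()` fits `value ~ scenario * alignment` with `stats::aov`
on the per-trial entropies, treating all observations as independent —
a between-style two-way ANOVA in which participant is deliberately not
a factor, so a full 21 × 3 × 3 cohort has residual df 180 and the
effects have df (2, 2, 4). This is the comparison model of record for
this design even though each participant contributes nine trials; the
report notes it, and the balanced design makes Type I/II/III sums of
squares coincide. Unbalanced inputs are rejected explicitly rather than
reinterpreted. Partial eta squared is
$SS_{effect} / (SS_{effect} + SS_{residual})$.

`dominance()` compares two scenarios within one alignment: the
percentage of participants whose entropy is *strictly* smaller under
the first scenario, rounded to the nearest integer. Ties count as "not
smaller", so the two directions of a pair sum to at most 100%.

## The synthetic cohort

No raw study data are distributable, so `simulate_cohort()` generates a
fixation dataset with the statistical structure the analysis assumes,
letting every pipeline stage be exercised end to end.

Each of the nine conditions has a template transition matrix
$P = (1-m) I + m \mathbf{1} q^\top$: gaze stays in place with
probability $1-m$ and otherwise redraws an AOI from the condition's
visit profile $q$. This construction makes $q$ exactly the stationary
law of $P$, so template truths are closed-form. Profiles and switch
rates encode the qualitative structure the method is meant to detect:

* scenario A concentrates gaze on the pavement (stationary PA mass
  0.60–0.70) and has the lowest entropies; B splits attention between
  pavement and central area; C is central-area/top-wall dominated with
  the highest entropies;
* curves concentrate gaze strongly (the inner wall anchors it — LW mass
  rises on left curves, RW on right curves) while straight sections
  leave gaze freer, so alignment is the *strongest* effect on both
  entropies, ahead of scenario — matching the effect hierarchy this
  kind of experiment produces;
* template truths order $H(A) < H(B) < H(C)$ within every alignment and
  straight > curve within every scenario, for both $H_t$ and $H_s$.

Around the templates, the generator adds (defaults in parentheses):
21 participants; per-trial Dirichlet perturbation of each template row
with concentration 200 (row$' \sim$ Dirichlet$(200 \cdot$ row$)$) — the
minimal distribution on the simplex for "participants differ modestly";
Poisson-jittered trial lengths around 120 fixations (comparable to the
~129 transitions implied by the worked example's count structure);
lognormal fixation durations with median 300 ms and sdlog 0.4 (typical
of fixation-duration literature), floored at 1 ms and kept as integer
milliseconds; uniform 20–80 ms saccade gaps; WS insertions with
probability 0.05 per fixation to exercise the exclusion path; and
positions drawn uniformly inside each fixation's AOI polygon of a
1920 × 1080 default layout, so position → label assignment round-trips.
The perturbation is drawn independently per participant × condition;
it creates inter-participant spread within each cell but no stable
participant trait shared across cells — consistent with the
between-style ANOVA above, but a simplification of real repeated
measures.

What the generator does **not** emulate: saccade kinematics, duration
differences between AOIs, serial correlation beyond first order,
learning or fatigue across the drive, and any geometry of the actual
road scene. Passing tests on synthetic data therefore validate the
*estimators and pipeline*, not claims about real drivers.

## Problem sizes used by the test suite

The suite checks the estimator's guarantees at sizes chosen to make the
checks sharp but quick: exhaustive oracle comparison over all 1,093
sequences of length ≤ 6 on a 3-AOI alphabet; bound checks on 1,000
random sequences; consistency of the plug-in estimators on single
chains of $10^5$ fixations (transition matrix recovered to max-abs
error < 0.02, entropies to < 0.01 bits); and 20 full default cohorts
(21 × 3 × 3 trials each) on consecutive seeds, of which at least 90%
must show significant scenario and alignment effects for both entropies
at $\alpha = 0.05$.

## Known limitations

* First-order model only; no bias-corrected entropy estimators are
  provided, so short-trial entropies are downward-biased (the plug-in
  bias is roughly $(\text{nonzero cells})/2n \ln 2$ bits).
* The group ANOVA ignores the repeated-measures structure by design
  (see above); a mixed-effects analysis is out of scope.
* The default AOI layout is a package convention shaped like a tunnel
  scene, not measured apparatus geometry; real analyses should supply
  their own layout file.
* Boundary points between adjacent AOIs are resolved by a configurable
  priority order (PA first by default) — a convention, since region
  edges have measure zero for real gaze data but must still be total.
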