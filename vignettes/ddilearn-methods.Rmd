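---
title: "Multi-view DDI prediction with relation regularization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view DDI prediction with relation regularization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddilearn)
```

## The prediction problem

A drug–drug interaction (DDI) network over $n$ drugs is a binary
symmetric matrix $J$ with zero diagonal; $J_{ij} = 1$ records a known
interaction. Each drug is additionally described in $m$ feature spaces
by binary incidence vectors — pathway, enzyme, target and chemical
substructure membership are the typical choices, giving feature matrices
$H^i \in \{0,1\}^{n \times n_i}$. The package addresses two tasks:

* **Goal 1** — score unobserved pairs among the $n$ networked drugs;
* **Goal 2** (cold start) — score a drug with no known interactions
  against the networked drugs, using only its feature vectors.

## Relation structure of the known network

Unknown interactions are assumed to follow the same relational patterns
as known ones. We capture those patterns with a non-negative
self-representation $M$: each drug's interaction profile (its row of
$J$) is reconstructed as a convex-like combination of the *other* drugs'
profiles,

$$\min_{M \ge 0,\ (N \odot M)e = e}\quad
  \tfrac12\lVert (N \odot M)J - J\rVert_F^2
  + \tfrac{\theta_{drr}}{2}\lVert (N \odot M)e\rVert_2^2,$$

where $N$ is the off-diagonal mask (so no drug represents itself), $e$
the all-ones vector, and $\theta_{drr}$ weighs the row-sum penalty (a
constant term $\tfrac12\lVert NJ - J\rVert^2$ is reported but does not
affect the optimization). `learn_relation()` starts from a seeded
strictly positive matrix — multiplicative updates cannot escape zeros,
so the start must be interior — and iterates the non-negativity
preserving rule implemented in `drr_update()`, whose numerator takes the
row-sum multiplier equal to $\theta_{drr}$.

Two numerical decisions matter here:

* **Constraint handling.** The multiplier update for the equality
  constraint is not uniquely determined by the stationarity conditions,
  so instead of tracking it we rescale each positive row of
  $N \odot M$ to unit sum after every sweep — this enforces
  $(N\odot M)e = e$ *exactly* for every drug with at least one known
  interaction, preserves non-negativity, and leaves the fixed points of
  the multiplicative rule unchanged.
* **Monotone stopping.** Rescaling is a projection, not a descent step,
  and very close to the optimum a rescaled sweep can raise the
  constrained objective slightly. A sweep is therefore accepted only if
  it lowers the objective; the first non-improving sweep stops the
  iteration and the best iterate is kept. The recorded
  `residual_history` is non-increasing by construction.

Rows of isolated drugs (no interactions) meet zero denominators in the
update; those entries are left unchanged and the rows are excluded from
the constraint — cold-start drugs by definition contribute nothing to
the relation structure, which is also why Goal-2 fits switch the
relation term off entirely.

## The joint objective

Projections $Z^i \ge 0$ ($n_i \times n$) map each feature space into the
interaction space, and a score matrix $S$ is learned jointly:

$$\theta\sum_{i=1}^m\left(\lVert S - H^iZ^i\rVert_F^2
  + \lVert J - H^iZ^i\rVert_F^2\right)
  + \lambda\sum_{i=1}^m\left(\mathrm{tr}\,(Z^i)^\top O Z^i
  + \mathrm{tr}\,(H^i)^\top O H^i\right)
  + \lVert S - J\rVert_F^2
  + \sigma\,\mathrm{tr}\!\left(((I-M)S)^\top MS\right)$$

with $O$ the all-ones matrix. The three weights have distinct roles:
$\theta$ controls how strongly the projected features must agree with
both the score matrix and the network; $\lambda$ penalizes squared
column sums of $Z^i$ (a group-sparsity surrogate — we use the
$\mathrm{tr}(Z^\top O Z)$ form throughout because it is the form the
solver algebra is derived from; the $H$ terms are data constants,
included in reported objective values and excluded from convergence
ratios); $\sigma$ weighs the relation-regularization term. $H$ is data
and is never optimized.

### Exact score solve

At fixed projections the objective is quadratic in $S$. Writing
$G = (I-M)^\top M$, its stationarity condition is

$$\Big((1+m\theta)I + \tfrac{\sigma}{2}\big(G + G^\top\big)\Big)S
  = \theta\sum_i H^iZ^i + J ,$$

which `solve_scores()` solves as a linear system (the matrix is fixed
throughout a fit and is factorized once). We deliberately use the exact
symmetrized gradient coefficient $\tfrac{\sigma}{2}(G+G^\top)$ rather
than the looser one-sided surrogate $\sigma(I-M)^\top$ sometimes used
with this regularizer: only the exact form makes the solved $S$ a true
stationary point (the package tests verify a vanishing central-difference
gradient) and makes the alternating scheme provably non-increasing. The
practical consequence is worth knowing: with the exact solve the trace
regularizer *damps* score mass on pairs strongly aligned with the
relation structure, rather than diffusing extra mass onto them as the
one-sided surrogate would; at the default Goal-1 weights the feature
projections carry the ranking signal and $\sigma$ acts as a small
structural shrinkage.

### Multiplicative projection updates

Substituting the closed-form $S$ back in gives a reduced objective in
the $Z^i$ alone (`reduced_objective()`; it differs from the full
objective at the corresponding optimal $S$ only by the data-constant
sparsity term, a property the tests assert). Because $S^\ast(Z)$ is the
argmin over $S$, the envelope theorem makes the reduced gradient equal
the partial gradient at fixed $S$, and the stationarity condition for
$Z^i$ is the linear form $CZ^i = B$ with

$$C = 2\theta (H^i)^\top H^i - \theta^2 (H^i)^\top Y H^i + \lambda O,
  \qquad
  B = \theta (H^i)^\top\big(Y R_{-i} + J\big),$$

where $Y$ is the inverse of the score system matrix and
$R_{-i} = J + \theta\sum_{j\ne i} H^jZ^j$. `update_projections()`
applies the sign-split multiplicative rule

$$Z \leftarrow Z \odot \frac{C^-Z + B^+}{C^+Z + B^-},
  \qquad X^\pm = \tfrac{|X| \pm X}{2},$$

the standard non-negativity-preserving update for quadratic objectives
with mixed-sign coefficient matrices. Entries with zero denominator are
left unchanged; a zero entry of $Z$ stays zero. One outer iteration of
`ddi_fit()` is one sweep over all $m$ projections followed by the exact
score solve; the objective history is non-increasing (asserted with
$10^{-8}$ relative slack over many seeded instances).

### Prediction

Goal-1 scores are read off $S$ symmetrized, $(S_{ij}+S_{ji})/2$ — the
network is unordered, and averaging removes the mild asymmetry the
relation term induces. Ranking ties break lexicographically on the
identifier pair. A cold-start drug with feature vectors $H^{*i}$ is
scored as $J^* = \big(\sum_i H^{*i}Z^i\big)/(m+1)$. The $m+1$ divisor
treats the (absent) network row as an $(m{+}1)$-th all-zero view; a
plain $1/m$ average is available via `goal2_denominator = "m"` — the
choice rescales all scores equally and cannot change a ranking.

## Tunable parameters

| parameter | role | default | notes |
|---|---|---|---|
| `lambda` | projection sparsity weight | 1e-1 (goal 1), 1e-3 (goal 2) | grid $10^{-5}..10^{-1}$ via `tune_ddi()` |
| `theta` | feature-projection fidelity | 1e-5 (goal 1), 1e-2 (goal 2) | larger values let features override the network |
| `sigma` | relation regularization | 1e-3 (goal 1), 0 (goal 2) | goal 2 forces 0: new drugs have no relation rows |
| `theta_drr` | relation row-sum penalty | 1e-2 | independent of `theta` |
| `tol` | relative objective change | 1e-4 | measured on the constant-free objective |
| `max_iter` | outer iteration cap | 100 | fits typically converge in < 10 |
| `alpha`, `beta` | Tanimoto / Dice weights | 0.5 / 0.2 | cosine gets the remaining 0.3 |
| `sim_cutoff` | severity neighbour threshold | 0.5 | below it, closest neighbour + low-confidence flag |

All randomness (relation start, projection initialization, fold draws,
simulation) flows from explicit integer seeds; identical seeds give
bitwise-identical results.

## Evaluation protocols

`ddi_crossval()` implements both 5-fold protocols. Goal 1 partitions the
known unordered pairs; each fold's pairs are zeroed in both triangles of
the training network and the scored candidates are the held-out
positives plus *all* never-interacting pairs — no negative sampling, so
the class imbalance of the real task is preserved, which is why AUPR is
the primary metric. Goal 2 partitions drugs; test drugs are scored
cold-start against the training drugs. AUC uses the rank statistic
(ties count half); AUPR uses step-wise summation over descending
distinct thresholds, never linear PR interpolation (which is biased
optimistic). Both agree exactly with brute-force enumeration oracles in
the tests.

The four thresholded metrics need a decision threshold the ranking
metrics do not; none is canonical for this task. The default sets the
threshold where the predicted-positive count equals the count implied by
the training interaction density, and `threshold` overrides it. A
66.67/16.67/16.67 train/validation/test drug split for case-study-style
experiments is available as `case_study_split()`.

## Severity grading

SMILES strings are converted to Open Babel FP2 fingerprints (1024-bit,
path-based, canonical in the molecular graph, so different spellings of
one molecule give identical bits). Structural similarity is the weighted
blend of Tanimoto, Dice and cosine coefficients; on binary bit vectors
the cosine equals $|A\cap B|/\sqrt{|A||B|}$, an identity the tests use.
Molecules with a single heavy atom have no bonded paths and are rejected
explicitly.

A predicted pair $(C, B)$ inherits severity from the known interactors
$A_k$ of $B$: the transferred score is the similarity-weighted average
of the recorded 1–100 scores over neighbours with
$\mathrm{sim}(C, A_k) \ge$ `sim_cutoff`, falling back to the single most
similar neighbour (flagged low-confidence) when none passes. Scores are
real-valued internally and banded on the half-up rounded integer: 1–30
MINOR, 31–60 MODERATE, 61–100 MAJOR. The weighted-average estimator is
a deliberate, documented heuristic — proximity-weighted transfer is the
rationale behind structure-based severity inference, but no published
estimator exists to reproduce, and recorded severities themselves vary
between databases.

## The synthetic generator

`simulate_ddi_data()` plants a shared low-rank structure: each drug gets
one dominant latent group (of `rank`) with a heterogeneous loading in
$[0.5, 1.5]$ plus weak uniform background, features are binarized
non-negative mixtures of the latent factors (top-quintile threshold,
then independent bit flips with probability `noise`), and the network is
the top-`density` quantile of the latent Gram matrix, symmetrized with
zero diagonal. Features and interactions therefore share structure and
the projection model has recoverable signal; `noise` degrades it
monotonically (a property the tests check across seeds).

The default shape — 200 drugs, 4 feature spaces of 120/100/150/300
descriptors, rank 10, density 0.05 — is a deliberate scale-down of
typical curated DDI datasets (one to two thousand drugs, descriptor
dimensions from a few hundred to the 881 PubChem substructure keys,
$10^5$ interactions) chosen so the full test suite and the
reproducibility script run in seconds to a couple of minutes on one CPU.

What the generator does *not* emulate: realistic degree distributions
(real DDI networks are heavy-tailed; the planted network is
community-like), correlated descriptors within a feature space, feature
sparsity patterns of real ontologies, and any pharmacological meaning of
the severity scores attached to simulated pairs. Green tests on this
generator demonstrate the optimization and protocol machinery and
signal recovery under the planted model — not predictive performance on
curated drug data.

## Degenerate inputs and numerical edges

* All-zero networks are rejected for fitting; isolated drugs are
  tolerated and their relation rows stay inert.
* Zero denominators in any multiplicative rule leave the entry
  unchanged rather than producing `NaN`.
* The score system matrix is validated by reciprocal condition number
  before solving; a near-singular system (possible only at large
  `sigma`) errors with the estimate rather than returning garbage.
* Weighted severity means are clamped to the contributing neighbour
  range to keep floating-point drift from crossing a band boundary.
* Metric denominators of zero (e.g. no predicted positives) return 0
  with a warning rather than `NaN`, so fold summaries stay finite.

## Known limitations

* Feature matrices are dense in memory; the implementation targets
  desk-scale problems (hundreds to a few thousand drugs), not
  pharmacovigilance-scale corpora.
* The relation matrix is learned from the network alone; feature-based
  similarity graphs are out of scope by design.
* Severity inference reproduces band assignments, not the recorded
  scores of any particular database; fingerprint choice (FP2 here)
  changes similarity values, so published similarity tables computed
  with unspecified fingerprints are not reproducible by construction.
* With the exact score solve, the relation term shrinks
  structure-aligned scores (see above); if diffusion-style boosting is
  wanted, increase `theta` so feature evidence dominates, or tune
  `sigma` per dataset with `tune_ddi()`.
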