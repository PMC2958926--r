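---
title: "Expert-based cooperative analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expert-based cooperative analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebca)
```

This vignette is the package's own account of the methodology it implements:
what each component assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The cooperative loop

The package operationalises a six-step loop: (1) data preparation, (2)
acquisition of prior expert knowledge into a formal knowledge base (KB) of
if-then rules, (3) KB-guided analysis by one of two engines, (4)
interpretation support and inconsistency detection, (5) incorporation of the
newly elicited knowledge into the KB and repetition, (6) post-processing for
decision support. Steps 2 and 5 are human; the package realises them as a
file-based KB hand-off (`run_loop()` consumes a pre-supplied sequence of KB
versions). The automated stopping rule — stop when the KB is unchanged *and*
no inconsistencies are flagged — is a stand-in for expert judgement and is
flagged as such in the iteration manifests.

## 2. The knowledge base

Rules are `ID : if <expr> then <label>` with atoms `VAR op literal`,
`VAR in interval`, `VAR in set`, connectives `and`/`or`/`not`.
Three deliberate choices:

* **No silent precedence.** Mixing `and` and `or` at one parenthesis level is
  a parse error. Published rule sets in this domain are sometimes printed
  unparenthesised; failing loudly beats guessing. The shipped example rule
  for patients in good condition is therefore stored as
  `(INGRESE = WORK) and ((GAFCLA > 70) or (GAFSOCIAL > 70))`, matching the
  prose reading "able to work and with high functioning".
* **Kleene three-valued evaluation.** A missing cell yields `unknown` only
  when the truth value actually depends on it (`FALSE and NA` is `FALSE`).
  Unknown-status records fall to the residual group with a warning count, so
  no data are invented.
* **First-match semantics.** A record satisfying several rules is assigned to
  the first in KB order, with an overlap warning. Deterministic and
  auditable; the original studies do not document their policy.

Negation and category sets are extensions beyond the minimal historical rule
language; round-trip identity (parse → serialise → parse) is property-tested.

## 3. Monte-Carlo DEA

Each unit × variable carries an expert-elicited distribution (uniform bounds,
triangular, or point mass). Per run the engine samples every cell, reflects
*non-standard* variables, solves one envelopment LP per unit, and appends the
scores to a pool.

* **Non-standard transform.** `x' = (max(x) + margin) − x` with
  `margin = 0.1 × range(x)` (floored at a small positive constant for
  constant columns), applied per run on the sampled values. The literature
  only pins "linear monotone decreasing"; this concrete form keeps outputs
  positive, scales with the data, and exactly reverses ranks. Applying it
  after sampling (not before) was an open point; sampling first keeps the
  expert's distribution on the observable scale.
* **LP solver.** The envelopment programmes are tiny but heavily degenerate
  (zero right-hand sides), which makes textbook pivoting cycle. The package
  ships a dense two-phase simplex with Bland's anti-cycling rule; tests check
  it against an independent vertex-enumeration solution of the multiplier
  (ratio) form to 1e-6 and verify the standard DEA invariants (unit
  invariance, dominance monotonicity, variable-returns ≥ constant-returns,
  one unit on the frontier per run).
* **Convergence.** "Stop when results converge" is operationalised as
  cumulative block-mean stability: after each block (default 500 runs,
  tolerance 0.005 on the max per-unit mean change, cap 20 000 runs) the
  engine compares consecutive cumulative means. Point-mass specs therefore
  converge after exactly two blocks with zero variance — a useful degeneracy
  test.
* **Tiers.** Efficient (mean ≥ 0.95 and frontier fraction ≥ 0.5),
  nearly-efficient (mean ≥ 0.90), uncertain (mean ≥ 0.75), else inefficient;
  the binary collapse groups the first two against the rest. The four-tier
  thresholds are not quantified in the source literature; these defaults are
  configurable and recorded in every run manifest.
* **Output orientation** reports `1/phi`, keeping one `(0, 1]` scale.

## 4. Rule-guided clustering (ClBR)

Records satisfying a rule are condensed into a **prototype**: per-variable
means, category frequency distributions, and a **mass** equal to the class
size. Prototypes and residual records are agglomerated together, so a rule
class of 40 patients attracts merges like 40 records would (mass-weighted
Lance–Williams); clustering prototypes with unit weight was the alternative
and is the reason the weighting is isolated behind `MixedDissimilarityParams`.

* **Mixed dissimilarity.** Block-weighted: standardised squared Euclidean on
  numeric variables, 0/1 mismatch (records) or half-L1 between frequency
  distributions (prototypes) on categorical ones; default block weights
  proportional to the variable counts, default scalings the per-variable
  standard deviations. The original mixed-metric reference is not reproduced
  in the source text, so the algebraic form is a package choice, isolated and
  swappable. Missing cells are handled pairwise-complete with block
  renormalisation.
* **Agglomeration.** Reciprocal-nearest-neighbour chains under the Ward cost
  `ΔW(A,B) = m_A m_B/(m_A+m_B) d²(Ā,B̄)`; ties break on the lowest leaf
  index; merges are height-sorted afterwards (Ward costs are reducible, so a
  stable sort preserves child-before-parent order). Small-instance
  equivalence with exhaustive greedy agglomeration is an acceptance
  criterion.
* **Cut selection.** Calinski–Harabasz over `k = 2..kmax`
  (`kmax = min(10, leaves−1)` by default), with mass-weighted between/within
  scatter computed in the mixed metric and an `Inf` sentinel when the within
  scatter vanishes. Ties go to the smallest k. When rules condense the data
  to fewer than three leaves the cut is forced trivially.
* **Semantics.** Because each rule class enters as one leaf, all its records
  share one final label — the property that makes results interpretable to
  the rule authors, and the reduction property (empty KB ⇒ plain Ward
  clustering) is its complement.

## 5. Interpretation support

* **Test selection.** Numeric variables: classical one-way ANOVA only when
  every class sample has n ≥ 8 and passes Shapiro–Wilk at 0.05, otherwise
  Kruskal–Wallis; categorical: chi-squared on the class × category table with
  rarest-category pooling until expected counts reach 5. The source lists the
  three tests without a selection rule; this screen is the package's rule.
  Benjamini–Hochberg adjustment across variables, raw p reported alongside.
* **Class panel graph.** Shared equal-width bins per numeric variable
  (Sturges on the pooled sample); per-class conditional frequencies sum to 1.
* **Characteristic cells.** Adjusted standardised residuals
  `(O−E)/√(E(1−r/n)(1−c/n))` with default threshold 2.0 — automating what a
  knowledge engineer would mark by eye, threshold configurable.
* **Inconsistency heuristics.** Bimodality: two substantial kernel-density
  modes (second ≥ 25% of the first) with a trough ≤ 0.3 of the smaller peak.
  The Sheather–Jones bandwidth is used because Silverman's rule oversmooths
  exactly the bimodal shapes the detector must find. Variance inflation:
  class variance > 1.5 × pooled within-class variance. Both thresholds are
  the package's operationalisation of the narrative anomaly that historically
  prompted a new rule (a class silently mixing community-dwelling and
  institutionalised patients), and both are configurable.

## 6. Agreement statistics

2×2 diagnostics use Wilson score intervals for proportions and the log method
for likelihood ratios, with documented sentinels (`LR+ = Inf` at specificity
1). The printed confidence intervals of the historical study match no
standard method we checked, so CI values are never asserted — the method name
is emitted with every interval instead. Cohen's kappa is unweighted; the ICC
is the two-way consistency single-measure form
`(MS_rows − MS_error)/(MS_rows + (k−1) MS_error)` with the F-based interval,
insensitive to fixed rater shifts. Multi-class partitions are compared after
optimal one-to-one class matching (Hungarian on the confusion matrix); note
that this matching biases kappa upward by construction, which is why the
chance-level sanity property is tested on the unmatched table.

## 7. Synthetic data: the stated world

The original study datasets (12 Spanish small health areas; 306 patients with
schizophrenia) are not deposited, so the generators emulate their structure:

* **Small health areas.** Twelve units; per-variable uniform ranges from the
  shipped expert-model fixture (types/places/utilisation of acute, non-acute
  hospital, residential community and day care, rates per 100 000); an
  inefficiency plan multiplies the inputs of the last third of units by 1.5,
  making them radially dominated by construction; the emitted stochastic spec
  puts a ±10% uniform band around each central value. The fixture's
  utilisation weights are carried as metadata only.
* **Patients.** n = 306, three planted severity profiles with equal mixing:
  numeric means (GAF clinical/social, family-burden hours) separated by 6
  within-cluster standard deviations between adjacent profiles, per-cluster
  category distributions (behavioural-problem frequency, employment) at
  pairwise total-variation distance ≥ 0.6, diagonal covariances, MCAR
  missingness (default 0). These are the separations the acceptance criteria
  state; the variable names are chosen so the shipped example rules run
  verbatim.

What a green test does **not** establish: the generators have no
between-variable correlation structure, no informative missingness, no
measurement error model, and no realistic epidemiological calibration — they
exercise code paths and recover planted structure, nothing more. The
historical data-dependent results (a specific ICC for one scenario, the
case-mix kappas) are out of reach by design and are replaced by
property-based criteria.

## 8. Numerical choices and degenerate inputs

* LP tolerance 1e-9 internally; scores clamped to `[eps_machine, 1]`.
* CSV output at 17 significant digits so round trips are bit-exact.
* Constant columns: `sd = 0` in summaries; scaling 1 in the mixed metric;
  positive floor in the non-standard transform.
* All-missing variables: warned, skipped in statistics; a pair of entities
  with no comparable variable at all is an error, not a guess.
* Every stochastic routine takes an explicit seed and restores the RNG state
  (`withr::with_seed`), so identical seeds give bit-identical pools,
  partitions and fixtures.

## 9. Known limitations

* Weighted DEA variants (the fixture's utilisation weights), super-efficiency,
  slack-based models and bootstrap bias correction are out of scope.
* The mixed metric is one defensible member of a family; swapping it changes
  partitions and no claim is made that it reproduces the original software's
  exact dendrograms.
* The inconsistency detectors are screening heuristics with configurable
  thresholds, not tests with controlled error rates.
* `run_loop`'s stopping rule cannot represent "the experts are satisfied";
  real use pauses for a human.
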