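---
title: "Detecting gene-gene interactions with multiobjective DE over MDR measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-gene interactions with multiobjective DE over MDR measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modemdr)
```

## The problem

Complex diseases can depend on *epistasis*: joint effects of several loci
that are invisible, or nearly invisible, in any single-locus scan. In a
case-control study with `y` genotyped SNPs (coded 0/1/2 as minor-allele
counts), detecting a `d`-locus interaction means searching the
`choose(y, d)` combinations for one whose joint genotype distribution
differs between cases and controls. Multifactor dimensionality reduction
(MDR) is the standard nonparametric way to score one combination; `modemdr`
wraps that score inside a multiobjective differential-evolution (DE) search
so that two complementary contingency-table measures are optimized at once,
and provides the penetrance-model simulator and exhaustive oracle needed to
study the method's behavior.

## The MDR fitness machinery

For a candidate combination of `d` SNPs there are `3^d` multifactor cells,
one per joint genotype. Under `k`-fold cross-validation, each fold in turn
serves as testing data and the rest as training data:

1. Every cell is labeled from the training data by the ratio
   `theta_hat_a = (n_+0 * n_a1) / (n_+1 * n_a0)`, where `n_ab` counts
   training samples in cell `a` with outcome `b` (1 = case) and `n_+b` are
   the training class totals. Scaling by `n_+0 / n_+1` makes 1 the natural
   threshold even when classes are unbalanced. A cell is *high risk* when
   `theta_hat_a >= 1` (the boundary counts as high), *low risk* below 1,
   and *empty* when the training data contain no sample for it.
2. Testing samples are classified against those labels, giving the
   confusion counts TP, FP, FN, TN (testing cases/controls in high/low
   cells). Testing samples in empty cells carry no risk evidence and are
   excluded by default (`empty_cells = "low"` pools them with low risk
   instead).
3. Two measures score the fold:
   * `CCR = 0.5 * (TP/(TP+FN) + TN/(FP+TN))` — balanced accuracy, chance
     level 0.5 for any class balance;
   * `NMI = (H(y) - H(y|x)) / H(y)` — the fraction of outcome uncertainty
     removed by the high/low prediction, computed from the closed form in
     counts with the `0 log 0 = 0` convention.
4. Both measures are averaged over the `k` folds.

Cross-validation folds come from a *balance strategy*: cases and controls
are shuffled independently and each class dealt round-robin across the `k`
folds, so every fold matches the global case:control ratio to within one
sample per class. Folds are drawn once per run and shared by every
evaluation, which makes fitness a fixed function during the search; were
folds redrawn per evaluation, dominance comparisons would be noisy and the
greedy selection unstable.

### Numerical conventions

* A CCR term with a zero denominator (no testing samples of that class in
  labeled cells) contributes 0 — bounded and pessimistic, keeping dominance
  comparisons total.
* NMI is 0 when the testing fold holds a single class (`H(y) = 0`); by the
  symmetry of mutual information it is 1 for perfectly *inverted* as well
  as perfect classification.
* `theta_hat_a = 1` exactly is high risk; a cell with training cases but no
  controls is `+Inf` (high); a cell with neither is empty.
* The `chi2_significance()` summary labels cells from the full data set and
  tests the pooled high/low-by-case/control table (Pearson, 1 df, no
  continuity correction). Because the dichotomy is chosen from the same
  data, null p-values pile up near zero; the value ranks reported
  interactions and is not a calibrated test.

## The search

A *target vector* is a set of `d` distinct SNP indices. Each generation,
for every target `X_i`:

* **Mutation** builds `V = round(X_r1 + F * (X_r2 - X_r3))` from three
  distinct donors other than `i`; each donor is independently replaced by a
  uniformly drawn archive member with probability `PV` when the archive is
  nonempty.
* **Recombination** crosses `V` with `X_i` componentwise: a component comes
  from `V` when a uniform draw is at most `CR`, and one randomly chosen
  component always does.
* **Boundary repair** redraws out-of-range components and one side of any
  within-vector duplicate until the trial holds `d` distinct in-range
  indices (with exact sampling without replacement as a total fallback).
* **Selection** replaces the target only when the trial *strictly
  dominates* it — better in both CCR and NMI. Ties in either objective
  block replacement; `strict = FALSE` switches to the standard weak-Pareto
  rule, but the strict rule is the documented default.

Once per generation the capacity-bounded Pareto archive is updated from the
post-selection population: candidates not dominated by any member are
admitted, members dominated by another member are purged, and a
combination already present (same unordered index set) is not re-admitted —
under strict dominance, equal-fitness duplicates would otherwise flood the
archive. When the filtered archive exceeds its capacity, members with the
smallest objective-space crowding distance are dropped, extremes first
protected; this keeps the spread of the front and is deterministic, unlike
random or FIFO eviction. Evaluations are cached on the unordered index set
(MDR is symmetric in the loci), and the entire run is a deterministic
function of the seed.

### Parameters

| parameter  | default | meaning |
|------------|---------|-----------------------------------------------|
| `pop_size` | 100     | target vectors per generation |
| `gen_size` | 300     | generations |
| `F`        | 0.5     | mutation scale factor, `[0, 2)` |
| `CR`       | 0.5     | crossover constant, `[0, 1)` |
| `PV`       | 0.5     | probability a mutation donor comes from the archive |
| `d`        | 2       | interaction order |
| `k`        | 5       | CV folds |
| `capacity` | 20% of `pop_size` | archive size bound |

`pop_size`, `gen_size`, `F`, `CR`, `k` and the capacity fraction are the
simulation-study settings. `PV` has no prescribed value in the method's
defining equations; 0.5 gives equal pull toward archive elites and
population diversity and is exposed in the configuration. Initialization
draws indices uniformly on the *integer* range `{lower..upper}` (the
integer form of `rand * (upper - lower) + lower`) so endpoint indices are
not half-weighted by rounding.

Single-measure comparators (`objective = "ccr"` or `"nmi"`) degrade
dominance to one objective and reuse the whole engine, which is how the
CCR-only and NMI-only DE-MDR baselines are expressed in benchmarks.

## The simulator

`penetrance_model(mafs, penetrance)` defines disease risk: a `3^d` table of
`P(disease | genotype)` plus per-locus minor-allele frequencies. Under
Hardy-Weinberg equilibrium the prevalence is `K = sum_g P(g) f(g)`, the
broad-sense heritability on the probability scale is
`h2 = sum_g P(g) (f(g) - K)^2 / (K (1 - K))`, and the model is *pure* (no
marginal effects) when every per-locus marginal penetrance equals `K`.

`generate_pure_epistatic_model()` searches for a two-locus pure model at a
requested MAF and heritability by random restarts: a random table is
projected toward zero marginal deviation by alternating HWE-weighted
row/column additive adjustments, rescaled about `K` by
`f <- K + c * (f - K)` (heritability scales as `c^2`), clipped to `[0, 1]`,
and iterated until both tolerances (default `1e-4`) hold. This reproduces
the *outcome* a genetics simulator provides — models with specified MAF and
`h2` and no marginal signal — without copying any particular tool's
internals.

`simulate_dataset()` draws disease-locus genotypes under HWE, assigns
status `Bernoulli(f(g))`, and rejection-samples until the case and control
quotas fill (budget: 1000 draws per requested sample, after which the model
is declared degenerate). Background SNPs are pure null — independent of
status, each with its own MAF drawn uniformly from `[0.05, 0.5)` — and the
functional pair is hidden at random distinct columns so detection cannot
exploit position. Defaults mirror the simulation study: 200 cases, 200
controls, 1,000 SNPs per dataset.

What the generator does *not* emulate: linkage disequilibrium between SNPs
(columns are independent), missing genotypes, genotyping error, covariates,
population structure, and quantitative phenotypes. Passing tests on these
data therefore demonstrate correctness of the machinery and behavior under
the idealized study conditions, not performance on real GWAS data.

## Benchmarking and oracles

`exhaustive_pareto()` evaluates every combination (guarded at `1e6`) and
returns the global nondominated set — the reference the engine is checked
against. `exhaustive_best_by_cvc()` is canonical MDR: each fold's winner by
*training* CCR (the usual MDR practice; testing-CCR selection would leak
the testing fold into model choice), with cross-validation consistency the
modal winner's fold count. `detection_success_rate()` scores a method by
whether the planted pair appears among its reported combinations — for the
multiobjective search, anywhere in the final archive, since the whole front
is the method's output. `wilcoxon_signed_rank()` compares paired per-model
rates with ties reported separately and a normal-approximation z (exact
enumeration below 15 non-tied pairs). `run_benchmark()` ties these together
over a grid of model settings, deriving every model, dataset and run seed
from one master seed.

## Known limitations

* **Coverage bounds detection of pure interactions.** For a pure model the
  fold-averaged fitness of any pair other than the functional one — including
  pairs sharing one functional locus — is at chance, so the landscape offers
  the search no gradient, and the probability of detecting the planted pair
  cannot exceed the number of distinct combinations evaluated divided by
  `choose(n_snps, 2)`. At the default budget (100 x 300 trials against
  499,500 pairs of 1,000 SNPs) that ceiling is about 6%, and the realized
  unique-evaluation count is far lower once the strictly elitist population
  converges. On such data an exhaustive scan (`exhaustive_pareto`,
  `exhaustive_best_by_cvc`) is the appropriate tool; the heuristic search
  earns its keep when marginal effects exist to guide it or when exhaustive
  enumeration is infeasible and a partial sweep is acceptable.
* **The archive can retain globally dominated members.** Only
  post-selection target vectors feed the archive, so a trial that would
  dominate an archive member but does not strictly dominate its own target
  is discarded before the archive sees it. The archive is always mutually
  nondominated, and nondominated with respect to every vector that ever
  entered the population, but not necessarily a subset of the exhaustive
  front.
* **Strict dominance stalls on plateaus.** Objective ties block both
  selection and purging; the weak rule is available via `strict = FALSE`
  for users who prefer movement on plateaus, at the cost of departing from
  the documented selection rule.
* **`chi2_significance()` is anti-conservative** for null combinations, as
  described above.

## Problem sizes in the test suite

The packaged tests exercise the full protocol at study scale for the
detection-rate checks (20 and 40 replicates of 1,000-SNP datasets) and
desk scale elsewhere: 30-SNP datasets for engine-vs-oracle comparisons,
`1e4` random tables for the measure identities, and `1e5` samples per class
for the simulator's distributional checks. These sizes were chosen so the
whole suite completes in minutes while keeping every statistical assertion
at three-or-more-sigma resolution.
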