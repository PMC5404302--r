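---
title: "Multi-class symbolic discriminant evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class symbolic discriminant evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mces)
```

## The model

`mces` performs symbolic discriminant analysis: classification by an evolved
symbolic function whose scalar output is thresholded to predict class
membership. A *classifier* is the combination of

1. an **expression tree** over building blocks — feature references,
   real constants, and the binary operators `+ - * /` — whose value on a
   sample is its *test value*;
2. a **multi-class threshold rule** derived from the training test values;
3. a **fitness record**: training accuracy and model complexity, where
   complexity is the total number of building blocks (nodes) in the
   expression.

### The median/threshold rule

Given training test values split by class, the rule is constructed as
follows. The median test value of each class is computed (even-sized classes
use the midpoint of the two central order statistics). Classes are ordered
by ascending median, \(m_1 \le \dots \le m_n\), and each successive pair of
ordered medians is averaged into a threshold,
\[ t_i = \frac{m_i + m_{i+1}}{2}, \qquad i = 1, \dots, n-1 . \]
A sample with test value \(v\) is assigned to class \(c_1\) if \(v < t_1\),
to \(c_i\) if \(t_{i-1} \le v < t_i\), and to \(c_n\) if
\(v \ge t_{n-1}\). Each of the \(n-1\) inequalities may independently be
strict or not, so there are \(2^{n-1}\) candidate rules; `fit_rule()`
evaluates all of them and keeps the one with the highest training accuracy.
Accuracy ties are broken toward the lexicographically smallest flag vector
(all-non-strict first), which makes fits deterministic.

Two degenerate-input decisions keep the rule total. Classes with *equal*
medians retain their first-appearance order, and the duplicated threshold
equals the shared median; the class index of a value is then one plus the
number of thresholds it crosses, which still partitions the real line (some
classes simply receive an empty interval). A flag `TRUE` keeps a value
exactly equal to \(t_i\) with the lower class; `FALSE` (the default,
matching the "typical" rule above) gives it to the upper class.

### Protected arithmetic

Expression evaluation must always return a finite test value, whatever the
tree. Division by a denominator with \(|d| < 10^{-9}\) returns 1.0 (the
common genetic-programming protected-division convention), and any
intermediate whose magnitude exceeds \(10^{12}\) is clamped to
\(\pm 10^{12}\). Constants are drawn uniformly from \([-10, 10]\) by
default; bounding the constants keeps thresholds on the scale of the data.

## The evolutionary search

Solutions evolve on a \(D \times D\) **toroidal grid** (default
\(D = 36\)), each cell holding one classifier. The torus is what makes the
"every solution has eight neighbors" structure uniformly true, including at
the borders. Each generation is a *synchronous* Pareto domination
tournament on a frozen copy of the grid:

* classifier \(a\) **dominates** \(b\) when
  \(\text{acc}_a \ge \text{acc}_b\) and \(\text{cplx}_a \le \text{cplx}_b\)
  with at least one strict;
* a cell that dominates **all eight** Moore neighbors writes mutated copies
  of itself into those eight positions; every new expression is re-fit
  (medians, thresholds, flags) and re-scored on the training data;
* cells not adjacent to any dominator persist unchanged;
* when several dominators target the same cell, the winner is the dominator
  with higher accuracy, then lower complexity, then the smaller (row,
  column) position. The update is therefore deterministic given the random
  stream, and a fixed seed reproduces a run bit-for-bit.

Mutation picks one of three structural edits with fixed, configurable
probabilities (defaults: add 0.25, remove 0.25, swap 0.5): *add* wraps a
random node in a new operator with a fresh random leaf, *remove* hoists a
child over a random operator node (a single leaf cannot shrink further),
*swap* replaces a node in place by one of equal arity. The original system
adapted such parameters with a learned meta-layer; this package instead
exposes them as fixed configuration, which keeps runs reproducible and the
parameter space inspectable. Subtree crossover (`recombine_trees()`) is
provided as part of the variation toolkit, but the tournament itself
repopulates by mutation only.

Initial trees use grow-style construction with leaf probability rising in
depth (and reaching certainty at the depth bound, default 4), so the first
population mixes single-feature classifiers with bushier expressions.

### The archive and Pareto levels

An external elitist **archive** maintains the Pareto front in the
(accuracy, complexity) plane over *every* classifier ever evaluated, so the
best accuracy reachable from an archive is non-decreasing in the number of
generations by construction. The archive is capped at 500 members; when the
cap is exceeded, the interior member with the smallest accuracy gap to its
neighbour on the front is dropped — never the accuracy extremes, so the
span of the front is preserved.

A **Pareto level** is one full evolution run. With `pareto_levels > 1`,
each level seeds the next level's initial grid with its archive (one member
per cell, remaining cells random) and evolution restarts; since the seeded
members are re-entered into the new level's archive, the best accuracy can
only improve across levels. The original description ties levels to
wall-clock budgets on a cluster; here levels are explicit sequential runs
with a fixed generation budget, which is hardware-independent.

Stopping is by generation count only. Wall-clock stopping was deliberately
excluded: it makes results depend on the machine.

## Expert knowledge

Evolution can be biased toward a pre-ranked feature subset: each feature
leaf is drawn from the expert set with probability `expert_bias` (default
0.8) and from the full vocabulary otherwise. The default expert set is the
top \(k = 100\) features by one-way ANOVA F statistic across the classes,
restricted to \(p < 0.05\) (F distribution with \(n-1\) and \(N-n\) degrees
of freedom). Biased-but-not-exclusive sampling is the weaker of the two
readings of "supplying expert knowledge to the search"; it leaves every
feature reachable, so a signal missed by the univariate pre-ranking can
still be found.

## Preprocessing

Two standard steps are provided for raw-count input: `filter_low_counts()`
removes features for which no sample reaches a raw count of 5, and
`log_transform()` applies \(\log_2(x + 1)\). Variance-stabilizing
transformations from external differential-expression packages can be used
instead; the pipeline only assumes the matrix it receives is on a roughly
variance-stable scale.

## Evaluation protocol

`ces_cv()` implements repeated stratified k-fold cross-validation (default
10 repetitions of 5 folds, i.e. 50 evaluations). Folds are stratified —
class proportions are preserved in every test set — because expression
studies typically have small, near-balanced classes and unstratified splits
risk starving a training fold of a class. Within each fold the *entire*
pipeline runs on the training split only: expert-knowledge ranking,
evolution, rule fitting. The single archive member with the highest
training accuracy (ties: fewest building blocks, then smallest expression
string) is then applied once, with its frozen rule, to the held-out split.

Reported aggregates:

* **accuracy** — mean per-fold test accuracy, using the simple multi-class
  formula (fraction correct); the binary balanced-accuracy formula is also
  provided for two-class work;
* **Tanimoto stability** — the mean over all unordered pairs of per-fold
  selected feature sets of
  \(S(s, s') = 1 - \frac{|s| + |s'| - 2|s \cap s'|}{|s| + |s'| - |s \cap s'|}\),
  which equals the Jaccard index. "Average across the 50 feature sets" is
  read as the mean over unordered pairs, the standard stability-index
  aggregation for this similarity;
* **selected features** — mean per-fold count of distinct features in the
  chosen expression. `feature_frequency()` additionally tabulates, across
  repeated runs, how often each feature is selected, dropping features seen
  only once.

## The synthetic generator

`ces_simulate()` stands in for real expression archives so that every stage
is testable offline. It emulates a transformed expression matrix: noise
features are i.i.d. standard Gaussian in every class; each informative
feature receives class means spaced `delta` noise standard deviations apart,
*monotone* in class index by default — exactly the geometry the
median/threshold rule assumes, since a single such feature orders the
classes along one axis. A non-monotone mode permutes the class-mean
profiles, creating the harder regime where no single feature separates the
classes and composite expressions are required. A negative-binomial mode
(dispersion 0.2, a typical bulk RNA-Seq overdispersion) produces raw counts
for exercising the preprocessing path; there `delta` acts on the log2 mean.

What the generator does **not** emulate: library-size variation, batch
structure, gene–gene correlation, heavy-tailed outliers. Passing tests on
synthetic data therefore demonstrate the mechanics and the recovery of
planted signal under idealized noise, not performance on real tissue
panels.

## Problem sizes and numerical choices in the shipped tests

The package's own experiments are scaled to run on a single CPU in minutes:
the recovery experiment uses 4 classes × 30 samples, 500 features, 6
informative at `delta = 2`, a 16×16 grid, 200 generations, and single-rep
5-fold cross-validation; property tests use 500–1000 randomized instances
against brute-force oracles (exhaustive flag enumeration, quadratic Pareto
filters). Production-scale settings (36×36 grid, 1000 generations, 10
repetitions) are the configuration defaults. Thresholds are serialized with
17 significant digits so records re-parse bit-exactly.

## Known limitations

* The rule thresholds a single scalar axis; class structures that are not
  separable along any evolvable scalar projection (e.g. strongly
  non-monotone multi-modal classes) require composite expressions that may
  be slow to discover at small budgets.
* Plain classification accuracy is appropriate for near-balanced classes;
  for imbalanced designs macro-averaged metrics would be better suited and
  are not implemented here.
* The domination tournament is elitist and local; with very small grids it
  can converge prematurely. Pareto levels and larger grids mitigate this.
* Fitness evaluation is serial; the contract is bit-identical results for a
  given seed, so any future parallelism must preserve the serial stream.
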