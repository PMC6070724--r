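---
title: "Ordinal partitioning with linear SVMs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal partitioning with linear SVMs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmop)
```

## The problem and the model

Ordinal regression sits between classification and regression: labels come
from a finite ordered set {1, …, P}, and the cost of an error grows with
the distance between predicted and true rank. The motivating application
is automatic rating of text consultations (e.g. doctor/patient message
threads on five-level satisfaction scales), where the design matrix is
huge and sparse — TF-IDF n-grams plus a handful of hand-crafted features —
and linear models with fast solvers are the realistic choice.

This package implements the *ordinal partitioning* approach. The P-class
problem becomes P − 1 binary sub-problems, the p-th asking "is the rank
greater than p?" with recoded labels `+1` iff `y > p`. Each sub-problem is
a linear soft-margin SVM,

$$\min_{w_p}\; \tfrac12\|w_p\|^2 + C \sum_i \max(0,\, 1 - \hat y_{pi}\, w_p^\top x_i),$$

solved in the dual
($\tfrac12\alpha^\top Q\alpha - e^\top\alpha$, $0\le\alpha_i\le C$,
$Q_{ij}=\hat y_i \hat y_j x_i^\top x_j$) by dual coordinate descent,
with $w_p=\sum_i \alpha_i \hat y_{pi} x_i$ maintained incrementally after
every coordinate update. The stacked weight matrix
$W = (w_1,\dots,w_{P-1})$ is the entire fitted model: prediction,
evaluation, and feature mining all read it.

Contrast with the *threshold* family (one shared direction plus ordered
cutpoints, e.g. SVOR-style models): partitioning trades the guaranteed
monotone structure of thresholds for P − 1 independent, embarrassingly
simple binary fits that scale to very high dimension. Those prior
threshold models are outside this package's scope; the naive baselines
(one-vs-rest SVM and logistic regression, rounded ridge regression) are
included because they isolate exactly what the ordering information buys.

## Joining the sub-models: the counting rule

The sub-model scores $s_p = w_p^\top x$ need a rule that turns P − 1
binary answers into one rank. Two aggregations are standard for this
decomposition, and the package provides both:

* **count** (default): $r(x) = 1 + \#\{p : s_p > 0\}$. Every sub-model
  votes independently; the rank is one plus the number of "yes" answers.
  If no score is positive, $r(x)=1$; if all are, $r(x)=P$.
* **sequential**: ask the questions in order and stop at the first
  non-positive score ($r(x) = 1 + \max\{p : s_1,\dots,s_p > 0\}$).

The two agree whenever the score sequence is sign-monotone (which is the
typical case once the sub-models are trained on the same data); they
differ only on non-monotone patterns, where the count rule degrades more
gracefully — a single inverted sub-model changes the rank by one rather
than truncating the whole sequence. That robustness, plus the exact
identities at the two extremes, is why count is the default; `sequential`
is retained as a sensitivity check (`svmop(..., prediction =
"sequential")`). Probability-based joining was deliberately avoided:
subtracting adjacent class-probability estimates can produce negative
"probabilities", an known pathology of that construction.

A score of exactly zero counts as "not greater than zero" (strict
inequality), so the all-zero score vector maps to rank 1.

## Solver: dual coordinate descent

* **Stopping rule**: the maximum absolute projected-gradient violation
  over a full pass must reach `tol` (default `1e-3`). This is a KKT
  residual: at the exact optimum it is 0. The default is deliberately
  strict; on noisy, heavily overlapping data the last factor of 10 in the
  violation can cost thousands of epochs while moving the objective (and
  every prediction) by nothing measurable, which is why `max_epochs`
  (default 1000) also bounds the run and non-convergence is *reported*
  (per sub-model, on `summary()`) rather than treated as failure.
* **Coordinate order**: a fresh random permutation per epoch, from a
  seeded xorshift generator inside the compiled code — deterministic
  across platforms and independent of R's RNG state.
* **Loss**: L1 hinge by default (box `0 ≤ α ≤ C`), squared hinge as an
  option (`loss = "l2"`: unbounded α with a diagonal shift `1/(2C)`).
* **Bias**: an augmented constant-1 feature, on by default; `bias = FALSE`
  gives the pure homogeneous form stated above.
* **Zero rows**: an instance with an all-zero feature row has constant
  dual gradient −1, so its α is fixed analytically at the box edge and it
  is excluded from the sweep (it cannot move w).
* **Single-class sub-problems** (e.g. no training instance above rank p):
  the QP is still well-posed; the solver runs normally, the returned w
  pushes scores toward the common side, and the model records a warning.
* **Shrinking**: the usual active-set heuristic is implemented but off by
  default — with it off, every epoch touches every coordinate, which
  makes convergence traces auditable; tests verify that turning it on
  changes w by no more than the tolerance.
* **Dual non-uniqueness**: the dual optimum can be a face, not a point
  (two mirrored support vectors already produce a segment of optimal α).
  Tests and cross-checks therefore compare *primal objectives* of the
  recovered w, never raw α values.

The per-update monotonicity of the dual objective and the equivalence
with an independent box-QP solver (accelerated projected gradient) are
asserted in the test suite.

## The feature pipeline

For consultation-style records the design matrix has three column blocks,
`[text | customized | boosted]`:

* **Text** (feature sets `T`, `T+C`, `T+C+B`): TF-IDF over unigrams and
  contiguous bigrams. TF is the raw in-document count; IDF is the
  smoothed `ln((1+N)/(1+df)) + 1` (never zero, defined for unseen terms);
  rows are L2-normalized. Vocabulary columns are lexicographically
  ordered and cut at `min_df` (default 2). Tokenization is pluggable:
  whitespace by default, plus a greedy longest-match dictionary segmenter
  for unsegmented scripts. Real-language word segmentation is out of
  scope.
* **Customized** (8 columns): counts of symptom/illness/medicine
  dictionary terms in the doctor text (longest-match, non-overlapping,
  counting occurrences rather than distinct terms), the numbers of
  patient and doctor turns, the response time to the first question in
  seconds, and the character counts of both sides. A consultation with no
  doctor reply has no response time; it is imputed with the training
  maximum — a "worst observed" sentinel. The block is z-scored with
  training-fold statistics, because raw counts and seconds would
  otherwise drown the unit-norm TF-IDF rows.
* **Boosted**: gradient-boosted regression trees (squared loss; each
  round fits the residuals, i.e. the negative gradient) are grown on the
  8 customized features only, and each instance is re-encoded by the
  one-hot identity of the leaf it reaches in every tree. Each leaf is a
  conjunction of threshold conditions, so the block adds learned feature
  *combinations* that a linear model can weight. Defaults M = 30 rounds,
  depth 3, learning rate 0.1 in the featurizer (M = 100 for a
  free-standing `gbdt()` fit); split search is exact greedy variance
  reduction with ties broken toward the lowest feature index, then lowest
  threshold, making trees fully reproducible.

## Evaluation metrics

MAE and MSE are plain means of `|gold − pred|` and `(gold − pred)²`.
Pairwise accuracy (PAcc) is the fraction of instance pairs ordered by the
gold labels whose predictions agree in direction — a concordance index.
Tied predictions on an ordered pair count as *incorrect* under the default
strict convention (the conservative reading); `ties = "half"` gives the
Kendall-τ-style half credit for sensitivity. PAcc is undefined (an error,
not 0) when all gold labels are equal. The implementation works on the
gold × predicted contingency table, so it is exact and fast; tests pin it
to an O(n²) enumeration oracle. Confusion matrices are reported with
row-normalized proportions and an *adjacent-class error share* — the
fraction of errors landing next to the truth, the signature quantity of
ordering-aware models.

## Synthetic generators: what they do and do not show

The package must be exercisable end-to-end without any proprietary
corpus, so two seeded generators define the study conditions.

**Latent-threshold ordinal data** (`gen_ordinal`): x is standard normal,
a latent score `u = βᵀx + ε` is cut by P − 1 strictly increasing
thresholds, and `y = 1 + #{t : u > t}`. This is the textbook
ordered-probit geometry — parallel discriminant planes — which is exactly
the structure the partitioning model assumes, so it is the right fixture
for *correctness*: with `noise_sd = 0` every binarization is linearly
separable and a correct solver must reach training MAE 0 and zero hinge
loss. The spec resolves β and the thresholds once (from its seed);
`gen_ordinal(spec, seed = ...)` redraws samples from the same population,
which is how train/test pairs are built. A `margin` parameter (default
0.1) keeps the noise-free latent score clear of every cutpoint by
rejection, guaranteeing a finite-margin hard separation so the
hard-margin solution is attainable at finite C. Default thresholds are
the normal quantiles that make classes equiprobable.

**Consultation corpus** (`gen_consultations`): records with timestamped
patient/doctor turns over an opaque ASCII vocabulary, three generated
term dictionaries, and labels drawn uniformly from 1–5. Two planted
signals tie features to the label through logistic links: a politeness
signal (the probability that a doctor token is a polite term rises with
the label) and an effort signal (more doctor turns, shorter response time
at higher labels). With both effects at zero the features carry no label
information — the null case tests can check against. Defaults (n = 200,
effects = 1, 30-term dictionaries, 50-token vocabulary) were chosen once
as a plausible small-corpus regime.

Passing tests on these generators shows the machinery is correct and that
the method exploits ordinal structure where it exists; it does *not* show
anything about real consultation language — no word-frequency tails, no
topic structure, no label noise from rater behavior.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make the
statistical claims stable while staying comfortably interactive: 20
random problems (n ≤ 30) for the QP-oracle equivalence; n = 500 for exact
recovery (C = 100, tol 1e-5 — the hard-margin regime; the residual hinge
is bounded by solver tolerance, asserted ≤ 1e-3); n = 2000 × 10 seeds for
the adjacency comparison; 200 features with 5 informative for importance
recovery; a 400-record corpus for the feature-set comparison. Class
balancing in the generator uses bounded rejection (200 batches) and
errors out on infeasible specs. Argmax ties in one-vs-rest prediction
break toward the lower class; SVR-style rounding is half-up, clipped to
[1, P]; JSON model round-trips are exact up to one ulp of decimal text.

## Limitations

* Linear kernels only — deliberate: the target regime is sparse
  high-dimensional text, where linear SVMs are the established tool.
  No kernelized or threshold-family (SVOR/RedSVM-style) models.
* Sub-models are trained independently; nothing enforces monotonicity of
  the P − 1 boundaries. The count rule absorbs, but does not remove,
  occasional non-monotone score patterns.
* The logistic baseline delegates to glmnet, which declines degenerate
  fits (a class with a single observation).
* The GBDT block boosts only the 8 customized features; boosting the text
  block is out of scope (and would be a different method).
* The number of leaf-encoding columns is data-dependent; it is reported,
  never targeted.
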