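# svmop — ordinal regression by SVM ordinal partitioning

Ratings such as five-level patient satisfaction ("very unsatisfied" …
"very satisfied") are *ordinal*: the labels are ordered, and predicting a
4 for a true 5 is a smaller mistake than predicting a 1. Treating the task
as plain multi-class classification throws that ordering away; treating it
as metric regression pretends the labels are real numbers. This package
implements the ordinal-partitioning middle road for linear models on
large, sparse feature spaces — the setting of text-heavy applications such
as rating doctor/patient text consultations — together with the
surrounding pipeline: text and dictionary features, boosted-tree feature
combinations, ordinal metrics, and feature-importance mining.

## The model

Given labels in {1, …, P}, the P-class problem is decomposed into P − 1
binary questions *"is the rank greater than p?"* (p = 1, …, P − 1). For
partition p the labels are recoded

    y_pi = +1 if y_i > p, else −1,

and a linear soft-margin SVM

    min_w  ½‖w_p‖² + C Σ_i max(0, 1 − y_pi · w_pᵀ x_i)

is trained by **dual coordinate descent** (DCD) on its dual
(½αᵀQα − eᵀα over 0 ≤ α ≤ C, with Q_ij = y_i y_j x_iᵀx_j), maintaining
w_p = Σ_i α_i y_pi x_i incrementally — the solver family built for exactly
this large-scale sparse linear regime. The P − 1 weight vectors are stacked
into W ∈ R^{l×(P−1)} and joined by a **counting prediction rule**

    r(x) = 1 + #{ p : w_pᵀ x > 0 },

so r(x) = 1 when no sub-model answers "yes" and r(x) = P when all do.
A sequential first-failure rule is available as an option.

Feature importance follows from the same object: the contribution of
feature j is Con_j = ‖W(j,:)‖₂, the L2 norm of its row across all
sub-models.

Evaluation uses the three ordinal metrics: MAE, MSE, and pairwise accuracy
(PAcc) — the fraction of label-ordered instance pairs whose predictions
agree in direction, a concordance index.

## Worked example

```r
library(svmop)

# a latent-threshold ordinal population: u = beta'x + eps cut by 4 thresholds
spec  <- latent_threshold_spec(n = 1000, l = 10, P = 5, noise_sd = 1, seed = 42)
train <- gen_ordinal(spec)
test  <- gen_ordinal(spec, seed = 43)   # same population, fresh draw

fit <- svmop(train, C = 1)
fit
#> Ordinal-partitioning linear SVM (4 sub-models, P = 5)
#> C: 1   bias: TRUE   prediction rule: count

ordinal_eval(test$y, predict(fit, test), P = 5)
#> n = 1000   MAE = 0.7900   MSE = 1.1940   PAcc = 67.84%

# the naive one-vs-rest SVM ignores the ordering and pays for it:
ordinal_eval(test$y, predict(svc_ovr(train, C = 1), test), P = 5)
#> n = 1000   MAE = 1.0280   MSE = 2.1340   PAcc = 61.87%

head(top_features(feature_contribution(fit), 3), 3)
#>   rank feature name       con
#> 1    1       2   x2 1.2806758
#> 2    2       4   x4 1.1735258
#> 3    3       9   x9 0.9036994
```

The MAE/MSE gap against the one-vs-rest baseline is the ordering
information at work: both models err, but the partitioning model's errors
land next to the truth far more often (its adjacent-class error share here
is 0.73 versus 0.53 for one-vs-rest).

For consultation-style data the pipeline is: `gen_consultations()` (or
your own JSON-lines records plus term dictionaries) → `fit_featurizer()`
(TF-IDF unigrams/bigrams, eight customized features, optional GBDT leaf
encodings) → `design_matrix()` → `svmop()`. A thin command-line wrapper
over the same stages lives at `inst/cli/ordpe.R`
(`Rscript inst/cli/ordpe.R simulate|featurize|train|predict|evaluate|importance|crossval|sweep ...`).

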