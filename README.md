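# seqtlboga

Wrapper feature selection for binary biomedical diagnosis that picks a
feature subset and tunes the SVM hyperparameters *at the same time*. The
search engine is **SeQTLBOGA**: teaching-learning-based optimization
(TLBO) with a quantum (qubit) encoding of the feature mask, a
self-adaptive teaching factor, and a self-adaptive genetic algorithm
layered on top. The package also ships the standard comparison
baselines (GA, PSO, cuckoo search, differential evolution, grasshopper)
under an identical evaluation budget, plus the nonparametric statistics
used to compare them (Friedman test with Holm / Hochberg / Li post-hoc
procedures).

It is aimed at people benchmarking metaheuristic wrappers on tabular
clinical data — the canonical examples being the two Wisconsin
breast-cancer collections (the 9-feature original dialect and the
30-feature diagnostic dialect, both loadable from local CSVs).

## The model in brief

Each of `n` features is a **qubit** `(alpha_j, beta_j)`,
`alpha_j^2 + beta_j^2 = 1`; `beta_j^2` is the probability the feature is
selected when the learner is *observed*. Two extra real dimensions carry
the SVM penalty `C` and RBF width `sigma` (the `n + 2` encoding). Each
iteration: observe → score by stratified K-fold SVM accuracy

```
fitness = (1/K) * sum_k accuracy_k
```

→ rotate qubits toward the best learner (the *teacher*) through the
rotation gate `U(theta)`, XOR-gated to disagreement positions → TLBO
teacher/learner phases on `(log C, log sigma)` with rank-based inertia
`omega_i = (rank_i/N)(omega_max - omega_min) + omega_min` and a
cosine-decaying teaching factor → self-adaptive GA crossover/mutation
whose probabilities follow the population's fitness spread, blended with
quantum rates (`beta^2` per position; `arccos` of the state overlap per
learner) → greedy elitist survivor selection.

## Worked example

```r
library(seqtlboga)

# a synthetic diagnostic-style dataset: 300 samples, 12 features,
# 4 of them informative (class means 2 SD apart), balanced classes
gen <- make_synthetic(synthetic_spec(
  n_samples = 300, n_features = 12, n_informative = 4,
  class_fraction_positive = 0.5, mean_shift = 2.0, seed = 7))
dataset <- gen$dataset
dataset
#> <bc_dataset:synthetic> 300 samples x 12 features, 159 positive (53.0%)

config <- optimizer_config(population_size = 15, max_iterations = 25,
                           k_folds = 5, seed = 1)
rec <- run_seqtlboga(dataset, config)
rec
#> <run_record:seqtlboga> best fitness 0.9867 with 5 features (C = 0.09739, sigma = 1.861)
#>   390 evaluations, 4.8 s, seed 1

which(rec$best_learner$mask == 1)
#> [1] 1 2 3 4 6          # all 4 planted informative features recovered
gen$informative
#> [1] 1 2 3 4

m <- rec$final_metrics
sprintf("sensitivity %.3f | specificity %.3f | balanced AUC %.3f",
        m$sensitivity, m$specificity, m$auc_balanced)
#> "sensitivity 0.994 | specificity 0.979 | balanced AUC 0.986"
```

The run record's `best_fitness_trace` is monotone non-decreasing by
construction (elitism), `n_evaluations` is exactly
`population_size * (max_iterations + 1)` for every algorithm — the
fair-comparison contract — and the whole run is reproducible from
`seed`. The reported fitness is a CV accuracy *maximized over masks*, so
read it as an optimistic estimate; `holdout_protocol()` wraps the run in
a stratified 80/20 outer split and reports honest test accuracy for the
final learner.

Benchmark statistics (here on the published average-rank table):

```r
fr <- friedman_statistic(c(2.25, 3.875, 5, 2.875, 1), N = 4)
sprintf("Friedman chi-square = %.2f on %d df, p = %.6f",
        fr$statistic, fr$df, fr$p_value)
#> "Friedman chi-square = 14.95 on 4 df, p = 0.004806"
```

14.95 on 4 degrees of freedom rejects "all five optimizers perform
alike" at the 5% level; `posthoc_z()` then compares each baseline with
the best-ranked method under Holm/Hochberg/Li corrections.

## Command line

```sh
Rscript inst/cli/seqtlboga-synth  --samples 400 --features 20 --informative 5 --out data.csv
Rscript inst/cli/seqtlboga-select data.csv --algorithm seqtlboga --seed 7 --out run1
Rscript inst/cli/seqtlboga-bench  data.csv --algorithms seqtlboga,ga --runs 10 --out bench1
```

`seqtlboga-select` writes a TSV run record plus a manifest;
`seqtlboga-bench` adds the score matrix, rank table, Friedman/post-hoc
report and FP/FN-rate histograms. A flat `key = value` config file can
supply any flag (`--config`); explicit flags win.

Real Wisconsin-dialect files (downloaded separately; nothing is fetched
by the package) load with `load_wbcd()` / `load_wdbc()`: `?` rows are
dropped, class labels map to 0 = benign, 1 = malignant.

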