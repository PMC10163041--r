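---
title: "Inferring sex from pain thresholds: models, controls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex from pain thresholds: models, controls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painsex)
```

## The question and the overall strategy

Sex differences in experimental pain sensitivity are usually reported as
per-variable significance tests. `painsex` implements the complementary,
machine-learning formulation of the question: if pain thresholds carry
relevant information about sex, it must be possible to *invert* the
association — to train a classifier on thresholds from one group of
subjects and have it infer the sex of subjects it has never seen. The
package operationalises this as a pipeline with three claims, each backed
by its own experiment:

1. **Positive evidence.** Classifiers trained on a held-back 80% training
   partition can assign sex in the untouched 20% validation partition with
   a balanced-accuracy confidence interval that excludes the 0.5 guessing
   level.
2. **Attribution.** A 26-method feature-selection ensemble, aggregated by
   computed ABC analysis of the per-variable vote counts, identifies
   *which* threshold variables carry that information.
3. **Negative evidence.** Two controls show the remaining variables carry
   none: training on column-permuted (nonsense) data, and training on the
   unselected complement of the chosen variables. Both must stay at
   guessing level; a "not informative" conclusion is thereby a
   demonstrated result, not an absence of evidence.

The cohort analysed is quantitative sensory testing (QST) data: one row
per subject, one column per pain-threshold variable, plus a binary sex
label (men = 0, women = 1).

## The data model and the synthetic cohort generator

The study population the generator emulates is 69 men and 56 women with
eleven variables: five baseline thresholds — blunt pressure (N/cm²),
punctate pressure (von Frey filaments, g), heat (°C), cold (°C) and
electrical current (mA) — three thresholds re-measured after topical
sensitization (punctate and heat after capsaicin, cold after menthol), and
three derived *sensitization effects*, defined as the difference of log10
stimulus magnitudes (sensitized − baseline). The 5 + 3 + 3 decomposition
is the package's reading of the eleven-variable space; the derived-effect
definition makes the effect variables live naturally on the log scale.

Thresholds are modelled log-normally: per class, log10 stimulus magnitudes
are multivariate normal with configurable means, SDs, and correlation
(default 0.3 within a stimulus modality, 0.1 across modalities — modest
positive dependence typical of QST batteries). A target Cohen's d per
variable is achieved by shifting each class mean symmetrically by ±d/2
pooled SDs, which leaves the pooled SD at its nominal value. Defaults
place signal on four variables — blunt pressure (d = −1.2), punctate
pressure with and without capsaicin (both −1.0), and electrical current
(−0.8); negative because women are the more sensitive class — and no
signal on thermal or sensitization-effect variables. The punctate and
punctate-capsaicin shifts are equal by design so their derived effect
variable has exactly zero sex effect.

Device physics is reproduced on the raw scale:

* the thermode operates between 0 and 50 °C from a 32 °C baseline, so cold
  stimuli are encoded by their *magnitude* 32 − T before any log
  transform, and both thermal variables are censored at the hardware
  limits;
* electrical stimuli stop at 20 mA;
* punctate thresholds are snapped to the 20-step von Frey force ladder
  (0.008–300 g, ties toward the weaker filament), with values beyond the
  strongest filament censored at 300 g.

A cell is flagged censored exactly when its recorded value sits on a
censor bound, the same rule the CSV loader applies, so simulated cohorts
round-trip through files without information loss.

What the generator does *not* emulate: trial-by-trial staircase dynamics,
session or handedness effects, non-normal within-class shapes, missing
data, and the real study's unpublished raw distributions. Tests passing on
synthetic cohorts therefore certify the pipeline's statistical machinery
(calibration of the controls, recovery of planted structure), not any
claim about real QST data.

## Preprocessing

Censored cells are imputed before the log transform. The default policy,
`at_bound`, substitutes the censor bound itself — deterministic and
conservative. The alternative, `tail_draw`, fits a log-normal to the
variable's uncensored magnitudes and draws seeded replacements from the
tail beyond the bound, estimating the latent threshold the device could
not record (such values intentionally lie outside the physical range).
`log10_transform()` then maps every measured variable to the log10 of its
positive stimulus magnitude; derived effect variables pass through
unchanged.

The descriptive layer mirrors standard practice: Welch two-sample t-tests
per variable (chosen because log-scale thresholds are near-normal under
the log-normal model), signed Cohen's d (women − men, pooled SD), and a
Pearson correlation matrix with pairwise p-values.

## Distribution-optimal splitting

The 20% validation sample is class-proportional (per-class sizes rounded
to nearest: 14 of 69 men, 11 of 56 women) and *distribution-optimal*:
among `n_candidates` stratified random splits, the one whose training part
is most similar in distribution to the complete sample is kept. Similarity
is the per-variable two-sample Kolmogorov–Smirnov distance between the
training part and the full sample, averaged over variables — scale-free
and cheap. The KS statistic is computed from pre-sorted columns with
tie-run handling (ladder-quantised variables always contain ties), which
makes scoring a candidate O(n) per variable and the million-candidate
full-fidelity search feasible. The package default is `n_candidates =
1e6`; the test suite and the reproduction script use 200–2000 candidates,
which on 125 subjects lands within a few thousandths of the large-search
score. Scoring the validation part instead is available as an option; the
training-part comparison is the default reading.

## The 26-method feature-selection ensemble

Selection runs inside repeated stratified cross-validation
(`cv_scheme(5, 20)` by default, i.e. 100 folds). The roster is:

* two univariate filters: the per-variable F-test at α = 0.05 without
  ("false positive rate") and with Bonferroni correction ("family-wise
  error rate");
* six multivariate families, each instantiated with four classifiers
  (linear SVM, random forest, ridge logistic regression, LDA): top-k by F
  value with k chosen over a 1..11 grid; select-from-model (importance
  above the mean importance); recursive feature elimination; forward and
  backward sequential selection; and permutation importance (mean
  held-out balanced-accuracy drop over 50 within-column permutations,
  selected when strictly positive).

That yields 2 + 6 × 4 = 26 method instances. Within each fold, subset
sizes for top-k, RFE and SFS are scored by balanced accuracy on the fold's
held-out part — the scheme itself is the cross-validation — with ties
resolved toward fewer features (and toward the smallest k on the top-k
grid). Each (variable, method) pair is reduced to one bit by majority vote
across folds; the aggregation rule is the package's choice, as is α =
0.05 and the importance thresholds, none of which are pinned down by the
workflow description the package follows. The deep neural network does
not participate in selection; only the four classical classifiers expose
the required importance weights. Classifier importances are |hyperplane
weights| (SVM), |ridge coefficients| (logistic), |discriminant loadings|
(LDA) and impurity importances (forest).

Row sums of the resulting 11 × 26 binary matrix count each variable's
votes and feed the categorisation step.

## Computed ABC analysis

Computed ABC (cABC) analysis divides positive item scores into the
"important few" (A), an intermediate set (B), and the "trivial many" (C)
using the ABC curve: items sorted by decreasing score, plotted as
cumulative share of the total (yield) against fraction of items (effort).
The package computes two canonical curve points:

* the **Pareto point**, the curve point closest to the ideal (0, 1),
  found by exact orthogonal projection onto each linear segment (a fine
  grid search over the curve can only do as well — this is the invariant
  the test suite checks on a thousand random score vectors);
* the **break-even point**, the earliest point where the curve's slope
  falls to 1; on the all-equal diagonal curve the convention is (1, 1).

The published cABC boundary formulas are not restated in the workflow the
package follows, so the boundaries here are the package's own computable
geometry, flagged as an approximation: the A/B boundary is the smaller of
the two efforts above, and the B/C boundary is the effort of the curve
point closest to (ab_limit, 1). Item counts at boundaries round up, so A
is never empty for positive input; zero-score items are always C; ties
keep input order. Categories are invariant to positive rescaling of the
scores.

The **recursive** variant re-applies the categorisation to the previous A
set until it has one member, stops shrinking, or a depth cap is reached;
the final A set is the *sparse* feature set. Note that the reduced (first
A) and sparse sets are whatever the data produce — the package hard-codes
neither their sizes nor their members.

## Classifiers

Five classifier types, with tuned defaults of ridge (L2) regularisation
for the linear SVM and logistic regression and a forest of 500 trees of
maximum depth 1 (decision stumps). Grid-search tuning by cross-validated
balanced accuracy is available (`tune_classifier()`; log-spaced penalty
grids for the linear models, {100, 500} trees × depth {1, 3} for the
forest) and is re-run per feature set in careful analyses; ties go to the
first grid point. Features are standardised with training-fold statistics
for the SVM, logistic regression, LDA and NN, since grams, °C, mA and
N/cm² are not commensurable; the forest is scale-invariant.

The deep neural network follows a fixed printed architecture: two hidden
layers of `int((d + 1)/0.5)` and `int((d + 1)/1)` neurons (24 and 12 at
d = 11), *linear* hidden activations, dropout 0.2 after each hidden
layer, a sigmoid output, binary cross-entropy loss and 1000 training
epochs. It is implemented directly in base-R matrix operations with Adam
(learning rate 0.01, full-batch), seeded weight initialisation and
inverted dropout. Because the hidden activations are linear, the decision
function is affine in the inputs — the network is a heavily
over-parameterised logistic regression, and the test suite checks that
its validation performance tracks logistic regression on linearly
structured data. This is a property of the architecture, not a bug.

## The validation experiment and its controls

Performance is measured by the repeated train/validate experiment: in
each of 100 runs, the classifier trains on a class-proportional random
67% subsample of the training partition (restricted to the feature set
under test) and is evaluated — balanced accuracy and ROC-AUC — on a
class-proportional random 80% subsample of the validation partition. The
run count is indexed by the 5 × 20 fold scheme, and the subsamples are
drawn independently per run; this is the package's resolution of the
coupling between the fold scheme and the printed subsample fractions,
chosen to honour both while yielding exactly 100 samples per cell. Each
cell is summarised by the median and the nonparametric 95% CI (2.5th to
97.5th percentiles), and a classifier counts as *successfully trained*
only when the CI's lower bound exceeds 0.5.

The permutation control re-runs the experiment with every
training-partition column independently permuted afresh each run
(validation data untouched); the unselected control re-runs it on the
complement of the selected variables. `run_pipeline()` assembles the full
five-condition grid — full, reduced, sparse, sparse-permuted, unselected
— for all five classifiers, and writes CSV/JSON artifacts plus a manifest
with the global seed and a configuration hash; a single global seed
deterministically spawns every stage's substream, so re-running a
manifest's seed reproduces every number exactly.

## Numerical choices and edge cases

* Balanced accuracy is (sensitivity + specificity)/2; ROC-AUC uses the
  midrank Mann–Whitney identity, counting ties half.
* A degenerate subsample cannot occur by construction: stratified draws
  keep at least one subject per class.
* Constant variables: undefined F-test p-values mean "not selected";
  correlation and Cohen's d raise errors rather than returning NaN.
* glmnet requires two columns, so single-feature ridge fits carry a
  constant zero pad column whose coefficient is identically zero.
* Ladder snapping resolves midpoint ties toward the weaker filament.
* Seeds are plain 32-bit integers; derived sub-seeds stay below 2³¹.

## Problem sizes used by the shipped tests

The full-fidelity settings (10⁶ split candidates, 5 × 20 folds, 100
evaluation runs) are the package defaults. The test suite exercises the
same code paths at sizes chosen for a single desk CPU: 200–2000 split
candidates, 5 × 1 or smaller fold schemes for selection-matrix builds, 25
seeded replicates for the feature-recovery rate, and 20 seeds × 25 runs
per effect-size level for the monotonicity check. These sizes are stated
here as the package's own reproducibility choices; the defaults remain
the faithful settings.

## Known limitations

* The cABC boundary geometry approximates, but is not verified against,
  the published cABC algorithm's exact limits.
* The censoring-imputation and transformation details of the original
  study are not public; `at_bound`/`tail_draw` are the package's own
  policies.
* The permutation-importance ">0" rule selects null variables in roughly
  half of folds by symmetry; the majority vote across folds, not the rule
  itself, provides the stability.
* Synthetic cohorts are idealised (see above); absolute performance
  levels on them need not match any real cohort — the calibrated
  quantities are the controls (≈ 0.5) and the orderings, not the medians
  on the informative sets.
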