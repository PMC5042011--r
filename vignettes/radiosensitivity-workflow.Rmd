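---
title: "Modelling radiosensitivity from gene and lncRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiosensitivity from gene and lncRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radsens implements a complete workflow for building a transcriptomic
radiosensitivity classifier and validating it in patient cohorts. The
chain has five analytic stages, each exposed as ordinary tibble-in /
tibble-out functions, plus seeded generators that produce synthetic inputs
with the statistical structure each stage assumes. This vignette is the
package's own account of the models, the tunable parameters, and the
design decisions taken where more than one defensible choice existed.

```{r setup}
library(radsens)
```

## The scientific problem

Radiotherapy benefits only a subset of patients, and a patient's intrinsic
radiosensitivity is largely invisible to the clinical variables used for
treatment planning. The working hypothesis of this workflow is that
radiosensitivity leaves a transcriptional signature: genes and long
non-coding RNAs (lncRNAs) whose expression responds to irradiation in
lymphocyte time-courses are candidate markers, and a fixed-size panel of
them, trained against a cell panel's clonogenic survival (SF2, the
surviving fraction after 2 Gy), can classify new samples as radiosensitive
(RS, SF2 at or below 0.4) or radioresistant (RR). The clinical readout is
survival: predicted-RS patients should outlive predicted-RR patients *only
among those actually treated with radiotherapy* (RT+); in untreated (RT−)
patients the marker should be inert. That interaction pattern — effect in
RT+, none in RT− — is the validation target, because a marker that
separates survival in both strata is prognostic rather than predictive of
radiotherapy benefit.

## Stage 1: differential expression in an irradiation time-course

`run_diffexpr()` screens a log2 expression matrix with three time groups
(0h, 2h, 6h post-irradiation) probe by probe:

* one-way fixed-effects ANOVA, `F = MS_between / MS_within` on
  `(k − 1, N − k)` degrees of freedom;
* Tukey's HSD for each pairwise contrast, referring the mean difference to
  the studentized-range distribution with the pooled within-group variance
  (Tukey–Kramer form, so unbalanced groups are handled);
* geometric-mean fold change `2^(Δ mean log2)` per contrast.

`select_differential()` keeps a probe for a contrast when **all three**
gates pass: ANOVA `p < alpha`, that contrast's Tukey `p < alpha`, and
`max(fc, 1/fc) ≥ fc_min`. Defaults are `alpha = 1e-4` and
`fc_min = 1.3` (both directions accepted, boundary inclusive). Only the
two 0h-referenced contrasts drive selection; 6h vs 2h is computed for
completeness but never used to select. Requiring the conjunction of ANOVA
and Tukey is a deliberate choice — either test alone would admit probes the
other rejects — and no multiplicity correction is applied beyond Tukey's
family-wise adjustment, which keeps the screen a per-probe decision rule
with an explicit alpha. Both tests are computed vectorized across probes
(a per-probe `aov()` call would be needlessly slow at array scale); the
test suite pins them to `stats::aov()`/`stats::TukeyHSD()` on small cases.

## Stage 2: co-expression network and gene–lncRNA pairs

On the union of the significant sets, built separately from the 2h and the
6h samples, the package builds a weighted co-expression network in the
WGCNA style, with the network mathematics implemented here:

* unsigned adjacency `a_ij = |cor(i,j)|^β`;
* `β` chosen by `pick_soft_threshold()` as the smallest candidate whose
  connectivity distribution fits a scale-free form with signed `R² ≥ 0.8`
  (equal-width binning of `k`, `log10` frequency regressed on `log10` mean
  `k`; the sign requires a negative slope), falling back to the
  best-fitting candidate;
* topological overlap
  `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, where `ℓ` counts
  shared neighbourhood weight — the similarity that module detection
  clusters on;
* average-linkage hierarchical clustering of `1 − TOM`, cut at a fixed
  fraction of the deepest merge height (0.99/0.97/0.94/0.90 for
  `deep_split` 0–3), keeping clusters of at least `min_module_size`
  (default 30) as modules labelled by decreasing size, everything else
  label 0.

The tree cut is intentionally a simplified "height plus minimum size"
rule rather than the full hybrid dynamic-cut algorithm: downstream stages
consume only module membership, and the planted-module recovery tests
(adjusted Rand index ≥ 0.9 on two latent-factor blocks) are the behaviour
that matters. Unsigned adjacency is the conventional default when nothing
argues for sign preservation. `extract_pairs()` then emits every
same-module lncRNA–gene pair with Pearson `r ≥ 0.75` — the threshold is
inclusive, since published pair tables list pairs at exactly 0.75 — and
`pool_predictor_candidates()` deduplicates the paired probes into the
candidate pool for feature selection. On the bundled 43-pair table this
pool is 41 probes: 34 genes and 7 lncRNAs.

## Stage 3: genetic-algorithm predictor search with SVM fitness

The pool is searched for the best fixed-size predictor combination
(`k = 20` by default; `choose(41, 20)` = 269,128,937,220 combinations, so
exhaustive search is out of the question — `search_space_size()` computes
this exactly with bignum arithmetic). `evolve()` implements a genetic
algorithm faithful to the workflow it models:

* **fitness** — `cv_accuracy()`: stratified 5-fold cross-validation of a
  linear-kernel SVM (cost 1), features standardized inside each fold by
  training-fold statistics, pooled test-fold accuracy. The fold partition
  is built once per run and reused for every chromosome. This is the key
  reproducibility decision: with re-randomized folds, roulette selection
  would be comparing CV noise rather than combinations.
* **selection** — roulette: parent probability is accuracy divided by the
  population's total accuracy.
* **crossover** — shared predictors are always kept; a uniform random
  number of parent-specific predictors is exchanged. There is no mutation
  operator: diversity comes from the random initial population (100
  uniform random k-subsets) and crossover.
* **elitism** — the single best chromosome is carried forward unchanged,
  which makes the best-fitness trace non-decreasing by construction (an
  invariant the tests assert on every run).

The SVM kernel and cost are not dictated by the modelled workflow; linear
kernel with unit cost and within-fold standardization was chosen because
with 60 samples and 20 features it is the most reproducible and least
tunable option. Fitness is pooled accuracy rather than mean-of-folds (the
two differ only under unequal fold sizes), and the reported model is the
best-ever chromosome, which under elitism is also the final generation's
best.

`permutation_null()` quantifies the selected combination against chance:
`n_perm` uniform random k-subsets of the same pool, scored on the *same*
fold partition, with the add-one empirical p-value
`(#{null ≥ observed} + 1) / (n_perm + 1)` — never zero by construction.
`compare_biotype_contribution()` splits the null draws by whether they
contain a lncRNA probe, the comparison used to ask whether lncRNAs add
predictive value.

## Stage 4: survival validation

`train_final_model()` freezes the classifier as explicit weights,
intercept and standardization constants (serializable to plain JSON at
full precision via `write_model()`/`read_model()`).
`classify_patients()` applies it to a patient table after standardizing
each predictor *within the cohort*; the training panel and patient arrays
are different platforms, and per-cohort centring/scaling absorbs additive
per-feature platform offsets without requiring any cross-platform
calibration data. `validate_cohort()` then runs the chain: truncate
follow-up at 24 months (dichotomized overall survival within two years is
the clinically reported horizon; truncation is applied before both the
Kaplan–Meier and the Cox analyses for consistency), classify, and within
each radiotherapy stratum compare predicted groups by log-rank and by a
Cox proportional-hazards fit (Efron tie handling, the modern default).
The model group is coded RR = 1 vs RS = 0, so hazard ratios above 1 mean
predicted-resistant patients die faster; published validations report the
model's hazard ratio on the same side. Patients with missing covariate
values are dropped from the Cox fit only, with a logged count.

## The synthetic-data generators

Every stage is testable offline because the generators reproduce the
statistical skeleton of the real inputs:

* `simulate_timecourse()` — three groups of `n_per_group` samples; planted
  differentially expressed probes shift by `effect_log2` (default 1) at 2h
  and 6h; modules are induced by one latent factor per module with loading
  `sqrt(within_module_r)`, the simplest mechanism giving controllable
  exchangeable intra-module correlation; each module contains
  `lnc_per_module` lncRNA-annotated probes; residual SD defaults to 0.4 on
  the log2 scale, a typical post-normalization microarray noise level
  (and one at which a 1-unit log2 shift is a ~2.5 SD effect, comfortably
  detectable at `alpha = 1e-4` with 50 samples per group).
* `simulate_cell_panel()` — `n_samples` lines (default 60, the size of the
  classic cell panel); SF2 drawn from two Beta(2, 2) distributions
  rescaled to either side of the 0.4 threshold so the dichotomization
  step has real work to do and class counts match `rs_fraction` exactly;
  a planted subset of features separated between classes by `effect`
  standardized units; all other features pure noise. Nothing is published
  about the real panel's SF2 distribution — the Beta shapes are a
  modelling choice, not an inference.
* `simulate_patient_cohort()` — patients carry a latent RS/RR state
  (prevalence 0.5), predictor expression drawn from the panel's class
  distributions plus a per-feature additive platform shift drawn once per
  cohort (exercising the per-cohort standardization above), and
  exponential survival — constant hazard, chosen so parameter-recovery
  tests have closed-form truth — with the RR hazard multiplied by
  `hr_rs_rtpos` in the treated stratum and `hr_rs_rtneg` (default 1) in
  the untreated one. Censoring is administrative: a random uniform
  censoring time with probability `censor_rate`, plus a follow-up cap.

Every generator is a pure function of its spec, including the seed, so
identical specs give bit-identical data.

What the generators deliberately do **not** emulate: probe-level array
artefacts, batch structure beyond the single additive platform shift,
non-proportional or non-constant hazards, correlated non-planted features,
and any real biology of the diseases involved. Tests passing on this
synthetic structure demonstrate that the machinery is correct and
calibrated — not that the workflow's biological conclusions transfer to
real cohorts.

## Numerical choices and degenerate inputs

* Quantile normalization (delegated to `limma::normalizeQuantiles`)
  averages reference values over ties and is idempotent to 1e-9; it
  refuses single-sample input.
* Constant probes make correlation undefined; the network stage errors
  and names them rather than silently dropping.
* Constant data in the ANOVA yields `F = 0, p = 1` (rather than 0/0).
* SF2 exactly at the threshold is RS (documented tie rule).
* `make_cv_folds()` reduces the fold count, with a warning, when a class
  is smaller than the requested fold count; an all-zero fitness vector
  makes roulette selection uniform.
* Cluster labels are contiguous and size-ordered; probes in clusters below
  the minimum size get label 0 and never pair.
* The GA fills odd population remainders by dropping one child of the last
  crossover pair.

## Problem sizes and runtime

The defaults used by the test suite and the demo pipeline are deliberately
modest: time-courses of a few hundred to ten thousand probes, the
60-sample/41-feature panel, GA populations of 100 for 50 generations, and
permutation nulls of 10⁴ draws. A full GA run at those sizes is about a
minute on one core (fitness caching means converged populations cost
little), and the 10⁴-draw null is a few minutes. The generators scale to
larger designs if needed.

## Known limitations

* With the default panel conditions (per-feature standardized effect 1.5,
  20 planted features among 41, n = 60), pooled 5-fold CV accuracy of the
  linear SVM *saturates*: a typical random 20-subset already contains
  about ten planted features and separates the classes by more than 4 SD,
  so a substantial fraction of random subsets scores a perfect 1.0. On
  such a plateau the GA's fitness signal vanishes — it cannot distinguish
  the planted subset from any other perfect scorer, planted-feature
  recovery stalls near the hypergeometric chance level, and the
  permutation null ties with the observed optimum, keeping the empirical
  p-value far from its add-one floor. Meaningful recovery and a sharp
  permutation p require a regime where accuracy still climbs as planted
  features are added (roughly, per-feature effects a third this size).
  The package reports what the data admit rather than engineering the
  generator around it.
* The classifier is a hard dichotomizer; radiosensitivity is plausibly
  continuous, and nothing here models a graded response.
* Per-cohort standardization assumes additive platform effects and a
  cohort that is not overwhelmingly one class; a cohort of almost-all-RR
  patients would shift the decision boundary.
* The simplified tree cut can split large loose modules differently from
  the full hybrid algorithm; only module membership, not dendrogram
  fidelity, is guaranteed.
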