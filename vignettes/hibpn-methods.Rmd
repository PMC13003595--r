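---
title: "Bidirectional prediction of social exclusion and hostile interpretation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional prediction of social exclusion and hostile interpretation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibpn)
```

## The scientific problem

Hostile interpretation bias — the tendency to read ambiguous social cues as
hostile — interacts with narcissistic personality traits and with experiences
of social exclusion in a reciprocal loop: trait-disposed individuals
interpret neutral interactions as exclusion, and perceived exclusion
reinforces hostile interpretation. Linear models struggle with this because
the interactions are conditional (for instance, exclusion sharply elevates
hostile interpretation in grandiose narcissists but vulnerable narcissists
sit high in both conditions).

HIBPN (Hostile Interpretation and Bidirectional Prediction Network) frames
the loop as two supervised problems over the same participant records:

* **forward chain** — predict whether a participant is in a social-exclusion
  or social-acceptance Cyberball condition from demographics, basic-needs
  threat, estimated catch percentage, narcissism scores, and the hostile /
  non-hostile interpretation scores;
* **reverse chain** — predict whether a participant falls in the high
  hostile-interpretation bin (summed score at or above 36) from
  demographics, situational covariates *including* the condition indicator,
  and narcissism scores.

## Network architecture

Three encoder modules feed the two heads:

* a **human-environment encoder**: a two-layer MLP that first upscales the
  covariates (default width 32) and then downscales (default 8). The
  upscale-then-downscale shape preserves interaction information between
  traits and situation before compressing to a core representation; the
  constructor rejects configurations that do not upscale then downscale.
* a **narcissism encoder**: a single upscaling layer (default 2 inputs to 8
  units) over the NPI-16 and HSNS totals.
* a **hostile-interpretation encoder**: a single layer (default 2 inputs to
  4 units) over the standardized hostile and non-hostile scores. How this
  intermediate feature is built is a genuine design choice (no construction
  is prescribed); we use the minimal one-layer encoding consistent with the
  other modules.

The forward head concatenates all three encodings and applies a sigmoid
hidden layer (default 16 units) and a sigmoid output — the probability of
exclusion. The reverse head concatenates only the first two encodings and
applies a ReLU hidden layer and a linear output. The reverse head is dual
mode: the linear output is the continuous bias value; applying a sigmoid to
the same pre-activation gives the probability of the high-hostility bin.
Classification mode is the default because the evaluation protocol scores
the reverse chain with ACC/F1/AUC.

Hidden activations are ReLU throughout, except the forward head where both
layers are sigmoid as specified for the exclusion classifier. An
`activation = "identity"` option supports the linearization check in the
test suite, which verifies that a pass-through configuration reproduces the
probabilities of a logistic regression exactly.

**Anti-leakage rule.** The condition label is the forward chain's target,
so the condition indicator is excluded from every forward-chain input and
included in the reverse chain's inputs. A test verifies that permuting the
condition column changes no forward prediction.

**Independent chains.** The two chains are trained independently with
separate encoder weights. Joint training or weight sharing was never
specified for the method and sharing the human-environment encoder would
leak the condition indicator into the forward chain, so independence is
both the conservative and the safe reading.

## Training

* 1:9 protocol: `split_1_9()` places `round(0.10 n)` records in training and
  the rest in test, stratified by the target so both classes appear in
  training. The ratio reads "1:9" as train:test — the protocol deliberately
  probes generalization from scarce data; a config flag allows the opposite
  reading for sensitivity analysis.
* Loss: binary cross-entropy for both classification heads, mean squared
  error in the reverse chain's regression mode.
* Optimizer: full-batch gradient descent, fixed learning rate (default 0.1,
  500 epochs). With a few hundred training rows and networks of a few
  hundred parameters, full-batch descent is fast, free of minibatch noise,
  and bit-reproducible given the seed. He-style initialization
  (`sd = sqrt(2/fan_in)`) keeps ReLU pre-activations stable.
* Standardization: continuous inputs are z-scored with training-set
  statistics; 0/1 indicators pass through. Test rows never contribute to
  the scaler or the gradients (verified by a bit-identity test).

## The synthetic cohort generator

No participant-level records from the underlying Cyberball experiments are
publicly deposited, so the generator is a first-class module that emulates
the reported statistical structure. Its defaults *are* the study
conditions:

| knob | default | source / rationale |
|---|---|---|
| trait-group proportions | 27 / 27 / 46 % | top-27% selection rule on each narcissism scale |
| interpretation scores | per-cell normal, truncated to 12–60, integer-rounded | the six reported group-by-condition cell means/SDs |
| exclusion pass schedule | exactly 2 catches of 30, both in passes 1–15 | reported 6.67% catch rate; avatars keep the ball in the second half |
| acceptance pass schedule | Bernoulli(1/3) per pass | reported 33.33% catch probability |
| condition ratio | 0.5 | the real split is reported only as "not 1:1"; exposed rather than guessed |
| basic-needs effect | −10 points under exclusion, baseline N(70, 8) on 20–100 | no cell statistics are reported; −10 puts excluded participants near the debrief threshold of 60 that the protocol treats as meaningful |
| catch-estimate noise | SD 8 percentage points | participants misestimate but track the true rate; keeps the two conditions distinguishable yet overlapping |
| gender, age | 2:1 male, uniform 19–22 | the reported intervention-study composition (24/12) and age range |
| narcissism scores | dominant: NPI ~ N(13, 1.5), HSNS ~ N(27, 5); implicit: HSNS ~ N(42, 3), NPI ~ N(6, 2.5); neutral: N(6, 2.5) / N(27, 5) | chosen once so each group sits in the upper range of its defining scale, making top-27% selection self-consistent |
| intervention arms | 18 + 18, implicit-only, 5-point hostile reduction | the reported arm sizes; the effect size is unreported, 5 points is the centre of the sensitivity grid {0, 2.5, 5, 10} |

Sampling uses the inverse-CDF of the range-truncated normal with a
continuity correction before integer rounding, so cell means are recovered
essentially unbiased (the tests compare sample means against the analytic
truncated-normal mean, and against the configured mean where truncation is
negligible — it distorts no cell mean by more than 0.25 points).

**What the generator does not emulate.** Item-level response vectors for
the NPI/HSNS (totals are drawn directly), correlations between hostile and
non-hostile scores within participant, avatar-to-avatar pass dynamics, and
any real-world dependence between narcissism and condition assignment
(conditions are randomized within trait group, as in the protocol).
Passing tests therefore demonstrate that the pipeline recovers structure
*of the kind reported*, not that it reproduces the original human data;
the absolute metric values from the undeposited data are out of reach by
construction.

## Evaluation

ACC, F1 (positive class: exclusion on the forward chain, high hostility on
the reverse) and ROC/AUC are computed in one shared code path used by the
network and all ten baselines. AUC credits tied scores 1/2 (Mann–Whitney
convention), which makes trapezoidal integration identical to
concordant-pair counting — the suite checks this exhaustively at small n
and against an independent ROC implementation. F1 is defined as 0 with a
warning when precision + recall is degenerate.

Drop percentages between models are `100 (ref − value) / denominator`.
Both denominator conventions are exposed because the reported ablation
accuracy drop uses the ablated value as denominator while every other
quoted drop uses the full model; the inconsistency is documented, not
resolved.

## Baselines, ablation, importance, intervention

* **Baselines**: logistic regression, random forest, gradient boosting,
  AdaBoost, SVM, naive Bayes, k-NN, LDA, QDA, decision tree — library
  implementations behind one adapter (AdaBoost is a discrete SAMME over
  stumps implemented here). SVM and AdaBoost contribute monotone decision
  values for ROC; scores are never re-oriented to flatter AUC.
  Hyperparameters are library defaults; none are reported for the original
  comparison, so absolute baseline numbers are not reproduction targets.
* **Ablation** retrains (never weight-zeroes) the forward chain without the
  narcissism group (encoder + trait indicators) or without the
  interpretation encoder, on the identical split.
* **Grouped importance** fits a 500-tree random forest on exactly the
  inputs the chain sees and sums Gini importances within the three
  dimension groups, normalized to 100%. Gender and age are mapped to the
  social-exclusion (human-environment) group so that every model column
  belongs to exactly one group; on the reverse chain the
  hostile-interpretation group is empty by the anti-leakage rule and is
  reported as 0 with a warning.
* **Intervention contrast**: the trained forward chain classifies each arm
  of the 18+18 intervention cohort; the positive response rate is the
  fraction predicted accepted, and the contrast is the arm difference in
  percentage points.

## Numerical choices and degenerate inputs

* Trait-group assignment: `round(0.27 n)` members per narcissism group,
  ranks tie-broken by ascending participant index; a participant in both
  top-27% sets goes to the scale with the higher percentile (HSNS on exact
  ties) and the other set back-fills from the next rank, so group sizes are
  exact and assignment is deterministic.
* Hostile binning: single cut at 36 over the attainable range 12–60. The
  published bin edges (15–35, 36–55) describe the observed data, not the
  instrument, so out-of-bin scores inside 12–60 are mapped by the same cut
  and scores outside 12–60 are rejected.
* Cross-entropy is clamped with eps = 1e-12; non-finite loss aborts with a
  diagnostic; zero epochs return the initialization unchanged.
* QDA falls back to a jittered refit (SD 1e-6) on singular covariance,
  with a warning.

## Problem sizes used by the test suite

Property tests run at sizes chosen to keep Monte-Carlo error well below
the tested effects: cell-mean recovery and pass-rate checks at n = 10,000
(3 standard errors); planted-signal recovery at n = 2,000 over 20 seeds;
null calibration at n = 1,000 over 10 seeds; ablation orderings at
n = 1,500; intervention monotonicity with 200-participant arms over 20
seeds per effect size. Planted-mechanism configurations (flattened
covariates, globally condition-linked hostile scores) are constructed in
the test helpers; they are analysis conditions for the properties under
test, not generator defaults.

## Known limitations

* The reverse chain's continuous (regression) output shares parameters
  with the classification head rather than being trained separately under
  MSE by default; experiments use classification mode throughout.
* The generator draws scale totals, not items, so item-level reliability
  analyses are out of scope.
* With the default catch-estimate noise the estimated catch percentage is
  a strong condition signal, so forward-chain metrics on synthetic
  cohorts are optimistic relative to any real cohort; tests that need
  unsaturated predictions flatten this covariate deliberately.
* Absolute performance tables from the original human-subjects data
  cannot be reproduced (data unavailable); the pipeline instead reproduces
  the printed arithmetic and the qualitative orderings under planted
  conditions.
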