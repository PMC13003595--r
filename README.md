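# hibpn

Bidirectional prediction of social exclusion and hostile interpretation
bias in narcissism research.

## What this package is for

In Cyberball-style social-exclusion experiments, three quantities are
entangled: narcissistic personality traits (grandiose/dominant, measured by
the NPI-16; vulnerable/implicit, measured by the Hypersensitive Narcissism
Scale), the situational state (social exclusion vs. acceptance), and
hostile interpretation bias (summed likelihood ratings of hostile readings
of ambiguous sentences). Their interactions are conditional and nonlinear,
which frustrates the usual regression toolkit.

`hibpn` implements the **Hostile Interpretation and Bidirectional
Prediction Network (HIBPN)**, a modular multilayer perceptron with two
prediction chains over the same participant records:

* **forward chain** — P(social exclusion | traits, cognition, covariates):

  ẑₑ = σ(Wₑ · σ(Wₑ⁽¹⁾ · [A_he ‖ A_n ‖ A_h] + bₑ⁽¹⁾) + bₑ)

* **reverse chain** — hostile interpretation bias | traits, situation:

  ŷ_h = W_h · σ(W_h⁽¹⁾ · [A_he ‖ A_n] + b_h⁽¹⁾) + b_h

where A_he is an upscale-then-downscale encoding of the human-environment
covariates, A_n an upscaled encoding of the two narcissism totals, and A_h
a one-layer encoding of the interpretation scores. The condition indicator
is excluded from forward-chain inputs (it is the target) and included in
reverse-chain inputs.

Around the network, the package provides the full experimental harness:

* psychometric scoring (NPI-16, HSNS, Basic Needs Scale with reverse-keyed
  items, interpretation ratings, low/high binning at 36, top-27% trait
  grouping);
* a synthetic cohort generator emulating the experiments' reported
  structure (group-by-condition score distributions, 2-of-30 vs.
  Bernoulli(1/3) Cyberball schedules, basic-needs deficit under exclusion,
  18+18 self-affirmation arms) — no participant data is deposited, so this
  module makes every downstream stage testable;
* ten classical baselines behind one adapter, evaluated through the same
  ACC/F1/ROC/AUC code path as the network;
* module ablation, grouped random-forest feature importance, and the
  intervention contrast (predicted acceptance rate per arm);
* a thin command-line front end (`inst/cli/hibpn.R`) with `score`,
  `simulate`, `train`, `evaluate`, `compare`, `ablate`, `importance`,
  `exp2` subcommands.

## Worked example

```r
library(hibpn)

cohort <- generate_cohort(cohort_config(n_participants = 258, seed = 42))
dplyr::count(cohort, trait_group, condition)
#>   trait_group condition      n
#> 1 dominant    acceptance    35
#> 2 dominant    exclusion     35
#> 3 implicit    acceptance    35
#> 4 implicit    exclusion     35
#> 5 neutral     acceptance    59
#> 6 neutral     exclusion     59
```

258 participants split 70/70/118 into dominant, implicit and neutral trait
groups (the 27/27/46% selection rule), with conditions randomized within
group. Train on 10% and evaluate on the held-out 90% (the 1:9 protocol):

```r
split <- split_1_9(cohort, "condition", train_config(seed = 42))
fit <- hibpn_fit(split$train, config = train_config(seed = 42))
fit
#> Bidirectional prediction network fit
#>   chains: forward, reverse | training rows: 26 | epochs: 500
#>   forward-chain final training loss: 0.0113
#>   reverse-chain final training loss: 0.0046

te <- encode_features(split$test, "forward")
evaluate_scores(te$y, predict(fit, split$test, chain = "forward"))[, 1:4]
#>     acc    f1   auc n_test
#> 1 0.862 0.876 0.949    232
```

The forward chain separates excluded from accepted participants well on
synthetic cohorts (AUC 0.95 here), largely because the estimated catch
percentage tracks the true pass rate. `run_experiment1()` builds the full
model-comparison table on an identical split:

```r
exp1 <- run_experiment1(cohort, config = train_config(seed = 42),
                        specs = baseline_specs(c("logistic_regression",
                                                 "decision_tree"), seed = 42))
dplyr::select(exp1$metrics, model, chain, acc, f1, auc)
#>   model               chain     acc    f1   auc
#> 1 hibpn               forward 0.862 0.876 0.949
#> 2 logistic_regression forward 0.836 0.855 0.909
#> 3 decision_tree       forward 0.879 0.882 0.879
#> 4 hibpn               reverse 0.703 0.763 0.760
#> 5 logistic_regression reverse 0.75  0.775 0.775
#> 6 decision_tree       reverse 0.668 0.609 0.715
```

Grouped feature importance over the reverse chain's inputs shows
narcissism as the dominant dimension (the hostile-interpretation group is
empty on this chain — those scores are its target — and reports 0):

```r
dimension_importance(cohort, "reverse", seed = 42)
#>   chain   dimension              weight_pct
#> 1 reverse social_exclusion             39.5
#> 2 reverse hostile_interpretation        0
#> 3 reverse narcissism                   60.5
```

`run_ablation()` retrains without a feature group and reports drops in both
denominator conventions; `run_experiment2()` contrasts the predicted
acceptance rates of the self-affirmation and control arms. `autoplot()`
methods plot ROC curves, metric tables, importance weights and arm rates;
`tidy()`/`glance()` summarize fits.

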