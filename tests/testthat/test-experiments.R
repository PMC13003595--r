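test_that("the comparison experiment evaluates every model on both chains", {
  coh <- generate_cohort(cohort_config(n_participants = 400, seed = 51))
  cfg <- train_config(epochs = 200, seed = 51)
  exp1 <- run_experiment1(coh, config = cfg,
                          specs = baseline_specs(c("logistic_regression",
                                                   "decision_tree", "knn"), seed = 51))
  expect_equal(nrow(exp1$metrics), (1 + 3) * 2)
  expect_setequal(unique(exp1$metrics$chain), c("forward", "reverse"))
  expect_true(all(exp1$metrics$model[c(1, 5)] == "hibpn"))
  expect_true(all(exp1$metrics$n_test == nrow(coh) - round(0.1 * nrow(coh))))
  expect_named(exp1$manifest, c("seed", "config", "dims", "n", "baselines"))
})

test_that("ablation retrains on the identical split and matches the full fit", {
  coh <- generate_cohort(cohort_config(n_participants = 400, seed = 53))
  cfg <- train_config(epochs = 200, seed = 53)
  abl <- run_ablation(coh, config = cfg)
  expect_setequal(abl$metrics$variant,
                  c("all_features", "without_narcissism", "without_hostile_interpretation"))
  exp1 <- run_experiment1(coh, config = cfg, specs = baseline_specs("knn", seed = 53),
                          chains = "forward")
  full_row <- abl$metrics[abl$metrics$variant == "all_features", c("acc", "f1", "auc")]
  hib_row <- exp1$metrics[exp1$metrics$model == "hibpn", c("acc", "f1", "auc")]
  expect_equal(as.data.frame(full_row), as.data.frame(hib_row))
  expect_equal(nrow(abl$gaps), 2)
})

test_that("dropping the signal-bearing group hurts; dropping a noise group does not", {
  # hostile scores carry a strong condition signal only for the dominant
  # group; covariates are flattened so the interpretation block is the carrier
  t1 <- interpretation_cell_params()
  t1$hostile_mean <- ifelse(t1$condition == "exclusion", 44, 30)
  coh <- generate_cohort(flat_covariate_config(1500, seed = 55, table1 = t1))
  cfg <- train_config(epochs = 400, seed = 55)
  abl <- run_ablation(coh, config = cfg)
  m <- function(v) abl$metrics$auc[abl$metrics$variant == v]
  expect_gt(m("all_features"), 0.75)
  # hostile block carries the planted signal
  expect_lt(m("without_hostile_interpretation"), 0.6)
  # narcissism block is condition-independent noise here
  expect_gt(m("without_narcissism"), m("without_hostile_interpretation"))
})

test_that("ablation ordering flips under planted narcissism dominance", {
  # narcissism columns carry the dominant condition signal; the hostile block
  # keeps only a weak uniform shift
  t1 <- interpretation_cell_params()
  t1$hostile_mean <- ifelse(t1$condition == "exclusion", 37, 35)
  coh <- generate_cohort(flat_covariate_config(1500, seed = 57, table1 = t1))
  withr::with_seed(57, {
    bump <- ifelse(coh$condition == "exclusion", 3, 0)
    coh$npi16_score <- pmin(16L, pmax(0L, as.integer(coh$npi16_score + bump +
                                                       round(rnorm(nrow(coh), 0, 1)))))
    coh$hsns_score <- pmin(50L, pmax(10L, as.integer(coh$hsns_score + 2L * bump +
                                                       round(rnorm(nrow(coh), 0, 2)))))
  })
  abl <- run_ablation(coh, config = train_config(epochs = 400, seed = 57))
  m <- function(v) abl$metrics$auc[abl$metrics$variant == v]
  expect_gt(m("without_hostile_interpretation"), m("without_narcissism"))
  expect_gt(abl$gaps$auc_drop_ref[abl$gaps$variant == "without_narcissism"],
            abl$gaps$auc_drop_ref[abl$gaps$variant == "without_hostile_interpretation"])
})

test_that("importance weights sum to 100 and respect planted dominance", {
  coh <- generate_cohort(cohort_config(n_participants = 500, seed = 61))
  for (ch in c("forward", "reverse")) {
    imp <- suppressWarnings(dimension_importance(coh, ch, ntree = 200, seed = 61))
    expect_equal(sum(imp$weight_pct), 100, tolerance = 0.01)
    expect_true(all(imp$weight_pct >= 0))
  }
  # flattened covariates leave narcissism as the only hostile-bin signal
  coh2 <- generate_cohort(flat_covariate_config(800, seed = 63))
  imp2 <- suppressWarnings(dimension_importance(coh2, "reverse", ntree = 300, seed = 63))
  expect_equal(imp2$dimension[which.max(imp2$weight_pct)], "narcissism")
  # empty hostile-interpretation group on the reverse chain reports 0
  expect_equal(imp2$weight_pct[imp2$dimension == "hostile_interpretation"], 0)
  expect_warning(dimension_importance(coh2, "reverse", ntree = 50, seed = 1),
                 "empty")
})

test_that("the intervention contrast reports per-arm predicted acceptance", {
  train_coh <- generate_cohort(cohort_config(n_participants = 1000, seed = 65,
                                             catch_noise_sd = 30))
  sp <- split_1_9(train_coh, "condition", train_config(seed = 65))
  fwd <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = 65))

  coh2 <- generate_intervention_cohort(cohort_config(seed = 65, catch_noise_sd = 30))
  rep2 <- run_experiment2(coh2, fwd)
  expect_equal(nrow(rep2), 2)
  expect_equal(sum(rep2$n), 36)
  expect_true(all(rep2$positive_response_rate >= 0 & rep2$positive_response_rate <= 1))
  expect_equal(attr(rep2, "difference_pct"),
               intervention_difference(
                 rep2$positive_response_rate[rep2$arm == "self_affirmation"],
                 rep2$positive_response_rate[rep2$arm == "control"]))

  no_arms <- dplyr::mutate(coh2, intervention = factor("none",
                                                       levels = levels(coh2$intervention)))
  expect_error(run_experiment2(no_arms, fwd), class = "hibpn_validation_error")
})

test_that("the predicted intervention effect grows with the planted effect", {
  # mechanism cohort: hostile interpretation tracks exclusion in every trait
  # group, covariates stay noisy enough that predictions are not saturated
  t1 <- global_assoc_table1()
  train_coh <- generate_cohort(cohort_config(n_participants = 2000, seed = 67,
                                             catch_noise_sd = 30, table1_params = t1))
  sp <- split_1_9(train_coh, "condition", train_config(seed = 67))
  fwd <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = 67))

  mean_diff <- vapply(c(0, 2.5, 5, 10), function(eff) {
    diffs <- vapply(1:20, function(s) {
      cc <- cohort_config(arm_sizes = c(self_affirmation = 200L, control = 200L),
                          affirmation_effect = eff, catch_noise_sd = 30,
                          table1_params = t1, seed = 700 + s)
      attr(run_experiment2(generate_intervention_cohort(cc), fwd), "difference_pct")
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_gt(mean_diff[3], 0) # a real 5-point effect shows up as positive
  expect_gt(mean_diff[4], mean_diff[1]) # and grows with the planted size
  expect_true(all(diff(mean_diff) > -1)) # monotone up to Monte-Carlo noise
})
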