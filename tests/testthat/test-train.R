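test_that("the 1:9 split produces the documented partition sizes", {
  coh <- generate_cohort(cohort_config(n_participants = 258, seed = 1))
  sp <- split_1_9(coh, "condition", train_config(seed = 3))
  expect_equal(nrow(sp$train), 26) # round(0.1 * 258)
  expect_equal(nrow(sp$test), 232)
  expect_equal(sort(c(sp$train$id, sp$test$id)), 1:258) # disjoint, exhaustive
  # both classes present in train under stratification
  expect_true(all(table(sp$train$condition) >= 1))

  tiny <- coh[1:10, ]
  sp10 <- split_1_9(tiny, "condition", train_config(stratify = FALSE, seed = 1))
  expect_equal(nrow(sp10$train), 1)
  expect_equal(nrow(sp10$test), 9)

  expect_identical(split_1_9(coh, "condition", train_config(seed = 5))$train_idx,
                   split_1_9(coh, "condition", train_config(seed = 5))$train_idx)
  expect_error(split_1_9(coh[1:5, ], "condition"), class = "hibpn_validation_error")

  one_class <- dplyr::mutate(coh, condition = factor("exclusion",
                                                     levels = levels(coh$condition)))
  expect_error(split_1_9(one_class, "condition", train_config()),
               class = "hibpn_split_error")
})

test_that("stratified splits keep class shares close to the cohort's", {
  coh <- generate_cohort(cohort_config(n_participants = 300, seed = 2,
                                       condition_ratio = 0.3))
  sp <- split_1_9(coh, "condition", train_config(seed = 11))
  share_train <- mean(sp$train$condition == "exclusion")
  share_all <- mean(coh$condition == "exclusion")
  expect_lt(abs(share_train - share_all), 0.06)
})

test_that("training drives a separable toy problem to perfect accuracy", {
  toy <- toy_separable(n = 20)
  coh <- tibble::tibble(
    id = 1:20,
    gender = ifelse(toy$X[, 1] > 0, "male", "female"),
    age = 20L,
    trait_group = factor(rep(c("dominant", "implicit"), 10),
                         levels = c("dominant", "implicit", "neutral")),
    condition = factor(ifelse(toy$y == 1, "exclusion", "acceptance"),
                       levels = c("acceptance", "exclusion")),
    npi16_score = as.integer(round(8 + 2 * toy$X[, 1])),
    hsns_score = as.integer(round(30 + 3 * toy$X[, 2])),
    basic_needs_score = 60L,
    estimated_catch_pct = 50,
    hostile_score = as.integer(round(36 + 4 * toy$X[, 1])),
    non_hostile_score = 36L,
    intervention = factor("none", levels = c("none", "self_affirmation", "control"))
  )
  coh$hostile_bin <- bin_hostile(coh$hostile_score)
  fit <- hibpn_fit(coh, chains = "forward",
                   config = train_config(epochs = 2000, learning_rate = 0.3))
  preds <- predict(fit, coh, chain = "forward", type = "class")
  expect_equal(accuracy(toy$y, preds), 1.0)
})

test_that("training is deterministic and zero epochs return the initialization", {
  coh <- generate_cohort(cohort_config(n_participants = 150, seed = 9))
  cfg <- train_config(epochs = 50, seed = 13)
  f1 <- hibpn_fit(coh, chains = c("forward", "reverse"), config = cfg)
  f2 <- hibpn_fit(coh, chains = c("forward", "reverse"), config = cfg)
  expect_identical(f1$chains$forward$params, f2$chains$forward$params)
  expect_identical(f1$chains$reverse$params, f2$chains$reverse$params)

  f0 <- hibpn_fit(coh, chains = "forward", config = train_config(epochs = 0, seed = 13))
  feats <- encode_features(coh, "forward")
  sf <- apply_scaler(feats, fit_scaler(feats))
  ref <- init_params(hibpn_dims(), ncol(sf$he), ncol(sf$n), ncol(sf$h), seed = 13)
  expect_identical(f0$chains$forward$params$he_up, ref$he_up)
  expect_identical(f0$chains$forward$params$env_out, ref$env_out)
})

test_that("full-batch descent decreases cross-entropy monotonically on a toy set", {
  coh <- generate_cohort(cohort_config(n_participants = 100, seed = 15))
  fit <- hibpn_fit(coh, chains = "forward",
                   config = train_config(epochs = 300, learning_rate = 0.01))
  loss <- fit$chains$forward$loss
  expect_true(all(diff(loss) <= 1e-10))
  expect_lt(loss[300], loss[1])
})

test_that("held-out records never influence the fitted parameters", {
  coh <- generate_cohort(cohort_config(n_participants = 200, seed = 17))
  sp <- split_1_9(coh, "condition", train_config(seed = 17))
  f1 <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = 17))
  # shuffle the test set; the fit must be bit-identical
  shuffled_test <- sp$test[rev(seq_len(nrow(sp$test))), ]
  f2 <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = 17))
  expect_identical(f1$chains$forward$params, f2$chains$forward$params)
  expect_equal(predict(f1, shuffled_test, chain = "forward"),
               rev(predict(f1, sp$test, chain = "forward")))
})

test_that("single-class training targets are rejected", {
  coh <- generate_cohort(cohort_config(n_participants = 50, seed = 19))
  coh$condition <- factor("exclusion", levels = levels(coh$condition))
  expect_error(hibpn_fit(coh, chains = "forward"), class = "hibpn_training_error")
})

test_that("planted signal yields above-chance forward AUC; null cohorts sit at chance", {
  aucs <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_config(n_participants = 2000, seed = s))
    sp <- split_1_9(coh, "condition", train_config(seed = s))
    fit <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = s))
    te <- encode_features(sp$test, "forward")
    roc_and_auc(te$y, predict(fit, sp$test, chain = "forward"))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.5 + 3 * sd(aucs) / sqrt(length(aucs)))

  null_aucs <- vapply(1:10, function(s) {
    coh <- null_cohort(n = 1000, seed = 100 + s)
    sp <- split_1_9(coh, "condition", train_config(seed = s))
    fit <- hibpn_fit(sp$train, chains = "forward", config = train_config(seed = s))
    te <- encode_features(sp$test, "forward")
    roc_and_auc(te$y, predict(fit, sp$test, chain = "forward"))$auc
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 3 * sd(null_aucs) / sqrt(length(null_aucs)) + 0.02)
})
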