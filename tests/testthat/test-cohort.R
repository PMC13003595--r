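test_that("Cyberball exclusion games give exactly 2 first-half catches", {
  for (s in 1:25) {
    g <- simulate_cyberball("exclusion", seed = s)
    expect_equal(g$catches, 2L)
    expect_equal(g$catch_rate_pct, 6.67)
    expect_equal(sum(g$schedule), 2L)
    expect_true(all(which(g$schedule == 1) <= 15)) # avatars only in 2nd half
  }
  expect_error(simulate_cyberball("banished"))
})

test_that("Cyberball acceptance games average a one-third catch rate", {
  rates <- vapply(1:2000, function(s)
    simulate_cyberball("acceptance", seed = s)$catch_rate_pct, numeric(1))
  se <- 100 * sqrt((1 / 3) * (2 / 3) / 30) / sqrt(2000)
  expect_lt(abs(mean(rates) - 100 / 3), 3 * se)
})

test_that("same condition and seed reproduce the identical schedule", {
  expect_identical(simulate_cyberball("acceptance", seed = 9),
                   simulate_cyberball("acceptance", seed = 9))
  expect_identical(simulate_cyberball("exclusion", seed = 9),
                   simulate_cyberball("exclusion", seed = 9))
})

test_that("interpretation sampler recovers each cell's mean within 3 SE", {
  # closed-form mean of a normal truncated to the instrument range (with the
  # sampler's continuity correction) -- the exact oracle for every cell
  trunc_mean <- function(mu, s) {
    a <- (12 - 0.5 - mu) / s; b <- (60 + 0.5 - mu) / s
    mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  params <- interpretation_cell_params()
  for (r in seq_len(nrow(params))) {
    cell <- params[r, ]
    # truncation barely distorts any configured cell mean
    expect_lt(abs(trunc_mean(cell$hostile_mean, cell$hostile_sd) - cell$hostile_mean), 0.25)
    draws <- sample_interpretation_scores(cell$trait_group, cell$condition,
                                          10000, seed = 100 + r)
    expect_lt(abs(mean(draws$hostile_score) - trunc_mean(cell$hostile_mean, cell$hostile_sd)),
              3 * cell$hostile_sd / 100)
    expect_lt(abs(mean(draws$non_hostile_score) -
                    trunc_mean(cell$non_hostile_mean, cell$non_hostile_sd)),
              3 * cell$non_hostile_sd / 100)
    expect_true(all(draws$hostile_score >= 12 & draws$hostile_score <= 60))
  }
  # the narrow dominant-exclusion cell recovers its configured mean directly
  d <- sample_interpretation_scores("dominant", "exclusion", 10000, seed = 17)
  expect_lt(abs(mean(d$hostile_score) - 45.65), 3 * 4.06 / 100)
})

test_that("interpretation sampler handles degenerate and missing cells", {
  p0 <- interpretation_cell_params()
  p0$hostile_sd <- 0
  d <- sample_interpretation_scores("dominant", "exclusion", 50, params = p0, seed = 1)
  expect_true(all(d$hostile_score == round(45.65)))
  expect_error(sample_interpretation_scores("dominant", "mars", 10),
               class = "hibpn_config_error")
})

test_that("generated cohorts have the configured design structure", {
  coh <- generate_cohort(cohort_config(n_participants = 258, seed = 5))
  expect_equal(as.vector(table(coh$trait_group)[c("dominant", "implicit", "neutral")]),
               c(70, 70, 118)) # round(0.27 * 258) = 70 each, remainder neutral
  expect_equal(nrow(coh), 258)
  # record invariants
  expect_true(all(coh$npi16_score >= 0 & coh$npi16_score <= 16))
  expect_true(all(coh$hsns_score >= 10 & coh$hsns_score <= 50))
  expect_true(all(coh$basic_needs_score >= 20 & coh$basic_needs_score <= 100))
  expect_true(all(coh$hostile_score >= 12 & coh$hostile_score <= 60))
  expect_true(all(coh$estimated_catch_pct >= 0 & coh$estimated_catch_pct <= 100))
  expect_identical(coh$hostile_bin, bin_hostile(coh$hostile_score))
  # planted direction: implicit scorers out-interpret neutral controls
  expect_gt(mean(coh$hostile_score[coh$trait_group == "implicit"]),
            mean(coh$hostile_score[coh$trait_group == "neutral"]))
})

test_that("cohort generation is byte-deterministic given the seed", {
  cc <- cohort_config(n_participants = 120, seed = 99)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("null basic-needs effect leaves the condition means equal", {
  coh <- generate_cohort(cohort_config(n_participants = 4000, seed = 21,
                                       basic_needs_effect = 0))
  m <- tapply(coh$basic_needs_score, coh$condition, mean)
  se <- sd(coh$basic_needs_score) * sqrt(2 / 2000)
  expect_lt(abs(m[["exclusion"]] - m[["acceptance"]]), 3 * se)
})

test_that("noise-free catch estimates sit at the true pass rates", {
  coh <- generate_cohort(cohort_config(n_participants = 3000, seed = 31,
                                       catch_noise_sd = 0))
  expect_equal(mean(coh$estimated_catch_pct[coh$condition == "exclusion"]), 6.67,
               tolerance = 1e-8)
  expect_equal(mean(coh$estimated_catch_pct[coh$condition == "acceptance"]),
               100 / 3, tolerance = 0.02)
})

test_that("intervention cohorts have implicit-only arms of the configured size", {
  coh <- generate_intervention_cohort(cohort_config(seed = 2))
  expect_equal(nrow(coh), 36)
  expect_equal(sum(coh$intervention == "self_affirmation"), 18)
  expect_equal(sum(coh$intervention == "control"), 18)
  expect_true(all(coh$trait_group == "implicit"))
  expect_error(generate_intervention_cohort(
    cohort_config(arm_sizes = c(self_affirmation = 0L, control = 18L))),
    class = "hibpn_config_error")
})

test_that("the planted affirmation effect is recovered at scale", {
  big <- cohort_config(arm_sizes = c(self_affirmation = 10000L, control = 10000L),
                       affirmation_effect = 5, seed = 4)
  coh <- generate_intervention_cohort(big)
  d <- mean(coh$hostile_score[coh$intervention == "control"]) -
    mean(coh$hostile_score[coh$intervention == "self_affirmation"])
  expect_equal(d, 5, tolerance = 0.2)

  none <- cohort_config(arm_sizes = c(self_affirmation = 10000L, control = 10000L),
                        affirmation_effect = 0, seed = 4)
  coh0 <- generate_intervention_cohort(none)
  d0 <- mean(coh0$hostile_score[coh0$intervention == "control"]) -
    mean(coh0$hostile_score[coh0$intervention == "self_affirmation"])
  expect_lt(abs(d0), 0.25)
})
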