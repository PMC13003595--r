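# Shared fixtures, all generated in code.

# linearly separable two-feature binary problem
toy_separable <- function(n = 20, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    x1 <- rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5)
    x2 <- rnorm(n, mean = ifelse(y == 1, 2, -2), sd = 0.5)
    list(X = cbind(a = x1, b = x2), y = y)
  })
}

# cohort whose condition labels are independent of every feature
null_cohort <- function(n = 500, seed = 1) {
  coh <- generate_cohort(cohort_config(n_participants = n, seed = seed))
  withr::with_seed(seed + 1000, {
    coh$condition <- sample(coh$condition)
  })
  coh
}

# brute-force AUC: concordant-pair counting with ties credited 1/2
auc_pair_count <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# config whose social-exclusion covariates are uninformative: basic needs
# unaffected by condition, catch estimates swamped by noise
flat_covariate_config <- function(n, seed, table1 = interpretation_cell_params()) {
  cohort_config(n_participants = n, seed = seed, basic_needs_effect = 0,
                catch_noise_sd = 60, table1_params = table1)
}

# cell parameters planting a hostile->exclusion association that holds in
# every trait group (the mechanism the intervention is meant to act through)
global_assoc_table1 <- function(shift = 6) {
  t1 <- interpretation_cell_params()
  base <- c(neutral = 32, dominant = 38, implicit = 40)
  t1$hostile_mean <- base[t1$trait_group] + shift * (t1$condition == "exclusion")
  t1$hostile_sd <- 5
  t1
}
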