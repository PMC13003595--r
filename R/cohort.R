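# Synthetic cohort generation.
#
# No participant-level data from the Cyberball experiments is publicly
# deposited, so every downstream stage (training, baselines, ablation,
# importance, intervention contrast) is exercised on synthetic cohorts that
# reproduce the reported statistical structure: trait-group proportions
# (27/27/46%), per-cell hostile / non-hostile interpretation score
# distributions, Cyberball pass schedules (2/30 catches under exclusion,
# per-pass probability 1/3 under acceptance), a basic-needs deficit under
# exclusion, and the 18+18 self-affirmation arms of the intervention study.

#' Default per-cell interpretation-score distribution parameters
#'
#' Means and standard deviations of the hostile and non-hostile
#' interpretation scores for each trait group under each Cyberball condition,
#' as observed in the source experiments.
#'
#' @return Tibble with columns `trait_group`, `condition`, `hostile_mean`,
#'   `hostile_sd`, `non_hostile_mean`, `non_hostile_sd`.
#' @export
interpretation_cell_params <- function() {
  tibble::tribble(
    ~trait_group, ~condition,   ~hostile_mean, ~hostile_sd, ~non_hostile_mean, ~non_hostile_sd,
    "neutral",    "exclusion",  30.09,         6.65,        42.50,             7.40,
    "dominant",   "exclusion",  45.65,         4.06,        32.73,             7.00,
    "implicit",   "exclusion",  43.91,         4.95,        34.82,             4.68,
    "neutral",    "acceptance", 30.56,         6.53,        42.53,             7.16,
    "dominant",   "acceptance", 36.68,         7.70,        36.39,             8.07,
    "implicit",   "acceptance", 43.64,         4.55,        34.69,             6.19
  )
}

# Group-conditional narcissism score distributions: the implicit group sits in
# the upper HSNS range, the dominant group in the upper NPI range, so that
# top-27% selection on the respective scale is internally consistent.
narcissism_group_params <- function() {
  tibble::tribble(
    ~trait_group, ~npi_mean, ~npi_sd, ~hsns_mean, ~hsns_sd,
    "dominant",   13,        1.5,     27,         5,
    "implicit",   6,         2.5,     42,         3,
    "neutral",    6,         2.5,     27,         5
  )
}

#' Cohort generator configuration
#'
#' All knobs of the synthetic cohort generator with defaults matching the
#' study conditions being emulated.
#'
#' @param n_participants Cohort size (default 258, the valid-questionnaire
#'   count of the screening wave).
#' @param condition_ratio Fraction assigned to social exclusion within each
#'   trait group (default 0.5; the real split is unreported).
#' @param table1_params Per-cell interpretation distribution parameters; see
#'   [interpretation_cell_params()].
#' @param group_proportions Named numeric of trait-group proportions; must sum
#'   to 1. Defaults to dominant 0.27, implicit 0.27, neutral 0.46.
#' @param basic_needs_effect Mean basic-needs reduction under exclusion
#'   (default 10 scale points).
#' @param basic_needs_base,basic_needs_sd Baseline basic-needs mean/SD under
#'   acceptance (defaults 70 and 8 on the 20-100 scale).
#' @param catch_noise_sd SD of the zero-mean noise added to the true Cyberball
#'   catch rate to give the participant's estimated catch percentage
#'   (default 8 percentage points).
#' @param prop_male Probability a participant is male (default 2/3).
#' @param age_range Inclusive integer age range (default 19-22).
#' @param arm_sizes Integer vector of intervention arm sizes
#'   (self-affirmation, control); used by [generate_intervention_cohort()].
#' @param affirmation_effect Mean hostile-score reduction in the
#'   self-affirmation arm (default 5 scale points).
#' @param seed Integer seed; every draw the generator makes is a
#'   deterministic function of it.
#' @return A list of class `hibpn_cohort_config`.
#' @export
cohort_config <- function(n_participants = 258,
                          condition_ratio = 0.5,
                          table1_params = interpretation_cell_params(),
                          group_proportions = c(dominant = 0.27, implicit = 0.27, neutral = 0.46),
                          basic_needs_effect = 10,
                          basic_needs_base = 70,
                          basic_needs_sd = 8,
                          catch_noise_sd = 8,
                          prop_male = 2 / 3,
                          age_range = c(19L, 22L),
                          arm_sizes = c(self_affirmation = 18L, control = 18L),
                          affirmation_effect = 5,
                          seed = 1L) {
  if (condition_ratio < 0 || condition_ratio > 1)
    stop_config("condition_ratio must lie in [0, 1]")
  if (abs(sum(group_proportions) - 1) > 1e-8)
    stop_config("group_proportions must sum to 1")
  if (any(table1_params$hostile_sd < 0) || any(table1_params$non_hostile_sd < 0))
    stop_config("distribution SDs must be non-negative")
  if (any(arm_sizes < 1)) stop_config("intervention arm sizes must be positive")
  structure(
    list(n_participants = n_participants, condition_ratio = condition_ratio,
         table1_params = table1_params, group_proportions = group_proportions,
         basic_needs_effect = basic_needs_effect, basic_needs_base = basic_needs_base,
         basic_needs_sd = basic_needs_sd, catch_noise_sd = catch_noise_sd,
         prop_male = prop_male, age_range = as.integer(age_range),
         arm_sizes = arm_sizes, affirmation_effect = affirmation_effect,
         seed = as.integer(seed)),
    class = "hibpn_cohort_config"
  )
}

#' Simulate one Cyberball game
#'
#' Thirty passes are made. Under exclusion the participant receives the ball
#' exactly twice, both catches falling in the first 15 passes (the avatars
#' pass exclusively between themselves in the second half), a 6.67% catch
#' rate. Under acceptance every pass reaches the participant independently
#' with probability 1/3 (33.33% expected catch rate).
#'
#' @param condition `"exclusion"` or `"acceptance"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so a seeded caller stays deterministic).
#' @return List with `n_passes` (30), `catches`, `catch_rate_pct` (rounded to
#'   2 decimals) and `schedule`, a 0/1 vector marking participant receipts.
#' @examples
#' simulate_cyberball("exclusion", seed = 1)$catch_rate_pct # 6.67
#' @export
simulate_cyberball <- function(condition, seed = NULL) {
  condition <- match.arg(condition, c("exclusion", "acceptance"))
  draw <- function() {
    schedule <- integer(30)
    if (condition == "exclusion") {
      schedule[sample.int(15, 2)] <- 1L
    } else {
      schedule <- rbinom(30, 1, 1 / 3)
    }
    schedule
  }
  schedule <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  catches <- sum(schedule)
  list(n_passes = 30L, catches = catches,
       catch_rate_pct = round(100 * catches / 30, 2), schedule = schedule)
}

# Inverse-CDF sampling from a normal truncated to [lo, hi], rounded to
# integers (summed-Likert semantics); `mean` may be a vector of length n.
# Degenerate sd = 0 returns the rounded mean clamped into range.
rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  if (all(sd == 0)) return(rep_len(pmin(pmax(as.integer(round(mean)), lo), hi), n))
  u <- runif(n)
  p_lo <- stats::pnorm(lo - 0.5, mean, sd)
  p_hi <- stats::pnorm(hi + 0.5, mean, sd)
  x <- stats::qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  pmin(pmax(as.integer(round(x)), lo), hi)
}

#' Sample interpretation score pairs for one design cell
#'
#' Draws hostile / non-hostile interpretation score pairs from the normal
#' distribution of the given trait-group-by-condition cell, truncated to the
#' instrument range 12-60 and rounded to integers.
#'
#' @param trait_group `"dominant"`, `"implicit"` or `"neutral"`.
#' @param condition `"exclusion"` or `"acceptance"`.
#' @param n Number of pairs.
#' @param params Cell parameter table; see [interpretation_cell_params()].
#' @param seed Optional integer seed (`NULL` = current RNG stream).
#' @return Tibble with integer columns `hostile_score`, `non_hostile_score`.
#' @export
sample_interpretation_scores <- function(trait_group, condition, n,
                                         params = interpretation_cell_params(),
                                         seed = NULL) {
  cell <- params[params$trait_group == trait_group & params$condition == condition, ]
  if (nrow(cell) != 1)
    stop_config("no parameter cell for trait_group=%s, condition=%s", trait_group, condition)
  if (n < 1) stop_invalid("n must be at least 1")
  draw <- function() {
    tibble::tibble(
      hostile_score = rtruncnorm_int(n, cell$hostile_mean, cell$hostile_sd,
                                     HOSTILE_RANGE[1], HOSTILE_RANGE[2]),
      non_hostile_score = rtruncnorm_int(n, cell$non_hostile_mean, cell$non_hostile_sd,
                                         HOSTILE_RANGE[1], HOSTILE_RANGE[2])
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# shared record assembly for both cohort flavours; runs inside a seeded stream
build_records <- function(ids, trait_group, condition, intervention, config,
                          hostile_shift = numeric(length(ids))) {
  n <- length(ids)
  gender <- ifelse(runif(n) < config$prop_male, "male", "female")
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)

  npar <- narcissism_group_params()
  npi <- integer(n); hsns <- integer(n)
  for (g in unique(trait_group)) {
    i <- which(trait_group == g)
    p <- npar[npar$trait_group == g, ]
    npi[i] <- rtruncnorm_int(length(i), p$npi_mean, p$npi_sd, 0L, 16L)
    hsns[i] <- rtruncnorm_int(length(i), p$hsns_mean, p$hsns_sd, 10L, 50L)
  }

  catches <- ifelse(condition == "exclusion", 2L, rbinom(n, 30, 1 / 3))
  true_rate <- 100 * catches / 30
  est_catch <- pmin(pmax(true_rate + rnorm(n, 0, config$catch_noise_sd), 0), 100)

  bn_mean <- config$basic_needs_base - config$basic_needs_effect * (condition == "exclusion")
  basic_needs <- pmin(pmax(as.integer(round(rnorm(n, bn_mean, config$basic_needs_sd))), 20L), 100L)

  hostile <- integer(n); non_hostile <- integer(n)
  for (g in unique(trait_group)) {
    for (cond in unique(condition)) {
      i <- which(trait_group == g & condition == cond)
      if (!length(i)) next
      cell <- config$table1_params[config$table1_params$trait_group == g &
                                     config$table1_params$condition == cond, ]
      if (nrow(cell) != 1) stop_config("no parameter cell for %s x %s", g, cond)
      hostile[i] <- rtruncnorm_int(length(i), cell$hostile_mean - hostile_shift[i],
                                   cell$hostile_sd, HOSTILE_RANGE[1], HOSTILE_RANGE[2])
      non_hostile[i] <- rtruncnorm_int(length(i), cell$non_hostile_mean, cell$non_hostile_sd,
                                       HOSTILE_RANGE[1], HOSTILE_RANGE[2])
    }
  }

  tibble::tibble(
    id = ids,
    gender = gender,
    age = age,
    trait_group = factor(trait_group, levels = c("dominant", "implicit", "neutral")),
    condition = factor(condition, levels = c("acceptance", "exclusion")),
    npi16_score = npi,
    hsns_score = hsns,
    basic_needs_score = basic_needs,
    estimated_catch_pct = round(est_catch, 2),
    hostile_score = hostile,
    non_hostile_score = non_hostile,
    hostile_bin = bin_hostile(hostile),
    intervention = factor(intervention,
                          levels = c("none", "self_affirmation", "control"))
  )
}

#' Generate a synthetic Cyberball cohort
#'
#' Builds one participant record per row: trait groups in the configured
#' 27/27/46 proportions with group-consistent narcissism scores, Cyberball
#' conditions randomized within trait group, basic-needs scores lowered under
#' exclusion, estimated catch percentages equal to the true game catch rate
#' plus noise, and interpretation scores drawn from the per-cell
#' distributions. Fully deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Tibble of participant records.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 100, seed = 7))
#' table(cohort$trait_group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hibpn_cohort_config"))
  n <- config$n_participants
  if (n < 4) stop_config("cohort too small")
  withr::with_seed(config$seed, {
    n_dom <- round(config$group_proportions[["dominant"]] * n)
    n_imp <- round(config$group_proportions[["implicit"]] * n)
    n_neu <- n - n_dom - n_imp
    trait_group <- c(rep("dominant", n_dom), rep("implicit", n_imp), rep("neutral", n_neu))

    condition <- character(n)
    for (g in c("dominant", "implicit", "neutral")) {
      i <- which(trait_group == g)
      n_exc <- round(config$condition_ratio * length(i))
      cond <- c(rep("exclusion", n_exc), rep("acceptance", length(i) - n_exc))
      condition[i] <- sample(cond)
    }
    build_records(seq_len(n), trait_group, condition, "none", config)
  })
}

#' Generate a synthetic self-affirmation intervention cohort
#'
#' All participants carry the implicit-narcissism trait profile (the
#' intervention study recruited only the top-27% HSNS scorers). Arms are the
#' configured sizes (default 18 + 18); the self-affirmation arm's hostile
#' interpretation score mean is reduced by `config$affirmation_effect`.
#' Cyberball conditions are randomized as in [generate_cohort()].
#'
#' @param config A [cohort_config()]; `arm_sizes` and `affirmation_effect`
#'   control the arms.
#' @return Tibble of participant records with `intervention` set to
#'   `self_affirmation` or `control`.
#' @export
generate_intervention_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hibpn_cohort_config"))
  sizes <- config$arm_sizes
  n <- sum(sizes)
  withr::with_seed(config$seed + 1L, {
    arm <- sample(c(rep("self_affirmation", sizes[["self_affirmation"]]),
                    rep("control", sizes[["control"]])))
    n_exc <- round(config$condition_ratio * n)
    condition <- sample(c(rep("exclusion", n_exc), rep("acceptance", n - n_exc)))
    shift <- ifelse(arm == "self_affirmation", config$affirmation_effect, 0)
    build_records(seq_len(n), rep("implicit", n), condition, arm, config,
                  hostile_shift = shift)
  })
}
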