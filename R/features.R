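# Feature encoding.
#
# Participant records are mapped to the three per-module input blocks. The
# condition indicator is the forward chain's target and is therefore excluded
# from its inputs (anti-leakage); it is a legitimate input to the reverse
# chain. Continuous columns are z-standardized with training-set statistics;
# binary indicators are left as 0/1.

# column -> dimension group, used by ablation and grouped importance
dimension_group_map <- function(cols) {
  groups <- c(
    gender_male = "social_exclusion", age = "social_exclusion",
    basic_needs_score = "social_exclusion", estimated_catch_pct = "social_exclusion",
    condition_exclusion = "social_exclusion",
    group_dominant = "narcissism", group_implicit = "narcissism",
    npi16_score = "narcissism", hsns_score = "narcissism",
    hostile_score = "hostile_interpretation", non_hostile_score = "hostile_interpretation"
  )
  unmapped <- setdiff(cols, names(groups))
  if (length(unmapped))
    stop_config("no dimension group for column(s): %s", paste(unmapped, collapse = ", "))
  groups[cols]
}

CONTINUOUS_COLS <- c("age", "basic_needs_score", "estimated_catch_pct",
                     "npi16_score", "hsns_score", "hostile_score", "non_hostile_score")

#' Encode a cohort into per-module model inputs
#'
#' Builds the three input blocks of the network for one chain and the
#' column-to-dimension-group map used by ablation and grouped feature
#' importance.
#'
#' The forward chain predicts the Cyberball condition, so the condition
#' indicator never appears among its inputs; the reverse chain predicts the
#' hostile-interpretation bin, so the interpretation scores never appear
#' among its inputs while the condition indicator does.
#'
#' @param cohort Tibble of participant records (see [generate_cohort()]).
#' @param chain `"forward"` (predict exclusion) or `"reverse"` (predict the
#'   high-hostility bin).
#' @param drop_groups Dimension groups to remove (module ablation):
#'   any of `"narcissism"`, `"hostile_interpretation"`.
#' @return List of class `hibpn_features`: matrices `he`, `n`, `h`, the
#'   binary target `y`, `group_map`, and `chain`.
#' @export
encode_features <- function(cohort, chain = c("forward", "reverse"),
                            drop_groups = character()) {
  chain <- match.arg(chain)
  bad <- setdiff(drop_groups, c("narcissism", "hostile_interpretation"))
  if (length(bad)) stop_config("unknown dimension group(s): %s", paste(bad, collapse = ", "))

  he <- cbind(
    gender_male = as.numeric(cohort$gender == "male"),
    age = cohort$age,
    basic_needs_score = cohort$basic_needs_score,
    estimated_catch_pct = cohort$estimated_catch_pct
  )
  if (!"narcissism" %in% drop_groups) {
    he <- cbind(he,
                group_dominant = as.numeric(cohort$trait_group == "dominant"),
                group_implicit = as.numeric(cohort$trait_group == "implicit"))
  }
  if (chain == "reverse") {
    he <- cbind(he, condition_exclusion = as.numeric(cohort$condition == "exclusion"))
  }

  n_block <- if ("narcissism" %in% drop_groups) {
    matrix(numeric(0), nrow(cohort), 0)
  } else {
    cbind(npi16_score = cohort$npi16_score, hsns_score = cohort$hsns_score)
  }

  h_block <- if (chain == "reverse" || "hostile_interpretation" %in% drop_groups) {
    matrix(numeric(0), nrow(cohort), 0)
  } else {
    cbind(hostile_score = cohort$hostile_score,
          non_hostile_score = cohort$non_hostile_score)
  }

  y <- if (chain == "forward") {
    as.numeric(cohort$condition == "exclusion")
  } else {
    as.numeric(cohort$hostile_bin == "high")
  }

  cols <- c(colnames(he), colnames(n_block), colnames(h_block))
  structure(list(he = he, n = n_block, h = h_block, y = y,
                 group_map = dimension_group_map(cols), chain = chain,
                 drop_groups = drop_groups),
            class = "hibpn_features")
}

# standardization statistics from (training) feature matrices
fit_scaler <- function(feats) {
  stats_for <- function(m) {
    sel <- intersect(colnames(m), CONTINUOUS_COLS)
    list(center = vapply(sel, function(cn) mean(m[, cn]), numeric(1)),
         scale = vapply(sel, function(cn) {
           s <- sd(m[, cn]); if (!is.finite(s) || s == 0) 1 else s
         }, numeric(1)))
  }
  list(he = stats_for(feats$he), n = stats_for(feats$n), h = stats_for(feats$h))
}

apply_scaler <- function(feats, scaler) {
  apply_one <- function(m, st) {
    for (cn in names(st$center))
      m[, cn] <- (m[, cn] - st$center[[cn]]) / st$scale[[cn]]
    m
  }
  feats$he <- apply_one(feats$he, scaler$he)
  feats$n <- apply_one(feats$n, scaler$n)
  feats$h <- apply_one(feats$h, scaler$h)
  feats
}

# flat design matrix (for baselines and the importance surrogate)
flatten_features <- function(feats) {
  cbind(feats$he, feats$n, feats$h)
}
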