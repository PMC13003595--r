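# Experiment orchestration: model comparison, module ablation, grouped
# feature importance, and the self-affirmation intervention contrast.

#' Model comparison on both chains (the headline experiment)
#'
#' Splits the cohort once per chain (1:9 protocol, stratified on that chain's
#' target), trains the network, fits every baseline on the identical split,
#' and evaluates all models through the shared metric code path.
#'
#' @param cohort Tibble of participant records.
#' @param config A [train_config()].
#' @param dims A [hibpn_dims()].
#' @param specs Baseline specifications; see [baseline_specs()].
#' @param chains Chains to evaluate (default both).
#' @return List of class `hibpn_comparison`: `metrics` (tibble of model x
#'   chain rows), `fits` (per-chain network fits), `splits`, and a `manifest`
#'   recording seeds and configuration.
#' @export
run_experiment1 <- function(cohort, config = train_config(), dims = hibpn_dims(),
                            specs = baseline_specs(seed = config$seed),
                            chains = c("forward", "reverse")) {
  chains <- match.arg(chains, several.ok = TRUE)
  targets <- c(forward = "condition", reverse = "hostile_bin")
  fits <- list(); splits <- list()
  metrics <- purrr::map_dfr(chains, function(ch) {
    sp <- split_1_9(cohort, targets[[ch]], config)
    splits[[ch]] <<- sp
    fit <- hibpn_fit(sp$train, chains = ch, dims = dims, config = config)
    fits[[ch]] <<- fit
    te <- encode_features(sp$test, ch)
    hib_row <- evaluate_scores(te$y, predict(fit, sp$test, chain = ch)) |>
      dplyr::mutate(note = NA_character_)
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(model = "hibpn", chain = ch), hib_row),
      evaluate_baselines(sp$train, sp$test, ch, specs)
    )
  })
  structure(
    list(metrics = structure(metrics, class = c("hibpn_metrics", class(metrics))),
         fits = fits, splits = splits,
         manifest = list(seed = config$seed, config = unclass(config),
                         dims = unclass(dims), n = nrow(cohort),
                         baselines = purrr::map_chr(specs, "name"))),
    class = "hibpn_comparison")
}

#' Module ablation of the forward chain
#'
#' Retrains the network three times on the identical split: with all
#' features, without the narcissism dimension group (narcissism encoder and
#' trait-group indicators removed), and without the hostile-interpretation
#' group (interpretation encoder removed). Feature-group removal plus
#' retraining, not weight zeroing. A companion table reports relative drops
#' against the full model in both denominator conventions.
#'
#' @param cohort Tibble of participant records.
#' @param config A [train_config()].
#' @param dims A [hibpn_dims()].
#' @param chain Chain to ablate (default `"forward"`).
#' @return List of class `hibpn_ablation`: `metrics` (one row per variant)
#'   and `gaps` (relative drops vs the full model).
#' @export
run_ablation <- function(cohort, config = train_config(), dims = hibpn_dims(),
                         chain = "forward") {
  target <- if (chain == "forward") "condition" else "hostile_bin"
  sp <- split_1_9(cohort, target, config)
  variants <- list(all_features = character(),
                   without_narcissism = "narcissism",
                   without_hostile_interpretation = "hostile_interpretation")
  if (chain == "reverse") variants$without_hostile_interpretation <- NULL
  metrics <- purrr::imap_dfr(variants, function(drop, nm) {
    fit <- hibpn_fit(sp$train, chains = chain, dims = dims, config = config,
                     drop_groups = drop)
    te <- encode_features(sp$test, chain, drop_groups = drop)
    row <- evaluate_scores(te$y, predict(fit, sp$test, chain = chain))
    dplyr::bind_cols(tibble::tibble(variant = nm, chain = chain), row)
  })
  full <- metrics[metrics$variant == "all_features", ]
  gaps <- metrics |>
    dplyr::filter(.data$variant != "all_features") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      acc_drop_ref = relative_gap(full$acc, .data$acc, "reference"),
      acc_drop_val = relative_gap(full$acc, .data$acc, "value"),
      auc_drop_ref = relative_gap(full$auc, .data$auc, "reference"),
      f1_drop_ref = relative_gap(full$f1, .data$f1, "reference")
    ) |>
    dplyr::ungroup() |>
    dplyr::select("variant", dplyr::ends_with("_ref"), dplyr::ends_with("_val"))
  structure(list(metrics = metrics, gaps = gaps, split = sp),
            class = "hibpn_ablation")
}

#' Grouped feature importance via a random-forest surrogate
#'
#' Fits a random forest on exactly the inputs the given chain sees, sums the
#' per-feature importances within each of the three core dimension groups
#' (social exclusion covariates, narcissism, hostile interpretation bias) and
#' normalizes to percentages summing to 100. An empty group is reported as 0
#' with a warning.
#'
#' @param cohort Tibble of participant records.
#' @param chain `"forward"` or `"reverse"`.
#' @param ntree Number of surrogate trees (default 500).
#' @param seed Seed for the forest.
#' @return Tibble of class `hibpn_importance`: `chain`, `dimension`,
#'   `weight_pct`.
#' @export
dimension_importance <- function(cohort, chain = c("forward", "reverse"),
                                 ntree = 500, seed = 1L) {
  chain <- match.arg(chain)
  feats <- encode_features(cohort, chain)
  X <- flatten_features(apply_scaler(feats, fit_scaler(feats)))
  rf <- withr::with_seed(as.integer(seed), {
    randomForest::randomForest(X, factor(feats$y, levels = c(0, 1)), ntree = ntree,
                               importance = FALSE)
  })
  imp <- randomForest::importance(rf)[, 1]
  groups <- c("social_exclusion", "hostile_interpretation", "narcissism")
  raw <- vapply(groups, function(g) {
    cols <- names(feats$group_map)[feats$group_map == g]
    if (!length(cols)) {
      warn(sprintf("dimension group '%s' is empty for the %s chain", g, chain))
      return(0)
    }
    sum(imp[cols])
  }, numeric(1))
  weight <- unname(100 * raw / sum(raw))
  structure(tibble::tibble(chain = chain, dimension = groups, weight_pct = weight),
            class = c("hibpn_importance", "tbl_df", "tbl", "data.frame"))
}

#' Intervention contrast: predicted acceptance rate per arm
#'
#' Classifies every participant of the intervention cohort with the trained
#' forward chain; the positive response rate of an arm is the fraction
#' predicted as socially accepted (exclusion probability below 0.5).
#'
#' @param cohort_exp2 Intervention cohort from
#'   [generate_intervention_cohort()], with both arms present.
#' @param forward_fit A forward-chain [hibpn_fit()].
#' @return Tibble of class `hibpn_intervention`: one row per arm with
#'   `positive_response_rate` and `n`; the attribute `difference_pct` is the
#'   self-affirmation minus control rate in percentage points.
#' @export
run_experiment2 <- function(cohort_exp2, forward_fit) {
  arms <- c("self_affirmation", "control")
  if (!all(arms %in% cohort_exp2$intervention))
    stop_invalid("intervention cohort must contain both arms")
  pred <- predict(forward_fit, cohort_exp2, chain = "forward", type = "class")
  report <- cohort_exp2 |>
    dplyr::mutate(accepted = 1L - pred) |>
    dplyr::filter(.data$intervention %in% arms) |>
    dplyr::group_by(arm = factor(.data$intervention, levels = arms)) |>
    dplyr::summarise(positive_response_rate = mean(.data$accepted), n = dplyr::n())
  diff_pct <- 100 * (report$positive_response_rate[report$arm == "self_affirmation"] -
                       report$positive_response_rate[report$arm == "control"])
  structure(report, class = c("hibpn_intervention", class(report)),
            difference_pct = diff_pct)
}

#' Difference in arm response rates, in percentage points
#'
#' @param rate_affirmation,rate_control Positive response rates (fractions).
#' @return `100 * (rate_affirmation - rate_control)`.
#' @examples
#' intervention_difference(0.1667, 0.1111) # 5.56
#' @export
intervention_difference <- function(rate_affirmation, rate_control) {
  if (any(c(rate_affirmation, rate_control) < 0 | c(rate_affirmation, rate_control) > 1))
    stop_invalid("rates must lie in [0, 1]")
  100 * (rate_affirmation - rate_control)
}
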