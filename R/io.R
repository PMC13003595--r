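# Cohort CSV round-trip and deterministic report serialization.

COHORT_COLUMNS <- c("id", "gender", "age", "trait_group", "condition",
                    "npi16_score", "hsns_score", "basic_needs_score",
                    "estimated_catch_pct", "hostile_score", "non_hostile_score",
                    "hostile_bin", "intervention")

validate_cohort <- function(cohort) {
  missing <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing))
    stop_invalid("missing cohort column(s): %s", paste(missing, collapse = ", "))
  if (nrow(cohort) == 0) stop_invalid("empty cohort")
  check_range <- function(col, lo, hi) {
    bad <- which(cohort[[col]] < lo | cohort[[col]] > hi | is.na(cohort[[col]]))
    if (length(bad))
      stop_invalid("invalid value in column '%s', row %d: %s",
                   col, bad[1], format(cohort[[col]][bad[1]]))
  }
  check_range("npi16_score", 0, 16)
  check_range("hsns_score", 10, 50)
  check_range("basic_needs_score", 20, 100)
  check_range("estimated_catch_pct", 0, 100)
  check_range("hostile_score", HOSTILE_RANGE[1], HOSTILE_RANGE[2])
  check_range("non_hostile_score", HOSTILE_RANGE[1], HOSTILE_RANGE[2])
  check_range("age", 10, 120)
  if (!all(as.character(cohort$hostile_bin) ==
             as.character(bin_hostile(cohort$hostile_score))))
    stop_invalid("hostile_bin inconsistent with hostile_score")
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads one participant record per row, validates every record invariant
#' (score ranges, bin consistency) and preserves row order. Errors name the
#' offending row and column.
#'
#' @param path CSV file path.
#' @return Tibble of participant records.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop_invalid("empty cohort")
  validate_cohort(raw)
  raw |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("id", "age", "npi16_score", "hsns_score",
                                    "basic_needs_score", "hostile_score",
                                    "non_hostile_score")), as.integer),
      trait_group = factor(.data$trait_group, levels = c("dominant", "implicit", "neutral")),
      condition = factor(.data$condition, levels = c("acceptance", "exclusion")),
      hostile_bin = factor(.data$hostile_bin, levels = c("low", "high"), ordered = TRUE),
      intervention = factor(.data$intervention,
                            levels = c("none", "self_affirmation", "control"))
    )
}

#' Write a cohort CSV
#'
#' @param cohort Tibble of participant records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Write a metrics/importance/intervention report
#'
#' Deterministic serialization: metric columns are rendered to 4 decimals,
#' percentage columns to 2; JSON keys are written in column order.
#'
#' @param report Data frame (e.g. the `metrics` tibble of
#'   [run_experiment1()], a [dimension_importance()] table, or a
#'   [run_experiment2()] report).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(report)
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  metric_cols <- intersect(names(out),
                           c("acc", "f1", "auc", "positive_response_rate"))
  pct_cols <- intersect(names(out), c("weight_pct", grep("_drop_|_pct$", names(out), value = TRUE)))
  for (cn in metric_cols) out[[cn]] <- sprintf("%.4f", out[[cn]])
  for (cn in setdiff(pct_cols, metric_cols)) out[[cn]] <- sprintf("%.2f", out[[cn]])
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' Serialize a fitted network to JSON
#'
#' Writes dims, training configuration and every layer's weights/biases at
#' full precision so checkpoints round-trip exactly.
#'
#' @param fit A [hibpn_fit()] object.
#' @param path Output path (.json).
#' @return The path, invisibly.
#' @export
write_hibpn_json <- function(fit, path) {
  stopifnot(inherits(fit, "hibpn_fit"))
  ser <- list(
    dims = unclass(fit$dims), config = unclass(fit$config),
    drop_groups = fit$drop_groups, n_train = fit$n_train,
    chains = purrr::map(fit$chains, function(st) {
      layers <- st$params[vapply(st$params, function(e) is.list(e) && !is.null(e$W),
                                 logical(1))]
      list(meta = st$params[c("d_he", "d_n", "d_h")],
           layers = purrr::map(layers, function(l) list(W = l$W, b = l$b)),
           # named lists serialize as JSON objects, keeping column names
           scaler = purrr::map(st$scaler, function(s)
             list(center = as.list(s$center), scale = as.list(s$scale))),
           loss = st$loss)
    })
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Restore a fitted network from JSON
#'
#' @param path Path written by [write_hibpn_json()].
#' @return A `hibpn_fit` object equivalent to the serialized one.
#' @export
read_hibpn_json <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- structure(as.list(ser$dims), class = "hibpn_dims")
  dims[names(dims) != "activation"] <- lapply(dims[names(dims) != "activation"],
                                              as.integer)
  cfg <- structure(as.list(ser$config), class = "hibpn_train_config")
  chains <- purrr::map(ser$chains, function(st) {
    params <- purrr::map(st$layers, function(l) {
      W <- l$W
      if (!is.matrix(W)) W <- matrix(unlist(W), nrow = length(W), byrow = TRUE)
      list(W = W, b = as.numeric(l$b))
    })
    params$dims <- dims
    params$d_he <- as.integer(st$meta$d_he)
    params$d_n <- as.integer(st$meta$d_n)
    params$d_h <- as.integer(st$meta$d_h)
    scaler <- purrr::map(st$scaler, function(s)
      list(center = unlist(s$center) %||% numeric(0) * 1,
           scale = unlist(s$scale) %||% numeric(0) * 1))
    list(params = structure(params, class = "hibpn_params"),
         scaler = scaler, loss = as.numeric(st$loss))
  })
  structure(list(dims = dims, config = cfg,
                 drop_groups = as.character(ser$drop_groups %||% character(0)),
                 n_train = as.integer(ser$n_train), chains = chains),
            class = "hibpn_fit")
}
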