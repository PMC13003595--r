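# Splitting and optimization.
#
# The validation protocol deliberately trains on the small side of the data:
# 10% of records are used for training and 90% held out, probing
# generalization from scarce data. Optimization is full-batch gradient
# descent on the binary cross-entropy (classification heads) or mean squared
# error (regression mode of the reverse head); with a fixed seed every run is
# bit-reproducible.

#' Training configuration
#'
#' @param split_ratio Fraction of records used for training (default 0.10,
#'   the 1:9 train:test protocol).
#' @param stratify Stratify the split by target label (default TRUE).
#' @param epochs Number of full-batch gradient steps (default 500).
#' @param learning_rate Step size (default 0.1).
#' @param seed Integer seed controlling the split and initialization.
#' @return List of class `hibpn_train_config`.
#' @export
train_config <- function(split_ratio = 0.10, stratify = TRUE, epochs = 500L,
                         learning_rate = 0.1, seed = 1L) {
  if (split_ratio <= 0 || split_ratio >= 1) stop_config("split_ratio must be in (0, 1)")
  if (epochs < 0) stop_config("epochs must be non-negative")
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  structure(list(split_ratio = split_ratio, stratify = stratify,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "hibpn_train_config")
}

#' Split records into training and test sets (1:9 protocol)
#'
#' Draws `round(split_ratio * n)` training rows, stratified by the target
#' label so both classes are represented in training; the remainder is the
#' test set. Deterministic given the seed.
#'
#' @param data Data frame of records.
#' @param target Name of the binary target column (its values define strata
#'   when `stratify` is on).
#' @param config A [train_config()].
#' @return List with tibbles `train` and `test` and the integer `train_idx`.
#' @export
split_1_9 <- function(data, target, config = train_config()) {
  n <- nrow(data)
  if (n < 10) stop_invalid("need at least 10 records to split")
  n_train <- round(config$split_ratio * n)
  withr::with_seed(config$seed, {
    if (config$stratify) {
      y <- data[[target]]
      classes <- split(seq_len(n), y)
      if (any(lengths(classes) == 0) || length(classes) < 2)
        abort("both target classes must be present to stratify", class = "hibpn_split_error")
      # proportional allocation, at least one per class, largest-remainder fixup
      want <- n_train * lengths(classes) / n
      take <- pmax(1L, floor(want))
      rem <- n_train - sum(take)
      if (rem > 0) {
        ord <- order(want - floor(want), decreasing = TRUE)
        for (j in head(ord, rem)) take[j] <- take[j] + 1L
      } else if (rem < 0) {
        ord <- order(want - floor(want))
        for (j in head(ord, -rem)) {
          if (take[j] > 1L) take[j] <- take[j] - 1L
        }
      }
      if (any(take >= lengths(classes)))
        abort("a class is too small to populate both train and test",
              class = "hibpn_split_error")
      train_idx <- sort(unlist(purrr::map2(classes, take, function(ix, k) sample(ix, k)),
                               use.names = FALSE))
    } else {
      train_idx <- sort(sample.int(n, n_train))
    }
  })
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE],
       train_idx = train_idx)
}

# gradient-descent loop over one chain; returns params + loss history
train_chain <- function(params, x, y, chain, mode, config) {
  lr <- config$learning_rate
  losses <- numeric(config$epochs)
  if (chain != "forward" && mode == "classification" && length(unique(y)) < 2)
    abort("training target has a single class", class = "hibpn_training_error")
  for (e in seq_len(config$epochs)) {
    cache <- chain_forward(params, x, chain, mode)
    losses[e] <- chain_loss(cache$p, y, if (chain == "forward") "classification" else mode)
    if (!is.finite(losses[e]))
      abort(sprintf("loss diverged (non-finite) at epoch %d", e),
            class = "hibpn_numeric_error")
    g <- chain_backward(params, x, y, cache, chain, mode)
    for (nm in names(g)) {
      params[[nm]]$W <- params[[nm]]$W - lr * g[[nm]]$W
      params[[nm]]$b <- params[[nm]]$b - lr * g[[nm]]$b
    }
  }
  list(params = params, loss = losses)
}

#' Fit the bidirectional network on a training set
#'
#' Trains the forward chain (probability of social exclusion) and/or the
#' reverse chain (probability of the high hostile-interpretation bin) on the
#' given training records. The two chains are trained independently, each
#' with its own encoder parameters; binary cross-entropy is minimized by
#' full-batch gradient descent.
#'
#' @param train_data Tibble of training participant records.
#' @param chains Character vector, subset of `c("forward", "reverse")`.
#' @param dims A [hibpn_dims()].
#' @param config A [train_config()] (`split_ratio`/`stratify` are unused
#'   here; splitting is the caller's responsibility, see [split_1_9()]).
#' @param drop_groups Dimension groups to ablate before training; see
#'   [encode_features()].
#' @return Object of class `hibpn_fit` holding per-chain parameters, scalers
#'   and loss histories.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 200, seed = 3))
#' fit <- hibpn_fit(cohort, chains = "forward",
#'                  config = train_config(epochs = 50))
#' head(predict(fit, cohort, chain = "forward"))
#' @export
hibpn_fit <- function(train_data, chains = c("forward", "reverse"),
                      dims = hibpn_dims(), config = train_config(),
                      drop_groups = character()) {
  chains <- match.arg(chains, several.ok = TRUE)
  fit <- list(dims = dims, config = config, drop_groups = drop_groups,
              n_train = nrow(train_data), chains = list())
  for (ch in chains) {
    feats <- encode_features(train_data, ch, drop_groups)
    if (length(unique(feats$y)) < 2)
      abort(sprintf("%s-chain training target has a single class", ch),
            class = "hibpn_training_error")
    scaler <- fit_scaler(feats)
    sf <- apply_scaler(feats, scaler)
    params <- init_params(dims, ncol(sf$he), ncol(sf$n), ncol(sf$h),
                          seed = config$seed)
    trained <- train_chain(params, list(he = sf$he, n = sf$n, h = sf$h),
                           sf$y, ch, "classification", config)
    fit$chains[[ch]] <- list(params = trained$params, scaler = scaler,
                             loss = trained$loss, group_map = feats$group_map)
  }
  structure(fit, class = "hibpn_fit")
}

#' Predict from a fitted network
#'
#' @param object A [hibpn_fit()] result.
#' @param newdata Tibble of participant records.
#' @param chain Which chain to predict from.
#' @param type `"prob"` (default) for the head probability, `"class"` for the
#'   0/1 label at threshold 0.5, `"continuous"` for the reverse chain's
#'   unbounded regression output.
#' @param ... Unused.
#' @return Numeric (or integer, for `"class"`) vector, one value per row.
#' @export
predict.hibpn_fit <- function(object, newdata, chain = c("forward", "reverse"),
                              type = c("prob", "class", "continuous"), ...) {
  chain <- match.arg(chain)
  type <- match.arg(type)
  st <- object$chains[[chain]]
  if (is.null(st)) stop_invalid("model was not fitted for the %s chain", chain)
  feats <- encode_features(newdata, chain, object$drop_groups)
  sf <- apply_scaler(feats, st$scaler)
  mode <- if (type == "continuous") "regression" else "classification"
  cache <- chain_forward(st$params, list(he = sf$he, n = sf$n, h = sf$h), chain, mode)
  p <- as.numeric(cache$p)
  switch(type, prob = p, continuous = p, class = as.integer(p >= 0.5))
}

#' @export
print.hibpn_fit <- function(x, ...) {
  cat("Bidirectional prediction network fit\n")
  cat(sprintf("  chains: %s | training rows: %d | epochs: %d\n",
              paste(names(x$chains), collapse = ", "), x$n_train, x$config$epochs))
  for (ch in names(x$chains))
    cat(sprintf("  %s-chain final training loss: %.4f\n", ch,
                utils::tail(x$chains[[ch]]$loss, 1)))
  if (length(x$drop_groups))
    cat("  ablated groups:", paste(x$drop_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-layer parameter summary of a fitted network
#'
#' @param x A `hibpn_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per chain and layer: dimensions and weight
#'   norms.
#' @method tidy hibpn_fit
#' @export
tidy.hibpn_fit <- function(x, ...) {
  purrr::map_dfr(names(x$chains), function(ch) {
    p <- x$chains[[ch]]$params
    layers <- p[vapply(p, function(e) is.list(e) && !is.null(e$W), logical(1))]
    purrr::map_dfr(names(layers), function(nm) {
      tibble::tibble(chain = ch, layer = nm,
                     in_dim = ncol(layers[[nm]]$W), out_dim = nrow(layers[[nm]]$W),
                     weight_norm = sqrt(sum(layers[[nm]]$W^2)))
    })
  })
}

#' One-row fit summary
#'
#' @param x A `hibpn_fit` object.
#' @param ... Unused.
#' @return Tibble with the training size, epochs, and per-chain final losses.
#' @method glance hibpn_fit
#' @export
glance.hibpn_fit <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    epochs = x$config$epochs,
    learning_rate = x$config$learning_rate,
    forward_loss = if (!is.null(x$chains$forward)) utils::tail(x$chains$forward$loss, 1) else NA_real_,
    reverse_loss = if (!is.null(x$chains$reverse)) utils::tail(x$chains$reverse$loss, 1) else NA_real_
  )
}
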