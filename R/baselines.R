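# Classical comparison models.
#
# Ten baselines are wrapped behind one adapter so the comparison table is a
# single call and every model's metrics flow through the same evaluation
# code path as the network's. Scores are class-1 probabilities where the
# library provides them, otherwise a monotone decision value usable for ROC
# (SVM decision values, AdaBoost vote margins).

BASELINE_NAMES <- c("logistic_regression", "random_forest", "gradient_boosting",
                    "adaboost", "svm", "naive_bayes", "knn", "lda", "qda",
                    "decision_tree")

#' Default baseline specifications
#'
#' @param names Subset of the ten supported model names.
#' @param seed Seed applied to every stochastic fit.
#' @return List of baseline specs (name, hyperparameters, seed).
#' @export
baseline_specs <- function(names = BASELINE_NAMES, seed = 1L) {
  if (anyDuplicated(names)) stop_invalid("duplicate baseline names")
  bad <- setdiff(names, BASELINE_NAMES)
  if (length(bad)) stop_invalid("unknown baseline(s): %s", paste(bad, collapse = ", "))
  hyper <- list(
    random_forest = list(ntree = 500),
    gradient_boosting = list(nrounds = 100, max_depth = 3, eta = 0.3),
    adaboost = list(n_rounds = 50),
    svm = list(kernel = "radial", cost = 1),
    knn = list(k = 5),
    decision_tree = list(cp = 0.01)
  )
  purrr::map(names, function(nm) {
    list(name = nm, hyperparameters = hyper[[nm]] %||% list(), seed = as.integer(seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discrete AdaBoost (SAMME with two classes) over depth-1 rpart stumps;
# returns the weighted vote margin as the ROC score
fit_adaboost <- function(X, y, n_rounds = 50) {
  df <- data.frame(X, check.names = TRUE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  yf <- factor(y, levels = c(0, 1))
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(yy ~ ., data = cbind(df, yy = yf), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas,
       score = function(newX) {
         ndf <- data.frame(newX, check.names = TRUE)
         margins <- rep(0, nrow(ndf))
         for (i in seq_along(stumps)) {
           p <- as.integer(as.character(predict(stumps[[i]], ndf, type = "class")))
           margins <- margins + alphas[i] * (2 * p - 1)
         }
         margins
       })
}

#' Fit one baseline classifier
#'
#' @param spec One element of [baseline_specs()].
#' @param X Numeric feature matrix (training rows).
#' @param y 0/1 training labels; both classes must be present.
#' @return Handle of class `hibpn_baseline` exposing `predict_scores(newX)`
#'   and `predict_labels(newX)`.
#' @export
fit_baseline <- function(spec, X, y) {
  if (length(unique(y)) < 2)
    abort("baseline training labels contain a single class",
          class = "hibpn_training_error")
  hp <- spec$hyperparameters
  df <- data.frame(X, check.names = TRUE)
  yf <- factor(y, levels = c(0, 1))
  score_fn <- withr::with_seed(spec$seed, switch(
    spec$name,
    logistic_regression = {
      fit <- suppressWarnings(glm(yy ~ ., data = cbind(df, yy = y), family = binomial()))
      function(newX) as.numeric(predict(fit, data.frame(newX, check.names = TRUE),
                                        type = "response"))
    },
    random_forest = {
      fit <- randomForest::randomForest(X, yf, ntree = hp$ntree %||% 500)
      function(newX) predict(fit, newX, type = "prob")[, "1"]
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth %||% 3,
                      eta = hp$eta %||% 0.3, nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds %||% 100, verbose = 0)
      function(newX) as.numeric(predict(fit, xgboost::xgb.DMatrix(newX, nthread = 1)))
    },
    adaboost = fit_adaboost(X, y, hp$n_rounds %||% 50)$score,
    svm = {
      fit <- e1071::svm(X, yf, kernel = hp$kernel %||% "radial",
                        cost = hp$cost %||% 1, scale = FALSE)
      function(newX) {
        dv <- attr(predict(fit, newX, decision.values = TRUE), "decision.values")
        # decision values are oriented toward the first class in the column name
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        if (first == "1") as.numeric(dv) else -as.numeric(dv)
      }
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(df, yf)
      function(newX) predict(fit, data.frame(newX, check.names = TRUE),
                             type = "raw")[, "1"]
    },
    knn = {
      k <- hp$k %||% 5
      function(newX) {
        pr <- class::knn(X, newX, yf, k = k, prob = TRUE)
        win <- attr(pr, "prob")
        ifelse(pr == "1", win, 1 - win)
      }
    },
    lda = {
      fit <- MASS::lda(X, grouping = yf)
      function(newX) predict(fit, newX)$posterior[, "1"]
    },
    qda = {
      fit <- tryCatch(MASS::qda(X, grouping = yf), error = function(e) {
        warn("QDA covariance singular; refitting on jittered features")
        MASS::qda(X + matrix(rnorm(length(X), 0, 1e-6), nrow(X)), grouping = yf)
      })
      function(newX) predict(fit, newX)$posterior[, "1"]
    },
    decision_tree = {
      fit <- rpart::rpart(yy ~ ., data = cbind(df, yy = yf), method = "class",
                          control = rpart::rpart.control(cp = hp$cp %||% 0.01, xval = 0))
      function(newX) predict(fit, data.frame(newX, check.names = TRUE),
                             type = "prob")[, "1"]
    },
    stop_invalid("unknown baseline '%s'", spec$name)
  ))
  structure(list(name = spec$name, spec = spec, predict_scores = score_fn,
                 predict_labels = function(newX) {
                   s <- score_fn(newX)
                   thr <- if (spec$name %in% c("svm", "adaboost")) 0 else 0.5
                   as.integer(s >= thr)
                 }),
            class = "hibpn_baseline")
}

#' Fit and evaluate every baseline on one chain's split
#'
#' Encodes the chain's features (identically to the network's input
#' standardization), fits each baseline on the training rows and scores the
#' test rows through the shared evaluation code path. A model that errors is
#' reported with `NA` metrics and the error message rather than aborting the
#' batch.
#'
#' @param train,test Tibbles of participant records.
#' @param chain `"forward"` or `"reverse"`.
#' @param specs List from [baseline_specs()].
#' @return Tibble: one row per model with `model`, `chain`, `acc`, `f1`,
#'   `auc`, `n_test`, `roc` (list-column), `note`.
#' @export
evaluate_baselines <- function(train, test, chain = c("forward", "reverse"),
                               specs = baseline_specs()) {
  chain <- match.arg(chain)
  if (anyDuplicated(purrr::map_chr(specs, "name")))
    stop_invalid("duplicate baseline names")
  tr <- encode_features(train, chain)
  te <- encode_features(test, chain)
  scaler <- fit_scaler(tr)
  Xtr <- flatten_features(apply_scaler(tr, scaler))
  Xte <- flatten_features(apply_scaler(te, scaler))
  purrr::map_dfr(specs, function(sp) {
    res <- tryCatch({
      h <- fit_baseline(sp, Xtr, tr$y)
      scores <- h$predict_scores(Xte)
      row <- evaluate_scores(te$y, scores,
                             threshold = if (sp$name %in% c("svm", "adaboost")) 0 else 0.5)
      dplyr::mutate(row, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(acc = NA_real_, f1 = NA_real_, auc = NA_real_,
                     n_test = nrow(test), roc = list(NULL),
                     note = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(model = sp$name, chain = chain), res)
  })
}
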