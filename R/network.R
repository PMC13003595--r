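# The bidirectional prediction network.
#
# Three encoder modules feed two prediction heads:
#   * human-environment encoder: two-layer MLP that first upscales then
#     downscales demographics, basic needs, estimated catch rate and
#     personality-type indicators (plus the condition indicator for the
#     reverse chain only);
#   * narcissism encoder: one upscaling layer over the NPI-16 and HSNS totals;
#   * hostile-interpretation encoder: one layer over the standardized
#     hostile / non-hostile interpretation scores, producing the intermediate
#     feature the forward head consumes.
# The forward head concatenates all three encodings and emits the probability
# of social exclusion through a sigmoid hidden layer and a sigmoid output.
# The reverse head concatenates the first two encodings and emits the hostile
# interpretation bias, either as an unbounded continuous value (regression
# mode) or as the probability of the high-hostility bin (classification
# mode, the default for evaluation).
#
# Weight matrices are stored out_dim x in_dim; batches are row-major, so a
# layer computes X %*% t(W) + b.

relu <- function(z) pmax(z, 0)
sigmoid <- stats::plogis

act_fun <- function(name) {
  switch(name, relu = relu, identity = identity,
         stop_config("unknown activation '%s'", name))
}
act_grad <- function(name, z) {
  switch(name, relu = (z > 0) * 1, identity = array(1, dim(z)),
         stop_config("unknown activation '%s'", name))
}

#' Network layer widths
#'
#' Hidden-layer widths of the network. Input widths are derived from the
#' encoded feature matrices at fit time; the upscale/downscale constraints
#' (first human-environment layer wider than its input, second narrower than
#' the first, narcissism layer wider than its two inputs) are validated when
#' parameters are initialized.
#'
#' @param he_up,he_down Widths of the human-environment encoder's upscaling
#'   and downscaling layers (defaults 32 and 8).
#' @param narc_up Width of the narcissism upscaling layer (default 8).
#' @param hostile_mid Width of the hostile-interpretation encoder (default 4).
#' @param env_hidden Width of the forward (exclusion) head's hidden layer
#'   (default 16).
#' @param hostile_hidden Width of the reverse (hostility) head's hidden layer
#'   (default 16).
#' @param activation Hidden-layer nonlinearity for the encoders and the
#'   reverse head: `"relu"` (default) or `"identity"`. The forward head's
#'   hidden and output layers always use the sigmoid.
#' @return List of class `hibpn_dims`.
#' @export
hibpn_dims <- function(he_up = 32L, he_down = 8L, narc_up = 8L, hostile_mid = 4L,
                       env_hidden = 16L, hostile_hidden = 16L,
                       activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  structure(list(he_up = he_up, he_down = he_down, narc_up = narc_up,
                 hostile_mid = hostile_mid, env_hidden = env_hidden,
                 hostile_hidden = hostile_hidden, activation = activation),
            class = "hibpn_dims")
}

new_layer <- function(out_dim, in_dim) {
  # He-style initialization: keeps pre-activation variance stable under ReLU
  list(W = matrix(rnorm(out_dim * in_dim, 0, sqrt(2 / max(in_dim, 1))),
                  nrow = out_dim, ncol = in_dim),
       b = numeric(out_dim))
}

#' Initialize network parameters
#'
#' Seed-deterministic initialization of every layer of both chains.
#'
#' @param dims A [hibpn_dims()].
#' @param d_he,d_n,d_h Input widths of the human-environment, narcissism and
#'   hostile-interpretation encoders (0 disables a module, as in ablation).
#' @param seed Integer seed.
#' @return List of class `hibpn_params` with per-layer `W`/`b` matrices.
#' @export
init_params <- function(dims, d_he, d_n, d_h, seed = 1L) {
  stopifnot(inherits(dims, "hibpn_dims"))
  if (d_he < 1) stop_config("human-environment module needs at least one input")
  if (dims$he_up <= d_he)
    stop_config("upscaling layer must be wider than its input (%d <= %d)", dims$he_up, d_he)
  if (dims$he_down >= dims$he_up)
    stop_config("downscaling layer must be narrower than the upscaled layer")
  if (d_n > 0 && dims$narc_up <= d_n)
    stop_config("narcissism layer must be wider than its input")

  fused <- dims$he_down + if (d_n > 0) dims$narc_up else 0L
  all_dim <- fused + if (d_h > 0) dims$hostile_mid else 0L

  withr::with_seed(as.integer(seed), {
    p <- list(
      he_up = new_layer(dims$he_up, d_he),
      he_down = new_layer(dims$he_down, dims$he_up),
      narc_up = if (d_n > 0) new_layer(dims$narc_up, d_n),
      hostile_mid = if (d_h > 0) new_layer(dims$hostile_mid, d_h),
      env_hidden = new_layer(dims$env_hidden, all_dim),
      env_out = new_layer(1L, dims$env_hidden),
      hostile_hidden = new_layer(dims$hostile_hidden, fused),
      hostile_out = new_layer(1L, dims$hostile_hidden)
    )
    structure(c(p, list(dims = dims, d_he = d_he, d_n = d_n, d_h = d_h)),
              class = "hibpn_params")
  })
}

as_batch <- function(x, d, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != d)
    stop_invalid("%s expects %d input columns, got %d", what, d, ncol(x))
  x
}

layer_fwd <- function(X, layer) sweep(X %*% t(layer$W), 2, layer$b, "+")

#' Human-environment encoder
#'
#' Two-layer upscale-then-downscale encoding of the human and situational
#' covariates.
#'
#' @param x_he Numeric vector or row-matrix of human-environment features.
#' @param params A [init_params()] result.
#' @return Matrix of encoded features (rows = observations).
#' @export
human_env_encode <- function(x_he, params) {
  X <- as_batch(x_he, params$d_he, "human-environment encoder")
  act <- act_fun(params$dims$activation)
  act(layer_fwd(act(layer_fwd(X, params$he_up)), params$he_down))
}

#' Narcissism encoder
#'
#' One-layer upscaling of the NPI-16 and HSNS totals.
#'
#' @inheritParams human_env_encode
#' @param x_n Numeric vector or row-matrix of narcissism features.
#' @return Matrix of encoded features.
#' @export
narcissism_encode <- function(x_n, params) {
  if (params$d_n == 0) return(matrix(numeric(0), nrow = NROW(rbind(x_n)), ncol = 0))
  X <- as_batch(x_n, params$d_n, "narcissism encoder")
  act_fun(params$dims$activation)(layer_fwd(X, params$narc_up))
}

#' Fuse encoder outputs by concatenation
#'
#' @param a_he,a_n Encoded feature matrices (human-environment first).
#' @return Column-bound matrix; values preserved position-wise.
#' @export
fuse <- function(a_he, a_n) {
  a_he <- rbind(a_he); a_n <- rbind(a_n)
  if (ncol(a_n) == 0) return(a_he)
  if (any(!is.finite(a_he)) || any(!is.finite(a_n)))
    stop_invalid("encoded features must be finite")
  cbind(a_he, a_n)
}

#' Hostile-interpretation encoder
#'
#' One-layer encoding of the standardized hostile and non-hostile
#' interpretation scores, producing the intermediate feature consumed by the
#' forward head.
#'
#' @inheritParams human_env_encode
#' @param x_h Numeric vector or row-matrix of interpretation-score features.
#' @return Matrix of encoded features.
#' @export
hostile_intermediate <- function(x_h, params) {
  if (params$d_h == 0) return(matrix(numeric(0), nrow = NROW(rbind(x_h)), ncol = 0))
  X <- as_batch(x_h, params$d_h, "hostile-interpretation encoder")
  act_fun(params$dims$activation)(layer_fwd(X, params$hostile_mid))
}

#' Forward prediction head: probability of social exclusion
#'
#' Concatenates the fused trait encoding with the hostile-interpretation
#' intermediate feature and passes it through a sigmoid hidden layer and a
#' sigmoid output unit.
#'
#' @inheritParams human_env_encode
#' @param a_hen Fused human-environment + narcissism encoding.
#' @param a_h_mid Hostile-interpretation intermediate feature (may have zero
#'   columns when the module is ablated).
#' @return Numeric vector of exclusion probabilities in (0, 1).
#' @export
forward_chain <- function(a_hen, a_h_mid, params) {
  A <- cbind(rbind(a_hen), rbind(a_h_mid))
  if (ncol(A) != ncol(params$env_hidden$W))
    stop_invalid("forward head expects %d inputs, got %d", ncol(params$env_hidden$W), ncol(A))
  ae <- sigmoid(layer_fwd(A, params$env_hidden))
  as.numeric(sigmoid(layer_fwd(ae, params$env_out)))
}

#' Reverse prediction head: hostile interpretation bias
#'
#' Passes the fused encoding through a hidden layer and returns both the
#' continuous bias value (linear output, regression mode) and the probability
#' of the high-hostility bin (sigmoid on the same pre-activation,
#' classification mode).
#'
#' @inheritParams human_env_encode
#' @param a_hen Fused human-environment + narcissism encoding.
#' @return List with `continuous` and `prob_high` numeric vectors.
#' @export
reverse_chain <- function(a_hen, params) {
  A <- rbind(a_hen)
  if (ncol(A) != ncol(params$hostile_hidden$W))
    stop_invalid("reverse head expects %d inputs, got %d", ncol(params$hostile_hidden$W), ncol(A))
  ah <- act_fun(params$dims$activation)(layer_fwd(A, params$hostile_hidden))
  z <- as.numeric(layer_fwd(ah, params$hostile_out))
  list(continuous = z, prob_high = sigmoid(z))
}

# Full forward pass with cached intermediates for backprop.
# chain = "forward": x = list(he, n, h), target = exclusion indicator.
# chain = "reverse": x = list(he, n), target = high-hostility indicator
# (classification) or continuous score (regression).
chain_forward <- function(params, x, chain, mode = "classification") {
  act <- act_fun(params$dims$activation)
  cache <- list()
  cache$z1 <- layer_fwd(x$he, params$he_up);   cache$a1 <- act(cache$z1)
  cache$z2 <- layer_fwd(cache$a1, params$he_down); cache$ahe <- act(cache$z2)
  if (params$d_n > 0) {
    cache$zn <- layer_fwd(x$n, params$narc_up); cache$an <- act(cache$zn)
  } else cache$an <- matrix(numeric(0), nrow(x$he), 0)
  cache$ahen <- cbind(cache$ahe, cache$an)
  if (chain == "forward") {
    if (params$d_h > 0) {
      cache$zm <- layer_fwd(x$h, params$hostile_mid); cache$am <- act(cache$zm)
    } else cache$am <- matrix(numeric(0), nrow(x$he), 0)
    cache$aall <- cbind(cache$ahen, cache$am)
    cache$ze <- layer_fwd(cache$aall, params$env_hidden)
    cache$ae <- sigmoid(cache$ze)
    cache$zo <- layer_fwd(cache$ae, params$env_out)
    cache$p <- sigmoid(cache$zo)
  } else {
    cache$zh <- layer_fwd(cache$ahen, params$hostile_hidden)
    cache$ah <- act(cache$zh)
    cache$zo <- layer_fwd(cache$ah, params$hostile_out)
    cache$p <- if (mode == "classification") sigmoid(cache$zo) else cache$zo
  }
  cache
}

# Gradients of the mean loss (BCE for sigmoid heads, MSE for regression)
# with respect to every parameter of the chain.
chain_backward <- function(params, x, y, cache, chain, mode = "classification") {
  n <- nrow(x$he)
  actg <- function(z) act_grad(params$dims$activation, z)
  g <- list()
  if (chain == "forward" || mode == "classification") {
    dzo <- (cache$p - y) / n              # d(mean BCE)/dz for sigmoid output
  } else {
    dzo <- 2 * (cache$p - y) / n          # d(mean squared error)/dz
  }
  if (chain == "forward") {
    g$env_out <- list(W = t(dzo) %*% cache$ae, b = colSums(dzo))
    dae <- dzo %*% params$env_out$W
    dze <- dae * cache$ae * (1 - cache$ae)
    g$env_hidden <- list(W = t(dze) %*% cache$aall, b = colSums(dze))
    dall <- dze %*% params$env_hidden$W
    k <- ncol(cache$ahen)
    dhen <- dall[, seq_len(k), drop = FALSE]
    if (params$d_h > 0) {
      dam <- dall[, k + seq_len(ncol(cache$am)), drop = FALSE]
      dzm <- dam * actg(cache$zm)
      g$hostile_mid <- list(W = t(dzm) %*% x$h, b = colSums(dzm))
    }
  } else {
    g$hostile_out <- list(W = t(dzo) %*% cache$ah, b = colSums(dzo))
    dah <- dzo %*% params$hostile_out$W
    dzh <- dah * actg(cache$zh)
    g$hostile_hidden <- list(W = t(dzh) %*% cache$ahen, b = colSums(dzh))
    dhen <- dzh %*% params$hostile_hidden$W
  }
  khe <- ncol(cache$ahe)
  dahe <- dhen[, seq_len(khe), drop = FALSE]
  if (params$d_n > 0) {
    dan <- dhen[, khe + seq_len(ncol(cache$an)), drop = FALSE]
    dzn <- dan * actg(cache$zn)
    g$narc_up <- list(W = t(dzn) %*% x$n, b = colSums(dzn))
  }
  dz2 <- dahe * actg(cache$z2)
  g$he_down <- list(W = t(dz2) %*% cache$a1, b = colSums(dz2))
  da1 <- dz2 %*% params$he_down$W
  dz1 <- da1 * actg(cache$z1)
  g$he_up <- list(W = t(dz1) %*% x$he, b = colSums(dz1))
  g
}

chain_loss <- function(p, y, mode = "classification") {
  if (mode == "classification") {
    eps <- 1e-12
    -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  } else {
    mean((p - y)^2)
  }
}
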