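#' Activation functions
#'
#' `relu(x)` is the rectified linear unit `max(0, x)` used on the hidden
#' layers; `sigmoid(x)` is `1 / (1 + exp(-x))` used on the single output
#' unit. The argument is clamped to +/- 500 against overflow and the result
#' to `[1e-12, 1 - 1e-12]`, so scores stay strictly inside (0, 1) even for
#' saturating logits.
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape as `x`.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' @rdname relu
#' @export
sigmoid <- function(x) {
  s <- 1 / (1 + exp(-pmin(pmax(x, -500), 500)))
  pmin(pmax(s, 1e-12), 1 - 1e-12)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y * log(s) + (1 - y) * log(1 - s))` over the batch. Scores are
#' clamped away from exact 0/1 (at 1e-12) so the loss stays finite.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param labels 0/1 labels, same length.
#' @return A single non-negative number.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L) {
    abort("scores and labels must be nonempty and the same length",
      class = "tpmda_shape_error"
    )
  }
  s <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  mean(-(labels * log(s) + (1 - labels) * log(1 - s)))
}

#' Classifier configuration
#'
#' Configuration of the fully connected classifier head: exactly three hidden
#' layers with ReLU activations and a single sigmoid output unit. The last
#' hidden width determines the dimension of the pair representation just
#' before scoring; 128 is the default (the best-performing width of the
#' 32/64/128/256 sweep), with 256, 256, 128 as the full stack.
#' Training uses full-batch Adam on binary cross-entropy; the default
#' learning rate is 1e-5 with 800 epochs.
#'
#' @param hidden_sizes Integer vector of exactly 3 hidden-layer widths.
#' @param learning_rate Adam learning rate.
#' @param epochs Number of full-batch training epochs.
#' @param seed Integer seed for weight initialisation.
#' @return A `fann_config` list.
#' @export
fann_config <- function(hidden_sizes = c(256L, 256L, 128L), learning_rate = 1e-5,
                        epochs = 800L, seed = 1L) {
  if (length(hidden_sizes) != 3L || any(hidden_sizes < 1L)) {
    abort("hidden_sizes must be exactly 3 positive integers",
      class = "tpmda_validation_error"
    )
  }
  stopifnot(learning_rate > 0, epochs >= 1L)
  structure(
    list(
      hidden_sizes = as.integer(hidden_sizes),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      seed = as.integer(seed)
    ),
    class = "fann_config"
  )
}

#' Initialise the fully connected classifier
#'
#' He-initialised weights for input -> h1 -> h2 -> h3 -> 1, seeded from the
#' configuration.
#'
#' @param input_size Length of the pair feature vector.
#' @param config A [fann_config()].
#' @return A `fann_model` list of weight matrices `W1..W4` and bias vectors
#'   `b1..b4`.
#' @export
fann_init <- function(input_size, config = fann_config()) {
  sizes <- c(input_size, config$hidden_sizes, 1L)
  withr::with_seed(config$seed, {
    layers <- lapply(seq_len(4L), function(l) {
      fan_in <- sizes[l]
      list(
        W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)), fan_in, sizes[l + 1L]),
        b = numeric(sizes[l + 1L])
      )
    })
  })
  params <- list()
  for (l in seq_len(4L)) {
    params[[paste0("W", l)]] <- layers[[l]]$W
    params[[paste0("b", l)]] <- layers[[l]]$b
  }
  structure(c(params, list(sizes = sizes)), class = "fann_model")
}

# Forward pass keeping layer activations for backprop.
fann_forward_cache <- function(model, X) {
  X <- matrix(X, ncol = model$sizes[1])
  Z1 <- sweep(X %*% model$W1, 2, model$b1, `+`); A1 <- relu(Z1)
  Z2 <- sweep(A1 %*% model$W2, 2, model$b2, `+`); A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% model$W3, 2, model$b3, `+`); A3 <- relu(Z3)
  Z4 <- sweep(A3 %*% model$W4, 2, model$b4, `+`)
  list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3,
       Z4 = Z4, scores = as.numeric(sigmoid(Z4)))
}

#' Score pair features with the classifier
#'
#' Deterministic forward pass; scores are strictly inside (0, 1).
#'
#' @param model A `fann_model` from [fann_init()] (or a trained fit's
#'   classifier).
#' @param X Feature matrix (one row per pair) or a single feature vector.
#' @return Numeric vector of association scores.
#' @export
fann_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$sizes[1]) {
    abort(sprintf("feature length %d does not match input layer %d", ncol(X), model$sizes[1]),
      class = "tpmda_shape_error"
    )
  }
  fann_forward_cache(model, X)$scores
}

# Backprop from dZ4 = dLoss/dZ4 (B x 1). Returns parameter grads and dX.
fann_backward <- function(model, cache, dZ4) {
  dZ4 <- matrix(dZ4, ncol = 1L)
  gW4 <- t(cache$A3) %*% dZ4; gb4 <- colSums(dZ4)
  dA3 <- dZ4 %*% t(model$W4); dZ3 <- dA3 * (cache$Z3 > 0)
  gW3 <- t(cache$A2) %*% dZ3; gb3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(model$W3); dZ2 <- dA2 * (cache$Z2 > 0)
  gW2 <- t(cache$A1) %*% dZ2; gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(model$W2); dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- t(cache$X) %*% dZ1; gb1 <- colSums(dZ1)
  dX <- dZ1 %*% t(model$W1)
  list(
    grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                 W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4),
    dX = dX
  )
}

# --- Adam on a flat named list of numeric arrays -------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
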