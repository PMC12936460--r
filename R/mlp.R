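#' Initialize the three-layer MLP
#'
#' The base classifier is a multilayer perceptron with two ReLU hidden
#' layers of `hidden` units each and a softmax output layer over the class
#' vocabulary. Hidden weights are drawn from a seeded scaled-uniform
#' (Glorot-style) distribution; all biases and the entire output layer
#' start at zero. The zero output layer makes the untrained network emit
#' exactly uniform class probabilities, so its loss on any two-class batch
#' is exactly `log(2)` — a useful analytic anchor for the first
#' communication rounds.
#'
#' @param input_dim flattened image length (e.g. 784 for 28 x 28 x 1).
#' @param hidden hidden-layer width; default 200.
#' @param n_classes number of output classes; default 2.
#' @param seed RNG seed; identical seeds give identical parameters.
#' @return object of class `model_params`: named list of tensors
#'   `W1 (input_dim x hidden)`, `b1`, `W2 (hidden x hidden)`, `b2`,
#'   `W3 (hidden x n_classes)`, `b3`.
#' @export
init_mlp <- function(input_dim, hidden = 200L, n_classes = 2L, seed = 42L) {
  if (!(input_dim >= 1 && hidden >= 1 && n_classes >= 2)) {
    stop("all dimensions must be positive (n_classes >= 2)")
  }
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  withr::with_seed(as.integer(seed), {
    structure(
      list(W1 = glorot(input_dim, hidden), b1 = rep(0, hidden),
           W2 = glorot(hidden, hidden),    b2 = rep(0, hidden),
           W3 = matrix(0, hidden, n_classes), b3 = rep(0, n_classes)),
      class = "model_params"
    )
  })
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", nrow(x$W1), "-", ncol(x$W1), "-", ncol(x$W2),
      "-", ncol(x$W3), " MLP (", format(sum(lengths(x)), big.mark = ","),
      " parameters)\n", sep = "")
  invisible(x)
}

# forward pass keeping intermediates for backprop
mlp_forward_full <- function(params, x) {
  if (ncol(x) != nrow(params$W1)) {
    stop("batch width ", ncol(x), " does not match input_dim ",
         nrow(params$W1))
  }
  z1 <- sweep(x %*% params$W1, 2L, params$b1, `+`)
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% params$W2, 2L, params$b2, `+`)
  a2 <- pmax(z2, 0)
  z3 <- sweep(a2 %*% params$W3, 2L, params$b3, `+`)
  if (!all(is.finite(z3))) stop("non-finite activations in forward pass")
  # row-wise softmax with max subtraction for stability
  zs <- z3 - apply(z3, 1L, max)
  e <- exp(zs)
  p <- e / rowSums(e)
  list(a1 = a1, z1 = z1, a2 = a2, z2 = z2, probs = p)
}

#' Forward pass: class probabilities
#'
#' Affine -> ReLU -> affine -> ReLU -> affine -> softmax. Every output row
#' is a probability distribution over the classes (non-negative, summing
#' to 1).
#'
#' @param params `model_params`.
#' @param x batch matrix, one flattened image per row (see
#'   [dataset_tensors()] for the flattening contract).
#' @return `nrow(x) x n_classes` probability matrix.
#' @export
mlp_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  mlp_forward_full(params, x)$probs
}

#' Mean categorical cross-entropy of a model on a batch
#'
#' `-(1/n) sum_i sum_c y_ic log p_ic`, with probabilities clipped below at
#' 1e-12 so that a confidently wrong prediction yields a large finite loss
#' rather than infinity.
#'
#' @param params `model_params`.
#' @param x batch matrix (rows = flattened images).
#' @param y one-hot label matrix.
#' @return non-negative scalar loss.
#' @export
local_loss <- function(params, x, y) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (nrow(x) == 0L) stop("empty batch")
  check_one_hot(y, nrow(x))
  p <- mlp_forward_full(params, x)$probs
  cross_entropy(p, y)
}

cross_entropy <- function(probs, y) {
  p <- pmax(probs, 1e-12)
  -sum(y * log(p)) / nrow(y)
}

check_one_hot <- function(y, n) {
  if (is.null(dim(y)) || nrow(y) != n || !all(y %in% c(0, 1)) ||
      !all(rowSums(y) == 1)) {
    stop("labels must be a one-hot matrix with one row per sample")
  }
}

#' Analytic gradients of the cross-entropy loss
#'
#' Exact reverse-mode differentiation of the affine/ReLU/softmax stack:
#' the softmax + cross-entropy output delta is `(p - y)/n`, propagated
#' through the ReLU masks. Returns tensors shaped exactly like the
#' parameters, suitable for [sgd_step()].
#'
#' @inheritParams local_loss
#' @return list of gradient tensors `W1, b1, W2, b2, W3, b3`.
#' @export
mlp_gradients <- function(params, x, y) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (nrow(x) == 0L) stop("empty batch")
  check_one_hot(y, nrow(x))
  f <- mlp_forward_full(params, x)
  n <- nrow(x)
  dz3 <- (f$probs - y) / n
  dimnames(dz3) <- NULL   # label names must not leak into the tensors
  dW3 <- crossprod(f$a2, dz3)
  db3 <- colSums(dz3)
  da2 <- tcrossprod(dz3, params$W3)
  dz2 <- da2 * (f$z2 > 0)
  dW2 <- crossprod(f$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, params$W2)
  dz1 <- da1 * (f$z1 > 0)
  dW1 <- crossprod(x, dz1)
  db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Fresh optimizer state for a model
#'
#' @param params `model_params`.
#' @return object of class `optimizer_state`: zero velocity tensors shaped
#'   like the parameters and `step_count = 0`.
#' @export
optimizer_state <- function(params) {
  structure(
    list(velocity = lapply(params, function(tensor) tensor * 0),
         step_count = 0L),
    class = "optimizer_state"
  )
}

#' One SGD-with-momentum update
#'
#' Classical momentum with time-based learning-rate decay, the default
#' behaviour of the standard SGD optimizer these hyperparameters come
#' from: at step `t` (0-based) the effective rate is
#' `lr_t = lr / (1 + decay * t)`, the velocity update is
#' `v <- momentum * v - lr_t * g`, and the parameters move by `w <- w + v`.
#' With `momentum = 0, decay = 0` this is vanilla SGD. Setting
#' `cfg$decay_mode = "l2"` instead treats `decay` as an L2 penalty added to
#' the gradient (`g + decay * w`) with a constant rate.
#'
#' @param params `model_params`.
#' @param grads gradient tensors from [mlp_gradients()].
#' @param state `optimizer_state`.
#' @param cfg a [fed_config()] (fields `learning_rate`, `momentum`,
#'   `decay`, `decay_mode`).
#' @return list with updated `params` and `state`.
#' @export
sgd_step <- function(params, grads, state, cfg) {
  for (nm in names(params)) {
    if (!identical(dim0(params[[nm]]), dim0(grads[[nm]]))) {
      stop("gradient shape mismatch in tensor '", nm, "'")
    }
  }
  if (identical(cfg$decay_mode, "l2")) {
    lr_t <- cfg$learning_rate
    grads <- mapply(function(g, w) g + cfg$decay * w, grads, params,
                    SIMPLIFY = FALSE)
  } else {
    lr_t <- cfg$learning_rate / (1 + cfg$decay * state$step_count)
  }
  for (nm in names(params)) {
    state$velocity[[nm]] <- cfg$momentum * state$velocity[[nm]] -
      lr_t * grads[[nm]]
    params[[nm]] <- params[[nm]] + state$velocity[[nm]]
  }
  state$step_count <- state$step_count + 1L
  list(params = params, state = state)
}
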