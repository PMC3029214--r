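#' Initialize a one-hidden-layer perceptron
#'
#' Architecture used both for the word-feature classifier (5-10-4 by default)
#' and the stacked-fusion meta-classifier (6-10-4): tangent-sigmoid hidden
#' units, log-sigmoid output units (one per severity level, outputs in
#' `(0, 1)`).
#'
#' @param n_in,n_hidden,n_out layer sizes; `n_out` defaults to 4 levels.
#' @param seed integer seed for the weight initialization.
#' @return an object of class `"vl_mlp"` with weight matrices `W1`, `W2` and
#'   bias vectors `b1`, `b2`.
#' @export
mlp_init <- function(n_in, n_hidden = 10L, n_out = 4L, seed = 1L) {
  with_seed(seed, {
    lim1 <- 1 / sqrt(n_in); lim2 <- 1 / sqrt(n_hidden)
    structure(list(
      W1 = matrix(runif(n_hidden * n_in, -lim1, lim1), n_hidden, n_in),
      b1 = runif(n_hidden, -lim1, lim1),
      W2 = matrix(runif(n_out * n_hidden, -lim2, lim2), n_out, n_hidden),
      b2 = runif(n_out, -lim2, lim2),
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out), norm = NULL),
      class = "vl_mlp")
  })
}

logsig <- function(z) 1 / (1 + exp(-z))

# forward pass; X is N x n_in, returns list(H N x hidden, Y N x out)
mlp_forward <- function(model, X) {
  H <- tanh(sweep(X %*% t(model$W1), 2, model$b1, `+`))
  Y <- logsig(sweep(H %*% t(model$W2), 2, model$b2, `+`))
  list(H = H, Y = Y)
}

# mean-squared-error loss and exact batch gradients (backpropagation)
mlp_gradients <- function(model, X, T_) {
  n <- nrow(X)
  fw <- mlp_forward(model, X)
  E <- fw$Y - T_
  loss <- mean(E^2)
  # dL/dY = 2 E / (n * n_out); logsig' = y(1-y); tanh' = 1 - h^2
  dZ2 <- 2 * E * fw$Y * (1 - fw$Y) / (n * model$n_out)
  dW2 <- t(dZ2) %*% fw$H
  db2 <- colSums(dZ2)
  dH <- dZ2 %*% model$W2
  dZ1 <- dH * (1 - fw$H^2)
  dW1 <- t(dZ1) %*% X
  db1 <- colSums(dZ1)
  list(loss = loss, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Train a perceptron by gradient-descent backpropagation
#'
#' Full-batch gradient descent on mean squared error. Inputs are z-scored
#' with statistics stored in the model; targets are one-hot level vectors.
#' Deterministic given the initialization seed. Optional early stopping
#' monitors validation MSE.
#'
#' @param model a `"vl_mlp"` from [mlp_init()].
#' @param inputs N x n_in matrix of raw inputs.
#' @param targets N-vector of levels (1..n_out) or N x n_out one-hot matrix.
#' @param epochs maximum epochs (default 2000).
#' @param lr learning rate (default 0.01).
#' @param validation optional `list(inputs, targets)` for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @return the trained model with `$loss_trace` (per-epoch training MSE).
#' @export
train_mlp <- function(model, inputs, targets, epochs = 2000L, lr = 0.01,
                      validation = NULL, patience = 100L) {
  X <- as.matrix(inputs)
  if (ncol(X) != model$n_in) vl_stop("input dimension mismatch", "dimension")
  T_ <- one_hot(targets, model$n_out)
  if (nrow(T_) != nrow(X)) vl_stop("inputs and targets misaligned", "dimension")
  mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv <= 0] <- 1
  model$norm <- list(mu = mu, sd = sdv)
  Xn <- scale(X, mu, sdv)
  Vn <- NULL; VT <- NULL
  if (!is.null(validation)) {
    Vn <- scale(as.matrix(validation$inputs), mu, sdv)
    VT <- one_hot(validation$targets, model$n_out)
  }
  best <- Inf; best_model <- model; stall <- 0L
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    g <- mlp_gradients(model, Xn, T_)
    if (!is.finite(g$loss))
      vl_stop("training diverged (NaN loss); lower the learning rate", "divergence")
    trace <- c(trace, g$loss)
    model$W1 <- model$W1 - lr * g$dW1; model$b1 <- model$b1 - lr * g$db1
    model$W2 <- model$W2 - lr * g$dW2; model$b2 <- model$b2 - lr * g$db2
    if (!is.null(Vn)) {
      vmse <- mean((mlp_forward(model, Vn)$Y - VT)^2)
      if (vmse < best - 1e-9) { best <- vmse; best_model <- model; stall <- 0L }
      else if ((stall <- stall + 1L) >= patience) { model <- best_model; break }
    }
  }
  if (!is.null(Vn) && best < Inf && stall < patience &&
      mean((mlp_forward(model, Vn)$Y - VT)^2) > best) model <- best_model
  model$loss_trace <- trace
  model
}

one_hot <- function(y, k) {
  if (is.matrix(y)) return(y)
  y <- as.integer(y)
  out <- matrix(0, length(y), k)
  out[cbind(seq_along(y), y)] <- 1
  out
}

#' Soft outputs and level decision of a perceptron
#'
#' @param model a trained `"vl_mlp"`.
#' @param input a single input vector or an N x n_in matrix (raw scale; the
#'   stored normalization is applied).
#' @return for a single vector, `list(level, soft)`; for a matrix, a list of
#'   `levels` (N-vector) and `soft` (N x n_out). Ties break to the lower
#'   level.
#' @export
predict_level <- function(model, input) {
  X <- if (is.matrix(input)) input else matrix(input, nrow = 1)
  if (ncol(X) != model$n_in) vl_stop("input dimension mismatch", "dimension")
  if (!is.null(model$norm)) X <- scale(X, model$norm$mu, model$norm$sd)
  Y <- mlp_forward(model, X)$Y
  lev <- apply(Y, 1, which.max)   # which.max is first-max: ties -> lower level
  if (!is.matrix(input)) list(level = lev[1], soft = Y[1, ])
  else list(levels = lev, soft = Y)
}

#' @export
print.vl_mlp <- function(x, ...) {
  cat(sprintf("<MLP %d-%d-%d (tansig/logsig)%s>\n", x$n_in, x$n_hidden,
              x$n_out,
              if (is.null(x$loss_trace)) ", untrained"
              else sprintf(", trained %d epochs, MSE %.4g",
                           length(x$loss_trace), tail(x$loss_trace, 1))))
  invisible(x)
}
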