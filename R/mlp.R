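# A compact feedforward multilayer perceptron for binary classification.
#
# Supports 1-3 hidden layers of 100 units, logistic/tanh/relu activations,
# and three optimizers: full L-BFGS (via stats::optim with analytic
# gradients), minibatch SGD with momentum and an adaptive learning rate
# (divided by 5 whenever two consecutive epochs fail to improve the loss),
# and Adam. Training is capped at `epochs` passes. Sigmoid output with
# binary cross-entropy loss (plus a small L2 weight penalty for numerical
# stability, matching common defaults).

mlp_activations <- list(
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(a) a * (1 - a)),
  tanh = list(f = tanh, df = function(a) 1 - a^2),
  relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1)
)

mlp_init <- function(sizes, seed) {
  keep <- .Random.seed_exists(); set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  list(W = W, b = b)
}

mlp_forward <- function(par, X, act) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L - 1)) {
    A[[l + 1]] <- act$f(sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`))
  }
  zout <- as.numeric(A[[L]] %*% par$W[[L]] + par$b[[L]])
  p <- 1 / (1 + exp(-zout))
  list(A = A, p = p)
}

# loss and gradient in one pass; lambda = L2 penalty
mlp_loss_grad <- function(par, X, y, act, lambda = 1e-4) {
  n <- nrow(X)
  fw <- mlp_forward(par, X, act)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) +
    lambda / (2 * n) * sum(vapply(par$W, function(w) sum(w^2), 0))
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix((fw$p - y) / n, n, 1)
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$A[[l]], delta) + lambda / n * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * act$df(fw$A[[l]])
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

mlp_flatten <- function(par) unlist(c(par$W, par$b), use.names = FALSE)

mlp_unflatten <- function(theta, sizes) {
  W <- list(); b <- list(); pos <- 0
  for (l in seq_len(length(sizes) - 1)) {
    k <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(theta[pos + seq_len(k)], sizes[l], sizes[l + 1]); pos <- pos + k
  }
  for (l in seq_len(length(sizes) - 1)) {
    k <- sizes[l + 1]
    b[[l]] <- theta[pos + seq_len(k)]; pos <- pos + k
  }
  list(W = W, b = b)
}

#' Fit a small multilayer perceptron for binary classification
#'
#' @param X Numeric matrix of predictors (already standardized by the caller).
#' @param y Binary response (0/1).
#' @param hidden_layers Number of hidden layers, 1-3 (100 units each).
#' @param activation `"logistic"`, `"tanh"` or `"relu"`.
#' @param solver `"lbfgs"`, `"sgd"` (momentum 0.9, learning rate divided by 5
#'   after two consecutive non-improving epochs) or `"adam"`.
#' @param learning_rate Initial learning rate for sgd/adam.
#' @param epochs Maximum training epochs (default 100).
#' @param hidden_units Units per hidden layer (default 100).
#' @param seed Seed for initialisation and minibatch shuffling.
#' @return An object of class `edapain_mlp`.
#' @export
mlp_fit <- function(X, y, hidden_layers = 1, activation = "relu",
                    solver = "adam", learning_rate = 1e-3, epochs = 100,
                    hidden_units = 100, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  act <- mlp_activations[[match.arg(activation, names(mlp_activations))]]
  solver <- match.arg(solver, c("lbfgs", "sgd", "adam"))
  sizes <- c(ncol(X), rep(hidden_units, hidden_layers), 1)
  par <- mlp_init(sizes, seed)

  if (solver == "lbfgs") {
    fn <- function(theta) mlp_loss_grad(mlp_unflatten(theta, sizes), X, y, act)$loss
    gr <- function(theta) {
      g <- mlp_loss_grad(mlp_unflatten(theta, sizes), X, y, act)
      unlist(c(g$gW, g$gb), use.names = FALSE)
    }
    opt <- optim(mlp_flatten(par), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = epochs))
    par <- mlp_unflatten(opt$par, sizes)
  } else {
    keep <- .Random.seed_exists(); set.seed(seed + 1L)
    n <- nrow(X)
    bs <- min(200L, n)
    lr <- learning_rate
    L <- length(par$W)
    vel_W <- lapply(par$W, function(w) w * 0); vel_b <- lapply(par$b, function(b) b * 0)
    mW <- vel_W; vW <- vel_W; mb <- vel_b; vb <- vel_b
    best <- Inf; bad <- 0L; it <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        g <- mlp_loss_grad(par, X[idx, , drop = FALSE], y[idx], act)
        it <- it + 1L
        for (l in seq_len(L)) {
          if (solver == "sgd") {
            vel_W[[l]] <- 0.9 * vel_W[[l]] - lr * g$gW[[l]]
            vel_b[[l]] <- 0.9 * vel_b[[l]] - lr * g$gb[[l]]
            par$W[[l]] <- par$W[[l]] + vel_W[[l]]
            par$b[[l]] <- par$b[[l]] + vel_b[[l]]
          } else {
            mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
            vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
            mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
            vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
            par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / (1 - b1^it)) /
              (sqrt(vW[[l]] / (1 - b2^it)) + eps)
            par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / (1 - b1^it)) /
              (sqrt(vb[[l]] / (1 - b2^it)) + eps)
          }
        }
      }
      ep_loss <- mlp_loss_grad(par, X, y, act)$loss
      if (ep_loss < best - 1e-4) { best <- ep_loss; bad <- 0L } else bad <- bad + 1L
      if (solver == "sgd" && bad >= 2L) { lr <- lr / 5; bad <- 0L }
    }
    if (keep$had) assign(".Random.seed", keep$seed, envir = globalenv())
  }
  structure(list(par = par, sizes = sizes, activation = activation,
                 solver = solver),
            class = "edapain_mlp")
}

#' @export
predict.edapain_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  act <- mlp_activations[[object$activation]]
  p <- mlp_forward(object$par, as.matrix(newdata), act)$p
  if (type == "prob") p else as.integer(p >= 0.5)
}
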