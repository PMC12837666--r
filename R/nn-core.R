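# Building blocks for the hand-written network: activations with derivatives,
# dense layers, batch normalization, parameter-tree utilities and Adam.
# Sequence batches are stored as matrices [D x (T*B)] with window-major
# columns; signal batches as arrays [F, C, T, B].

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

leaky_relu <- function(x, slope = 0.01) {
  0.5 * ((1 + slope) * x + (1 - slope) * abs(x))
}

leaky_relu_grad <- function(x, slope = 0.01) {
  0.5 * ((1 + slope) + (1 - slope) * sign(x))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(y)))

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

linear_fwd <- function(W, x, b = NULL) {
  y <- W %*% x
  if (!is.null(b)) y <- y + b
  y
}

linear_bwd <- function(W, x, dy, bias = TRUE) {
  out <- list(dW = tcrossprod(dy, x), dx = crossprod(W, dy))
  if (bias) out$db <- rowSums(dy)
  out
}

# Batch normalization over the feature (row) dimension of a [F x M] view.
bn_init <- function(f) list(gamma = rep(1, f), beta = rep(0, f))

bn_buffers <- function(f) list(mean = rep(0, f), var = rep(1, f), n = 0)

# Running statistics are a cumulative average over all training batches seen,
# so inference-mode normalization is meaningful from the first epoch on
# (relevant because early stopping compares validation losses across epochs).
bn_fwd <- function(x, par, buf, train, eps = 1e-5) {
  if (train) {
    mu <- rowMeans(x)
    v <- rowMeans(x^2) - mu^2
    buf$n <- buf$n + 1
    m <- 1 / buf$n
    buf$mean <- (1 - m) * buf$mean + m * mu
    buf$var <- (1 - m) * buf$var + m * v
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv_sd
  list(y = par$gamma * xhat + par$beta,
       cache = list(xhat = xhat, inv_sd = inv_sd, train = train),
       buf = buf)
}

bn_bwd <- function(dy, par, cache) {
  xhat <- cache$xhat
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * par$gamma
  if (cache$train) {
    dx <- cache$inv_sd *
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dx <- cache$inv_sd * dxhat
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- parameter trees ------------------------------------------------------
# Parameters, gradients and Adam moments are nested named lists whose leaves
# are numeric arrays; they are flattened to single vectors for the optimizer.

tree_flatten <- function(tree) unlist(tree, use.names = FALSE)

tree_fill <- function(tree, vec) {
  i <- 0
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- x
    out[] <- vec[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  rec(tree)
}

tree_zeros <- function(tree) {
  rec <- function(x) if (is.list(x)) lapply(x, rec) else x * 0
  rec(tree)
}

tree_count <- function(tree) length(tree_flatten(tree))

adam_init <- function(params) {
  n <- tree_count(params)
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  p <- tree_flatten(params)
  g <- tree_flatten(grads)
  stopifnot(length(p) == length(g))
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = tree_fill(params, p), state = state)
}
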