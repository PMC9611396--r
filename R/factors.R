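# Parameter factors.
#
# A factor is an environment holding named parameter arrays plus matching
# gradient accumulators and Adam moment estimates. Environments give
# reference semantics: assigning one factor to two graph partitions makes
# the sharing literal — both sides read and update the same storage.

.glorot <- function(nin, nout, rng) {
  lim <- sqrt(6 / (nin + nout))
  matrix(rng$runif(nin * nout, -lim, lim), nin, nout)
}

# orthogonal init via QR of a Gaussian matrix; per-gate blocks for LSTMs
.orthogonal <- function(n, rng) {
  a <- matrix(rng$rnorm(n * n), n, n)
  qr_d <- qr(a)
  q <- qr.Q(qr_d)
  q * sign(diag(qr.R(qr_d)))
}

.new_factor <- function(kind, params) {
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$params <- params
  env$grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  env$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  env$v <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  class(env) <- c(paste0(kind, "_factor"), "st_factor")
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-hidden-layer perceptron applied per frame: relu(X W + b)
new_mlp_factor <- function(n_in, n_out, rng) {
  .new_factor("mlp", list(W = .glorot(n_in, n_out, rng),
                          b = matrix(0, 1, n_out)))
}

# LSTM factor, optionally with a linear output projection and output
# activation ("none", "relu", "tanh"); gate order (i, f, g, o)
new_lstm_factor <- function(n_in, n_hidden, n_out = NULL, rng,
                            activation = "relu") {
  Wx <- do.call(cbind, lapply(1:4, function(k) .glorot(n_in, n_hidden, rng)))
  Wh <- do.call(cbind, lapply(1:4, function(k) .orthogonal(n_hidden, rng)))
  params <- list(Wx = Wx, Wh = Wh, b = matrix(0, 1, 4 * n_hidden))
  f <- if (!is.null(n_out)) {
    c(params, list(Wz = .glorot(n_hidden, n_out, rng),
                   bz = matrix(0, 1, n_out)))
  } else params
  env <- .new_factor("lstm", f)
  env$project <- !is.null(n_out)
  env$activation <- match.arg(activation, c("none", "relu", "tanh"))
  env$n_hidden <- n_hidden
  env
}

new_dense_factor <- function(n_in, n_out, rng, activation = "none") {
  env <- .new_factor("dense", list(W = .glorot(n_in, n_out, rng),
                                   b = matrix(0, 1, n_out)))
  env$activation <- match.arg(activation, c("none", "relu", "tanh"))
  env
}

.act_code <- function(a) c(none = 0L, relu = 1L, tanh = 2L)[[a]]

# ---- forward/backward wrappers -------------------------------------------

mlp_forward <- function(f, X) {
  pre <- sweep(X %*% f$params$W, 2, f$params$b, "+")
  list(Y = pmax(pre, 0), pre = pre, X = X)
}

mlp_backward <- function(f, cache, dY) {
  dpre <- dY * (cache$pre > 0)
  .accum_cpp(f$grads$W, crossprod(cache$X, dpre))
  .accum_cpp(f$grads$b, colSums(dpre))
  dpre %*% t(f$params$W)
}

dense_forward <- function(f, X) {
  pre <- sweep(X %*% f$params$W, 2, f$params$b, "+")
  Y <- switch(f$activation, none = pre, relu = pmax(pre, 0), tanh = tanh(pre))
  list(Y = Y, pre = pre, X = X)
}

dense_backward <- function(f, cache, dY) {
  dpre <- switch(f$activation,
                 none = dY,
                 relu = dY * (cache$pre > 0),
                 tanh = dY * (1 - cache$Y^2))
  if (is.null(dim(dpre))) dpre <- matrix(dpre, nrow = 1)
  .accum_cpp(f$grads$W, crossprod(cache$X, dpre))
  .accum_cpp(f$grads$b, colSums(dpre))
  dpre %*% t(f$params$W)
}

lstm_forward <- function(f, X) {
  p <- f$params
  out <- .lstm_forward_cpp(
    X, p$Wx, p$Wh, p$b,
    if (f$project) p$Wz else matrix(0, 0, 0),
    if (f$project) p$bz else matrix(0, 1, 0),
    f$project, .act_code(f$activation))
  out$X <- X
  out
}

lstm_backward <- function(f, cache, dZ, need_dx = TRUE) {
  p <- f$params
  g <- .lstm_backward_cpp(
    cache$X, p$Wx, p$Wh,
    if (f$project) p$Wz else matrix(0, 0, 0),
    cache$H, cache$C, cache$TC, cache$G,
    if (f$project) cache$Zpre else matrix(0, 0, 0),
    dZ, f$project, .act_code(f$activation), need_dx)
  .accum_cpp(f$grads$Wx, g$dWx)
  .accum_cpp(f$grads$Wh, g$dWh)
  .accum_cpp(f$grads$b, g$db)
  if (f$project) {
    .accum_cpp(f$grads$Wz, g$dWz)
    .accum_cpp(f$grads$bz, g$dbz)
  }
  g$dX
}

# ---- bookkeeping ----------------------------------------------------------

factor_n_params <- function(f) sum(vapply(f$params, length, 0L))

zero_grads <- function(factors) {
  for (f in factors) .zero_arrays_cpp(f$grads)
  invisible(NULL)
}

# clip each factor's gradient to a global L2 norm
clip_grads <- function(factors, max_norm) {
  for (f in factors) {
    nrm <- sqrt(sum(vapply(f$grads, function(g) sum(g^2), 0)))
    if (nrm > max_norm) {
      scale <- max_norm / nrm
      for (nm in names(f$grads)) f$grads[[nm]] <- f$grads[[nm]] * scale
    }
  }
  invisible(NULL)
}

# Adam update (in place); step counter t supplied by the trainer
adam_step <- function(factors, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (f in factors) {
    .adam_step_cpp(f$params, f$grads, f$m, f$v, lr, t, beta1, beta2, eps)
  }
  invisible(NULL)
}
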