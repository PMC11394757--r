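# Minimal dense-network machinery: MLPs with ReLU hidden units, batch
# normalization, explicit reverse-mode gradients, and Adam. Written against
# base-R matrix ops; every forward has a mirrored backward and gradients are
# verified against finite differences in the test suite.

# --- RNG-backed initialization -----------------------------------------------

# He (ReLU) initialization for a linear layer in -> out.
init_linear <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

# An MLP is a list of linear layers; ReLU on all but the last. out_gain
# shrinks the output layer's initialization; components feeding Max
# aggregations or residual sums use gains < 1 so that activations stay O(1)
# at initialization (Max over n i.i.d. draws grows like sqrt(2 log n)).
init_mlp <- function(dims, out_gain = 1) {
  nl <- length(dims) - 1L
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    sc <- if (l < nl) sqrt(2 / dims[l]) else out_gain * sqrt(1 / dims[l])
    layers[[l]] <- init_linear(dims[l], dims[l + 1L], sc)
  }
  layers
}

zeros_like_mlp <- function(mlp) {
  lapply(mlp, function(l) list(W = l$W * 0, b = l$b * 0))
}

# --- MLP forward/backward ----------------------------------------------------

mlp_forward <- function(mlp, X, cache = FALSE) {
  nl <- length(mlp)
  inputs <- if (cache) vector("list", nl) else NULL
  H <- X
  for (l in seq_len(nl)) {
    if (cache) inputs[[l]] <- H
    H <- H %*% mlp[[l]]$W
    H <- sweep(H, 2, mlp[[l]]$b, "+")
    if (l < nl) H[H < 0] <- 0
  }
  if (cache) list(out = H, inputs = inputs) else H
}

# dY: gradient wrt output. Returns dX and per-layer grads.
mlp_backward <- function(mlp, cache, dY) {
  nl <- length(mlp)
  grads <- vector("list", nl)
  dH <- dY
  for (l in rev(seq_len(nl))) {
    Xl <- cache$inputs[[l]]
    if (l < nl) {
      # recompute the layer's post-ReLU output mask from the next layer input
      act <- cache$inputs[[l + 1L]]
      dH <- dH * (act > 0)
    }
    grads[[l]] <- list(W = crossprod(Xl, dH), b = colSums(dH))
    dH <- dH %*% t(mlp[[l]]$W)
  }
  list(dX = dH, grads = grads)
}

# --- Batch normalization -----------------------------------------------------

init_batchnorm <- function(dim) {
  list(gamma = rep(1, dim), beta = numeric(dim),
       run_mean = numeric(dim), run_var = rep(1, dim))
}

bn_forward <- function(bn, X, training = TRUE, momentum = 0.1, eps = 1e-5) {
  if (training && nrow(X) > 1L) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu, "-")^2)
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  xhat <- sweep(sweep(X, 2, mu, "-"), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  upd <- bn
  if (training && nrow(X) > 1L) {
    upd$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    upd$run_var <- (1 - momentum) * bn$run_var + momentum * v
  }
  list(out = out, xhat = xhat, mu = mu, var = v, eps = eps, X = X,
       training = training && nrow(X) > 1L, bn = upd)
}

bn_backward <- function(bn, cache, dY) {
  xhat <- cache$xhat
  m <- nrow(xhat)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  if (!cache$training) {
    dX <- sweep(sweep(dY, 2, bn$gamma, "*"), 2, sqrt(cache$var + cache$eps), "/")
    return(list(dX = dX, dgamma = dgamma, dbeta = dbeta))
  }
  istd <- 1 / sqrt(cache$var + cache$eps)
  dxhat <- sweep(dY, 2, bn$gamma, "*")
  dX <- sweep(
    dxhat - matrix(colMeans(dxhat), m, length(istd), byrow = TRUE) -
      sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
    2, istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- Parameter flattening + Adam --------------------------------------------

# Parameters live in nested lists of numeric arrays; these helpers walk the
# tree in deterministic order.
tree_keys <- function(p) {
  nm <- names(p)
  if (is.null(nm)) nm <- as.character(seq_along(p))
  nm
}

param_leaves <- function(p, path = character()) {
  if (is.numeric(p)) return(stats::setNames(list(p), paste(path, collapse = "/")))
  out <- list()
  keys <- tree_keys(p)
  for (k in seq_along(p)) {
    if (keys[k] %in% c("run_mean", "run_var")) next  # BN running stats: not trained
    out <- c(out, param_leaves(p[[k]], c(path, keys[k])))
  }
  out
}

map_leaves <- function(p, f, path = character()) {
  if (is.numeric(p)) return(f(p, paste(path, collapse = "/")))
  keys <- tree_keys(p)
  for (k in seq_along(p)) {
    if (keys[k] %in% c("run_mean", "run_var")) next
    p[[k]] <- map_leaves(p[[k]], f, c(path, keys[k]))
  }
  p
}

adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

# PyTorch-style Adam with L2 weight decay folded into the gradient.
adam_step <- function(params, grads, state, lr = 5e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 1e-5) {
  state$t <- state$t + 1L
  t <- state$t
  gl <- param_leaves(grads)
  new <- map_leaves(params, function(x, key) {
    g <- gl[[key]]
    if (is.null(g)) return(x)
    g <- g + weight_decay * x
    state$m[[key]] <<- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <<- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    x - lr * mhat / (sqrt(vhat) + eps)
  })
  list(params = new, state = state)
}

# elementwise sum of two congruent parameter trees
add_trees <- function(a, b, w = 1) {
  if (is.numeric(a)) return(a + w * b)
  for (k in seq_along(a)) a[[k]] <- add_trees(a[[k]], b[[k]], w)
  a
}

# gradient tree of zeros congruent with params
zero_tree <- function(p) {
  if (is.numeric(p)) return(p * 0)
  for (k in seq_along(p)) p[[k]] <- zero_tree(p[[k]])
  p
}

tree_grad_norm <- function(p) {
  sqrt(sum(vapply(param_leaves(p), function(x) sum(x^2), numeric(1))))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable log(1 + exp(z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
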