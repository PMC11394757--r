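# Learned chemical features: each surface point aggregates its 16 nearest
# in-alphabet atoms. Every atom contributes the output of a small embedding
# network on [one-hot(element) + 1/distance]; contributions are summed and
# linearly mapped to 6 scalars. The embedding network is trained jointly
# with the rest of the model.

#' Initialize chemical-feature network parameters
#'
#' Architecture: linear 7 -> 6, batch normalization, ReLU, linear 6 -> 6
#' (per-atom embedding), then a post-sum linear map 6 -> 6.
#'
#' @return Parameter list of class `chem_net_params`.
#' @export
init_chem_net <- function() {
  structure(list(
    l1 = init_linear(7L, 6L),
    bn = init_batchnorm(6L),
    l2 = init_linear(6L, 6L),
    # contributions of ~16 atoms are summed before this map; 1/16 keeps the
    # post-sum features O(1) at initialization
    post = init_linear(6L, 6L, scale = sqrt(1 / 6) / 16)
  ), class = "chem_net_params")
}

# Geometry cache: nearest eligible atoms per surface point. Fixed during
# training, so computed once per structure.
chem_precompute <- function(cloud, atoms, k = 16L) {
  elig <- which(atoms$is_protein & !is.na(atoms$chem_index))
  if (length(elig) == 0L) {
    stop("chemical featurization: no atoms in the chemical alphabet", call. = FALSE)
  }
  AC <- atoms$coords[elig, , drop = FALSE]
  ci <- atoms$chem_index[elig]
  n <- nrow(cloud$coords)
  kk <- min(k, length(elig))
  pt_id <- rep(seq_len(n), each = kk)
  X <- matrix(0, n * kk, 7L)
  block <- max(1L, floor(2e7 / length(elig)))
  for (b in seq(1L, n, by = block)) {
    idx <- b:min(n, b + block - 1L)
    D2 <- pairwise_dist2(cloud$coords[idx, , drop = FALSE], AC)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      ord <- order(D2[ii, ])[seq_len(kk)]
      rows <- ((i - 1L) * kk + 1L):(i * kk)
      X[cbind(rows, ci[ord] + 1L)] <- 1
      X[rows, 7L] <- 1 / pmax(sqrt(pmax(D2[ii, ord], 0)), 1e-6)
    }
  }
  list(X = X, pt_id = pt_id, n = n, k = kk)
}

chem_forward <- function(params, pre, training = FALSE) {
  h1 <- sweep(pre$X %*% params$l1$W, 2, params$l1$b, "+")
  bnc <- bn_forward(params$bn, h1, training = training)
  a1 <- bnc$out
  a1[a1 < 0] <- 0
  h2 <- sweep(a1 %*% params$l2$W, 2, params$l2$b, "+")
  S <- rowsum(h2, pre$pt_id, reorder = TRUE)
  out <- sweep(S %*% params$post$W, 2, params$post$b, "+")
  list(out = out, cache = list(pre = pre, h1 = h1, bnc = bnc, a1 = a1, S = S),
       bn_updated = bnc$bn)
}

chem_backward <- function(params, cache, dOut) {
  pre <- cache$pre
  dS <- dOut %*% t(params$post$W)
  g_post <- list(W = crossprod(cache$S, dOut), b = colSums(dOut))
  dh2 <- dS[pre$pt_id, , drop = FALSE]
  g_l2 <- list(W = crossprod(cache$a1, dh2), b = colSums(dh2))
  da1 <- dh2 %*% t(params$l2$W)
  da1 <- da1 * (cache$a1 > 0)
  bnb <- bn_backward(params$bn, cache$bnc, da1)
  g_l1 <- list(W = crossprod(pre$X, bnb$dX), b = colSums(bnb$dX))
  # run_mean/run_var carried as zeros so the gradient tree is congruent with
  # the parameter tree (they are never updated by the optimizer)
  list(grads = structure(list(l1 = g_l1,
                              bn = list(gamma = bnb$dgamma, beta = bnb$dbeta,
                                        run_mean = params$bn$run_mean * 0,
                                        run_var = params$bn$run_var * 0),
                              l2 = g_l2, post = g_post),
                         class = "chem_net_params"))
}

#' Compute the 6 chemical features per surface point
#'
#' Evaluation-mode forward pass of the chemical-feature network (batch-norm
#' running statistics are used). For training, the network is evaluated
#' inside the end-to-end model so its weights receive gradients.
#'
#' @param cloud A [surface_cloud()].
#' @param atoms The [atom_set()] the surface was sampled from.
#' @param params Parameters from [init_chem_net()].
#' @param k Number of nearest in-alphabet atoms per point (default 16).
#' @return N x 6 feature matrix.
#' @export
compute_chemical_features <- function(cloud, atoms, params = init_chem_net(),
                                      k = 16L) {
  pre <- chem_precompute(cloud, atoms, k)
  chem_forward(params, pre, training = FALSE)$out
}
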