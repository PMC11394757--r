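# The point-cloud GNN: T = 3 layers with auto-registration offsets, Max edge
# aggregation and residual state updates, followed by a per-vertex
# classification MLP with a logistic output. Forward passes are mirrored by
# hand-written reverse-mode gradients (verified against finite differences
# in the test suite), so the chemical-feature and embedding networks train
# end-to-end with the GNN.

#' Initialize the full model
#'
#' Components: chemical-feature network, initial-state embedding MLP
#' (19 -> state_dim -> state_dim), three GNN layers with unshared weights
#' (`mlp_w`: state_dim -> 64 -> 3 offset head; `mlp_f`: state_dim+3 ->
#' state_dim -> state_dim edge network; `mlp_g`: state_dim -> state_dim ->
#' state_dim update network), and a 4-layer classifier ending in one logit.
#'
#' @param state_dim Vertex state dimension (default 300).
#' @param n_layers Number of GNN iterations (default 3).
#' @param offset_hidden Hidden width of the offset head (default 64).
#' @param clf_hidden Classifier hidden widths (default c(128, 64)).
#' @param n_features Per-point feature count (default 16).
#' @return Object of class `pgnn_model`.
#' @export
init_model <- function(state_dim = 300L, n_layers = 3L, offset_hidden = 64L,
                       clf_hidden = c(128L, 64L), n_features = 16L) {
  layers <- vector("list", n_layers)
  for (t in seq_len(n_layers)) {
    layers[[t]] <- list(
      mlp_w = init_mlp(c(state_dim, offset_hidden, 3L), out_gain = 0.5),
      mlp_f = init_mlp(c(state_dim + 3L, state_dim, state_dim), out_gain = 0.5),
      mlp_g = init_mlp(c(state_dim, state_dim, state_dim), out_gain = 0.25)
    )
  }
  structure(list(
    chem = init_chem_net(),
    embed = init_mlp(c(n_features + 3L, state_dim, state_dim), out_gain = 0.5),
    layers = layers,
    clf = init_mlp(c(state_dim, clf_hidden, 1L), out_gain = 0.25),
    dims = list(state_dim = as.integer(state_dim), n_layers = as.integer(n_layers),
                offset_hidden = as.integer(offset_hidden),
                clf_hidden = as.integer(clf_hidden),
                n_features = as.integer(n_features))
  ), class = "pgnn_model")
}

#' @export
print.pgnn_model <- function(x, ...) {
  cat(sprintf("<pgnn_model> state_dim=%d, %d GNN layers, classifier %s\n",
              x$dims$state_dim, x$dims$n_layers,
              paste(c(x$dims$state_dim, x$dims$clf_hidden, 1), collapse = "->")))
  invisible(x)
}

edge_groups <- function(edges, m) {
  if (nrow(edges) == 0L) {
    return(list(has = integer(0), slots = matrix(NA_integer_, 0L, 0L)))
  }
  g <- split(seq_len(nrow(edges)), factor(edges[, 1], levels = seq_len(m)))
  has <- which(lengths(g) > 0L)
  list(has = has, slots = group_slots(g[has]))
}

gnn_layer_forward <- function(lp, H, X, edges, groups, cache = FALSE) {
  m <- nrow(H)
  D <- ncol(H)
  fw_w <- mlp_forward(lp$mlp_w, H, cache = cache)
  Delta <- if (cache) fw_w$out else fw_w
  nE <- nrow(edges)
  if (nE == 0L) {
    if (cache) return(list(out = H, empty = TRUE, fw_w = fw_w))
    return(H)
  }
  i <- edges[, 1]; j <- edges[, 2]
  U <- cbind(X[j, , drop = FALSE] - X[i, , drop = FALSE] + Delta[i, , drop = FALSE],
             H[j, , drop = FALSE])
  fw_f <- mlp_forward(lp$mlp_f, U, cache = cache)
  Ef <- if (cache) fw_f$out else fw_f
  has <- groups$has
  gm <- grouped_max(Ef, groups$slots, want_argmax = cache)
  A <- gm$max
  argmax <- gm$argmax
  fw_g <- mlp_forward(lp$mlp_g, A, cache = cache)
  G <- if (cache) fw_g$out else fw_g
  H2 <- H
  H2[has, ] <- H2[has, , drop = FALSE] + G
  if (cache) {
    list(out = H2, empty = FALSE, fw_w = fw_w, fw_f = fw_f, fw_g = fw_g,
         argmax = argmax, has = has, nE = nE, i = i, j = j, m = m, D = D)
  } else H2
}

gnn_layer_backward <- function(lp, cache, dH2) {
  if (isTRUE(cache$empty)) {
    zg <- list(mlp_w = zeros_like_mlp(lp$mlp_w), mlp_f = zeros_like_mlp(lp$mlp_f),
               mlp_g = zeros_like_mlp(lp$mlp_g))
    return(list(dH = dH2, grads = zg))
  }
  D <- cache$D
  dH <- dH2  # residual path
  dG <- dH2[cache$has, , drop = FALSE]
  bw_g <- mlp_backward(lp$mlp_g, cache$fw_g, dG)
  dA <- bw_g$dX
  dEf <- grouped_max_backward(dA, cache$argmax, cache$nE)
  bw_f <- mlp_backward(lp$mlp_f, cache$fw_f, dEf)
  dU <- bw_f$dX
  dRel <- dU[, 1:3, drop = FALSE]
  dHj <- dU[, -(1:3), drop = FALSE]
  # neighbor states
  agg_j <- rowsum(dHj, cache$j, reorder = FALSE)
  dH[as.integer(rownames(agg_j)), ] <- dH[as.integer(rownames(agg_j)), , drop = FALSE] + agg_j
  # offsets: Delta[i] appears once per out-edge of i
  dDelta <- matrix(0, cache$m, 3L)
  agg_i <- rowsum(dRel, cache$i, reorder = FALSE)
  dDelta[as.integer(rownames(agg_i)), ] <- agg_i
  bw_w <- mlp_backward(lp$mlp_w, cache$fw_w, dDelta)
  dH <- dH + bw_w$dX
  list(dH = dH, grads = list(mlp_w = bw_w$grads, mlp_f = bw_f$grads,
                             mlp_g = bw_g$grads))
}

#' One GNN layer update
#'
#' Applies the auto-registration offset, edge-feature MLP, per-vertex Max
#' aggregation and residual update: `offset_i = MLP_w(h_i)`; for each edge
#' (i, j) `e_ij = MLP_f([x_j - x_i + offset_i, h_j])`;
#' `h_i' = MLP_g(Max_j e_ij) + h_i`. Vertices without edges keep their state.
#'
#' @param states M x state_dim vertex states.
#' @param coords M x 3 vertex coordinates.
#' @param edges Edge matrix from [build_radius_graph()].
#' @param params One element of `model$layers` (lists `mlp_w`, `mlp_f`, `mlp_g`).
#' @return Updated M x state_dim state matrix.
#' @export
gnn_layer <- function(states, coords, edges, params) {
  groups <- edge_groups(edges, nrow(states))
  gnn_layer_forward(params, states, as.matrix(coords), edges, groups)
}

# Prepared structure: everything fixed during training for one structure.
# cloud must be labeled if used for training/evaluation of labels.
prepare_graph_input <- function(cloud, atoms, config = graph_config(),
                                k_chem = 16L, downsample = TRUE, aggregate = TRUE) {
  graph <- build_point_graph(cloud, config, downsample = downsample,
                             aggregate = aggregate)
  list(
    graph = graph,
    chem_pre = chem_precompute(cloud, atoms, k_chem),
    geom_feat = cloud$geom_feat,
    groups = edge_groups(graph$edges, nrow(graph$vertex_coords)),
    labels = graph$vertex_labels
  )
}

model_forward_full <- function(model, prep, training = FALSE, cache = FALSE) {
  cf <- chem_forward(model$chem, prep$chem_pre, training = training)
  feats <- cbind(cf$out, prep$geom_feat)
  af <- aggregate_forward(model$embed, feats, prep$graph$agg, cache = cache)
  H <- if (cache) af$states else af
  X <- prep$graph$vertex_coords
  lcaches <- if (cache) vector("list", length(model$layers)) else NULL
  for (t in seq_along(model$layers)) {
    res <- gnn_layer_forward(model$layers[[t]], H, X, prep$graph$edges,
                             prep$groups, cache = cache)
    if (cache) { lcaches[[t]] <- res; H <- res$out } else H <- res
  }
  clf <- mlp_forward(model$clf, H, cache = cache)
  logits <- if (cache) clf$out else clf
  list(
    probs = as.vector(sigmoid(logits)),
    logits = as.vector(logits),
    cache = if (cache) list(cf = cf, af = af, lcaches = lcaches, clf = clf,
                            feats = feats) else NULL,
    bn_updated = cf$bn_updated
  )
}

#' Per-vertex binding-site probabilities
#'
#' Full forward pass: chemical features, initial-state aggregation, three GNN
#' layers, classification MLP. Outputs lie strictly in (0, 1).
#'
#' @param model A [init_model()] (possibly trained) parameter set.
#' @param prep A prepared structure from [prepare_structure()].
#' @return Numeric vector of vertex probabilities.
#' @export
predict_vertices <- function(model, prep) {
  model_forward_full(model, prep, training = FALSE)$probs
}

# Weighted binary cross-entropy on logits. Loss is the weight-normalized
# mean; pos_weight multiplies positive-class terms.
bce_loss_grad <- function(logits, labels, pos_weight = 1) {
  w <- ifelse(labels == 1, pos_weight, 1)
  wsum <- sum(w)
  # loss_i = y*softplus(-z) + (1-y)*softplus(z)
  li <- labels * softplus(-logits) + (1 - labels) * softplus(logits)
  loss <- sum(w * li) / wsum
  p <- sigmoid(logits)
  dlogits <- w * (p - labels) / wsum
  list(loss = loss, dlogits = dlogits)
}

# Full backward pass; returns gradient tree congruent with the model.
model_backward_full <- function(model, prep, fw, dlogits) {
  cc <- fw$cache
  bw_clf <- mlp_backward(model$clf, cc$clf, matrix(dlogits, ncol = 1))
  dH <- bw_clf$dX
  lgrads <- vector("list", length(model$layers))
  for (t in rev(seq_along(model$layers))) {
    bl <- gnn_layer_backward(model$layers[[t]], cc$lcaches[[t]], dH)
    lgrads[[t]] <- bl$grads
    dH <- bl$dH
  }
  ab <- aggregate_backward(model$embed, prep$graph$agg, cc$af, dH,
                           n_feat_cols = ncol(cc$feats))
  dFeats <- matrix(0, nrow(cc$feats), ncol(cc$feats))
  dFeats[ab$dFeats_points, ] <- ab$dFeats
  dChem <- dFeats[, 1:6, drop = FALSE]
  cb <- chem_backward(model$chem, cc$cf$cache, dChem)
  structure(list(chem = cb$grads, embed = ab$grads, layers = lgrads,
                 clf = bw_clf$grads), class = "pgnn_grads")
}

# Loss + gradients for one structure (training mode). Returns the BN-updated
# chem params so running statistics advance.
model_loss_grads <- function(model, prep, pos_weight = 1) {
  fw <- model_forward_full(model, prep, training = TRUE, cache = TRUE)
  lg <- bce_loss_grad(fw$logits, prep$labels, pos_weight)
  grads <- model_backward_full(model, prep, fw, lg$dlogits)
  list(loss = lg$loss, grads = grads, bn_updated = fw$bn_updated,
       probs = fw$probs)
}

trainable_model <- function(model) {
  model[c("chem", "embed", "layers", "clf")]
}

#' Save / load a model checkpoint
#'
#' Weights are written as JSON (text, exact to double precision via base64-free
#' full-precision serialization) with an architecture sidecar; loading
#' validates dimensions strictly.
#'
#' @param model A `pgnn_model`.
#' @param path Output file (JSON).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  ser <- function(x) {
    if (is.matrix(x)) return(list(dim = dim(x), data = as.vector(x)))
    if (is.list(x)) return(lapply(unclass(x), ser))
    x
  }
  jsonlite::write_json(ser(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  rebuild <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      return(matrix(x$data, x$dim[1], x$dim[2]))
    }
    if (is.list(x)) return(lapply(x, rebuild))
    x
  }
  m <- rebuild(raw)
  m$dims <- lapply(m$dims, as.integer)
  model <- structure(m, class = "pgnn_model")
  d <- model$dims
  stopifnot(length(model$layers) == d$n_layers,
            nrow(model$layers[[1]]$mlp_f[[1]]$W) == d$state_dim + 3L,
            nrow(model$clf[[1]]$W) == d$state_dim)
  model
}
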