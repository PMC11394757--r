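# Point-cloud graph construction: voxel downsampling, r0 feature
# aggregation into vertex initial states, fixed-radius edges.

# Squared distances between row blocks, computed from coordinate differences
# (not the |x|^2 + |y|^2 - 2xy expansion, whose cancellation error grows with
# the distance from the origin and would break translation stability of
# neighbor sets at radius boundaries).
pairwise_dist2 <- function(A, B) {
  D2 <- outer(A[, 1], B[, 1], "-")^2
  D2 <- D2 + outer(A[, 2], B[, 2], "-")^2
  D2 + outer(A[, 3], B[, 3], "-")^2
}

#' Graph construction configuration
#'
#' @param voxel_size Voxel edge in Angstrom for downsampling (default 1.0).
#' @param r0 Aggregation radius in Angstrom (default 2.0).
#' @param r Edge radius in Angstrom (default 4.0); edges require distance
#'   strictly below `r`.
#' @param max_edges Maximum out-degree per vertex (default 32); when more
#'   neighbors are in range the nearest are kept.
#' @param state_dim Vertex state dimension (default 300).
#' @return A validated list of class `graph_config`.
#' @export
graph_config <- function(voxel_size = 1.0, r0 = 2.0, r = 4.0, max_edges = 32L,
                         state_dim = 300L) {
  stopifnot(voxel_size > 0, r0 > 0, r > 0, r > voxel_size, max_edges >= 1,
            state_dim >= 1)
  structure(list(voxel_size = voxel_size, r0 = r0, r = r,
                 max_edges = as.integer(max_edges),
                 state_dim = as.integer(state_dim)),
            class = "graph_config")
}

#' Voxel-downsample a point cloud
#'
#' Space is partitioned into axis-aligned cubes of edge `voxel_size` anchored
#' at the origin. From each occupied voxel the original point nearest the
#' centroid of that voxel's points is selected (ties broken by lowest index).
#' Selected points keep their original coordinates.
#'
#' @param cloud A [surface_cloud()] (or plain coordinate matrix).
#' @param voxel_size Cube edge in Angstrom.
#' @return Integer vector of selected point indices, ascending.
#' @export
voxel_downsample <- function(cloud, voxel_size) {
  stopifnot(voxel_size > 0)
  X <- if (inherits(cloud, "surface_cloud")) cloud$coords else as.matrix(cloud)
  vox <- floor(X / voxel_size)
  key <- paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")
  sel <- vapply(split(seq_len(nrow(X)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    ctr <- colMeans(X[idx, , drop = FALSE])
    d2 <- (X[idx, 1] - ctr[1])^2 + (X[idx, 2] - ctr[2])^2 + (X[idx, 3] - ctr[3])^2
    # lowest index among (near-)ties: two-point voxels are exactly tied by
    # construction, and the tolerance keeps the choice stable under the
    # floating-point noise of translated coordinates
    idx[which(d2 <= min(d2) + 1e-9)[1]]
  }, integer(1))
  sort(unname(sel))
}

#' Fixed-radius directed edge list
#'
#' Directed edges (i, j), j != i, for all pairs with Euclidean distance
#' strictly below `r`. When a vertex has more than `max_edges` in-range
#' neighbors, only the `max_edges` nearest are kept (ties by lower index).
#'
#' @param vertex_coords M x 3 coordinate matrix.
#' @param r Edge radius in Angstrom.
#' @param max_edges Maximum out-degree.
#' @return Integer matrix with columns `i`, `j`, sorted by (i, j), plus a
#'   `dist` attribute-free third column of distances.
#' @export
build_radius_graph <- function(vertex_coords, r, max_edges = 32L) {
  X <- as.matrix(vertex_coords)
  m <- nrow(X)
  if (m < 1L) stop("build_radius_graph: empty vertex set", call. = FALSE)
  res_i <- vector("list", m)
  block <- max(1L, floor(2e7 / m))
  for (b in seq(1L, m, by = block)) {
    idx <- b:min(m, b + block - 1L)
    D2 <- pairwise_dist2(X[idx, , drop = FALSE], X)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      d2 <- D2[ii, ]
      d2[i] <- Inf
      nb <- which(d2 < r^2)
      if (length(nb) == 0L) next
      if (length(nb) > max_edges) {
        nb <- nb[order(d2[nb], nb)][seq_len(max_edges)]
      }
      nb <- sort(nb)
      res_i[[i]] <- cbind(i = rep.int(i, length(nb)), j = nb,
                          dist = sqrt(pmax(d2[nb], 0)))
    }
  }
  out <- do.call(rbind, res_i)
  if (is.null(out)) out <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "dist")))
  out
}

# Aggregation geometry cache: pairs (vertex, original point within r0),
# self always included; relative coordinates point - vertex.
aggregate_precompute <- function(cloud, selected, r0) {
  X <- cloud$coords
  V <- X[selected, , drop = FALSE]
  m <- nrow(V)
  pairs_v <- vector("list", m)
  for (v in seq_len(m)) {
    d2 <- (X[, 1] - V[v, 1])^2 + (X[, 2] - V[v, 2])^2 + (X[, 3] - V[v, 3])^2
    nb <- which(d2 <= r0^2 + 1e-12)
    if (!(selected[v] %in% nb)) nb <- c(nb, selected[v])
    pairs_v[[v]] <- cbind(vertex = rep.int(v, length(nb)), point = nb)
  }
  pairs <- do.call(rbind, pairs_v)
  rel <- X[pairs[, "point"], , drop = FALSE] - V[pairs[, "vertex"], , drop = FALSE]
  rows_by_vertex <- split(seq_len(nrow(pairs)),
                          factor(pairs[, "vertex"], levels = seq_len(m)))
  list(pairs = pairs, rel = rel, rows_by_vertex = rows_by_vertex, m = m,
       slots = group_slots(rows_by_vertex))
}

# Ragged groups as an NA-padded slot matrix (one row per group); grouped
# column-wise max then reduces over at most max-degree vectorized pmax steps.
group_slots <- function(rows_by_group) {
  sizes <- lengths(rows_by_group)
  if (length(sizes) == 0L || max(sizes) == 0L) {
    return(matrix(NA_integer_, length(sizes), 0L))
  }
  G <- matrix(NA_integer_, length(sizes), max(sizes))
  for (g in seq_along(rows_by_group)) {
    if (sizes[g] > 0L) G[g, seq_len(sizes[g])] <- rows_by_group[[g]]
  }
  G
}

# Column-wise max of E within row groups given a slot matrix; returns the
# max matrix and (optionally) the argmax row of E per (group, column).
grouped_max <- function(E, slots, want_argmax = FALSE) {
  ng <- nrow(slots)
  D <- ncol(E)
  A <- matrix(-Inf, ng, D)
  AM <- if (want_argmax) matrix(0L, ng, D) else NULL
  for (s in seq_len(ncol(slots))) {
    rows <- slots[, s]
    valid <- which(!is.na(rows))
    if (length(valid) == 0L) next
    Es <- E[rows[valid], , drop = FALSE]
    cur <- A[valid, , drop = FALSE]
    upd <- Es > cur
    cur[upd] <- Es[upd]
    A[valid, ] <- cur
    if (want_argmax) {
      am <- AM[valid, , drop = FALSE]
      src <- matrix(rows[valid], length(valid), D)
      am[upd] <- src[upd]
      AM[valid, ] <- am
    }
  }
  list(max = A, argmax = AM)
}

# Scatter of grouped-max gradients back to E rows. (argmax row, column)
# pairs are unique across groups because each row belongs to one group.
grouped_max_backward <- function(dA, argmax, n_rows) {
  D <- ncol(dA)
  dE <- matrix(0, n_rows, D)
  ix <- cbind(as.vector(argmax), rep(seq_len(D), each = nrow(dA)))
  dE[ix] <- as.vector(dA)
  dE
}

# Forward: embed [features(16) + relative coords(3)] of each in-range point
# with the 2-layer MLP, elementwise Max per vertex.
aggregate_forward <- function(embed_net, feats, agg, cache = FALSE) {
  Xin <- cbind(feats[agg$pairs[, "point"], , drop = FALSE], agg$rel)
  fw <- mlp_forward(embed_net, Xin, cache = cache)
  E <- if (cache) fw$out else fw
  gm <- grouped_max(E, agg$slots, want_argmax = cache)
  states <- gm$max
  if (cache) list(states = states, mlp_cache = fw, argmax = gm$argmax,
                  n_rows = nrow(Xin))
  else states
}

aggregate_backward <- function(embed_net, agg, fcache, dStates, n_feat_cols) {
  dE <- grouped_max_backward(dStates, fcache$argmax, fcache$n_rows)
  bw <- mlp_backward(embed_net, fcache$mlp_cache, dE)
  dXin <- bw$dX
  dFeats_rows <- dXin[, seq_len(n_feat_cols), drop = FALSE]
  dFeats <- rowsum(dFeats_rows, agg$pairs[, "point"], reorder = FALSE)
  pts <- as.integer(rownames(dFeats))
  list(grads = bw$grads, dFeats = dFeats, dFeats_points = pts)
}

#' Aggregate dense-point features into vertex initial states
#'
#' For each selected vertex, all original points within `r0` (the vertex
#' itself always included) are embedded as `MLP([features, x_point - x_vertex])`
#' and reduced by an elementwise Max into the vertex's initial state.
#'
#' @param cloud A featurized [surface_cloud()].
#' @param selected Vertex indices from [voxel_downsample()].
#' @param r0 Aggregation radius in Angstrom.
#' @param embed_net 2-layer MLP parameters (19 -> state_dim -> state_dim),
#'   e.g. from `init_mlp(c(19, 300, 300))` inside [init_model()].
#' @return M x state_dim matrix of initial vertex states.
#' @export
aggregate_initial_states <- function(cloud, selected, r0, embed_net) {
  agg <- aggregate_precompute(cloud, selected, r0)
  aggregate_forward(embed_net, full_features(cloud), agg)
}

#' Assemble a point graph from a featurized cloud
#'
#' Runs [voxel_downsample()], [build_radius_graph()] and records provenance.
#' Vertex states are attached later by the model (they depend on trainable
#' weights). Vertex labels are the representative points' own labels.
#'
#' @param cloud A featurized, optionally labeled [surface_cloud()].
#' @param config A [graph_config()].
#' @param downsample If `FALSE`, every point becomes a vertex (full-point
#'   configuration).
#' @param aggregate If `FALSE`, each vertex aggregates only itself
#'   (downsampling-without-aggregation configuration).
#' @return Object of class `point_graph`.
#' @export
build_point_graph <- function(cloud, config = graph_config(),
                              downsample = TRUE, aggregate = TRUE) {
  selected <- if (downsample) voxel_downsample(cloud, config$voxel_size)
              else seq_len(nrow(cloud$coords))
  V <- cloud$coords[selected, , drop = FALSE]
  edges <- build_radius_graph(V, config$r, config$max_edges)
  agg <- aggregate_precompute(cloud, selected,
                              if (aggregate) config$r0 else 0)
  structure(list(
    vertex_coords = V,
    selected = selected,
    edges = edges,
    agg = agg,
    vertex_labels = if (is.null(cloud$labels)) NULL else cloud$labels[selected],
    r = config$r, r0 = if (aggregate) config$r0 else 0,
    n_points = nrow(cloud$coords)
  ), class = "point_graph")
}

#' @export
print.point_graph <- function(x, ...) {
  cat(sprintf("<point_graph> %d vertices (from %d points), %d directed edges, r=%g r0=%g\n",
              nrow(x$vertex_coords), x$n_points, nrow(x$edges), x$r, x$r0))
  invisible(x)
}
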