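# OPTICS density clustering (ordering + reachability, with xi and
# DBSCAN-style eps-cut extraction). Implemented in-package; the ordering and
# reachability follow the classic algorithm with the min_samples convention
# that the query point counts among its own neighbors (so the core distance
# is the distance to the (min_samples-1)-th other point).

#' OPTICS ordering and reachability
#'
#' @param coords n x d coordinate matrix.
#' @param min_samples Neighborhood size for core distances (point itself
#'   counts), default 5.
#' @param max_eps Maximum neighborhood radius in coordinate units; `Inf`
#'   disables the cutoff.
#' @return List with `order` (visit order, original indices), `reachability`
#'   and `core_dist` (per original index; `Inf` where undefined).
#' @export
optics_order <- function(coords, min_samples = 5L, max_eps = Inf) {
  X <- as.matrix(coords)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  core <- unname(apply(D, 1L, function(d) sort(d)[min(min_samples, n)]))
  core[core > max_eps] <- Inf
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ord <- integer(n)
  for (step in seq_len(n)) {
    un <- which(!processed)
    p <- un[which.min(reach[un])]  # all-Inf -> lowest index
    processed[p] <- TRUE
    ord[step] <- p
    if (is.finite(core[p])) {
      nb <- which(!processed & D[p, ] <= max_eps)
      if (length(nb) > 0L) {
        reach[nb] <- pmin(reach[nb], pmax(core[p], D[p, nb]))
      }
    }
  }
  # reachability of the first point of each component is undefined (Inf)
  reach[ord[1]] <- Inf
  list(order = ord, reachability = reach, core_dist = core)
}

# DBSCAN-equivalent cluster extraction at a fixed eps over the ordering.
extract_eps <- function(opt, eps) {
  ord <- opt$order
  r <- opt$reachability[ord]
  cd <- opt$core_dist[ord]
  labels <- rep(-1L, length(ord))
  cur <- 0L
  lab_ord <- rep(-1L, length(ord))
  for (k in seq_along(ord)) {
    if (r[k] > eps) {
      if (cd[k] <= eps) {
        cur <- cur + 1L
        lab_ord[k] <- cur
      } else lab_ord[k] <- -1L
    } else lab_ord[k] <- cur
  }
  labels[ord] <- lab_ord
  labels
}

# extend a steep region, tolerating up to min_samples consecutive
# non-steep points that do not move in the opposite direction
extend_region <- function(steep, opposite, start, min_samples) {
  n <- length(steep)
  non_steep <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep[index]) {
      end <- index
      non_steep <- 0L
    } else if (!opposite[index]) {
      non_steep <- non_steep + 1L
      if (non_steep > min_samples) break
    } else break
    index <- index + 1L
  }
  end
}

# xi-method cluster extraction over the reachability plot (steep-area
# algorithm; no predecessor correction, boundaries may include a border
# point that the corrected variant would trim).
extract_xi <- function(opt, xi = 0.05, min_samples = 5L,
                       min_cluster_size = min_samples) {
  ord <- opt$order
  n <- length(ord)
  r <- c(opt$reachability[ord], Inf)
  xic <- 1 - xi
  ratio <- r[seq_len(n)] / r[seq_len(n) + 1L]
  ratio[is.nan(ratio)] <- 1  # Inf/Inf plateaus
  steep_up <- ratio <= xic
  steep_down <- ratio >= 1 / xic
  up <- ratio < 1
  down <- ratio > 1
  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- -Inf
  filter_sdas <- function(sdas, mib) {
    keep <- Filter(function(s) r[s$start] * xic >= mib, sdas)
    lapply(keep, function(s) { s$mib <- max(s$mib, mib); s })
  }
  while (index <= n) {
    mib <- max(mib, r[index])
    if (steep_down[index]) {
      sdas <- filter_sdas(sdas, mib)
      d_start <- index
      d_end <- extend_region(steep_down, up, index, min_samples)
      sdas[[length(sdas) + 1L]] <- list(start = d_start, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- r[index]
    } else if (steep_up[index]) {
      sdas <- filter_sdas(sdas, mib)
      u_start <- index
      u_end <- extend_region(steep_up, down, index, min_samples)
      index <- u_end + 1L
      mib <- r[index]
      u_clusters <- list()
      for (s in sdas) {
        c_start <- s$start
        c_end <- u_end
        if (r[u_end + 1L] * xic < s$mib) next
        d_max <- r[s$start]
        if (d_max * xic >= r[u_end + 1L]) {
          while (c_start < s$end && r[c_start + 1L] > r[u_end + 1L]) {
            c_start <- c_start + 1L
          }
        } else if (r[u_end + 1L] * xic >= d_max) {
          while (c_end > u_start && r[c_end] > d_max) c_end <- c_end - 1L
        }
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > s$end) next
        if (c_end < u_start) next
        u_clusters[[length(u_clusters) + 1L]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters))
    } else {
      index <- index + 1L
    }
  }
  labels <- rep(-1L, n)
  cur <- 0L
  for (cl in clusters) {
    rng <- cl[1]:cl[2]
    if (all(labels[rng] == -1L)) {
      cur <- cur + 1L
      labels[rng] <- cur
    }
  }
  out <- rep(-1L, n)
  out[ord] <- labels
  out
}

#' OPTICS cluster labels
#'
#' @param coords n x d coordinates.
#' @param min_samples Core-distance neighborhood size (default 5).
#' @param max_eps Maximum neighborhood radius (default 6 Angstrom for pocket
#'   vertices).
#' @param method `"eps"` (default) for a DBSCAN-equivalent cut of the
#'   reachability plot, or `"xi"` for steep-area extraction. Pocket point
#'   sets are compact near-uniform patches, for which the eps cut keeps the
#'   whole patch; xi extraction targets nested variable-density structure
#'   and tends to trim such patches.
#' @param xi Steepness parameter for `method = "xi"` (default 0.05).
#' @param eps Cut level for `method = "eps"`; defaults to `max_eps / 2`.
#' @return Integer labels, 1..k for clusters and -1 for noise.
#' @export
optics_cluster <- function(coords, min_samples = 5L, max_eps = 6,
                           method = c("eps", "xi"), xi = 0.05, eps = NULL) {
  method <- match.arg(method)
  X <- as.matrix(coords)
  if (nrow(X) < min_samples) return(rep(-1L, nrow(X)))
  opt <- optics_order(X, min_samples, max_eps)
  if (method == "xi") {
    extract_xi(opt, xi, min_samples)
  } else {
    extract_eps(opt, if (is.null(eps)) max_eps / 2 else eps)
  }
}
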