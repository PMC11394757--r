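# From per-vertex probabilities to ranked pockets: strict 0.5 threshold,
# OPTICS clustering of the positive vertices, probability-sum ranking.

#' Indices of predicted-positive vertices
#'
#' Strictly-greater-than comparison: a probability equal to the threshold is
#' negative.
#'
#' @param probs Vertex probabilities in (0, 1).
#' @param threshold Decision threshold (default 0.5).
#' @return Integer indices (possibly empty).
#' @export
threshold_points <- function(probs, threshold = 0.5) {
  which(probs > threshold)
}

#' Cluster positive vertices into ranked pockets
#'
#' OPTICS over the 3-D coordinates of predicted-positive vertices; noise
#' points are discarded; each cluster becomes a pocket whose score is the sum
#' of its member probabilities and whose center is the unweighted mean of its
#' member coordinates. Pockets are ranked by score, descending.
#'
#' @param coords Coordinates of the positive vertices (n x 3).
#' @param probs Matching probabilities.
#' @param min_samples,max_eps,method,xi,eps Passed to [optics_cluster()].
#' @param weighted_center Use probability-weighted centers instead of the
#'   unweighted mean (default `FALSE`).
#' @return List of `pocket_cluster` objects, in rank order (possibly empty).
#' @export
cluster_pockets <- function(coords, probs, min_samples = 5L, max_eps = 6,
                            method = "eps", xi = 0.05, eps = NULL,
                            weighted_center = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(probs))
  if (nrow(coords) == 0L) return(list())
  labels <- optics_cluster(coords, min_samples, max_eps, method, xi, eps)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(list())
  pockets <- lapply(ids, function(id) {
    mem <- which(labels == id)
    w <- probs[mem]
    ctr <- if (weighted_center) colSums(coords[mem, , drop = FALSE] * w) / sum(w)
           else colMeans(coords[mem, , drop = FALSE])
    ctr <- unname(ctr)
    structure(list(member_indices = mem, member_probs = w, score = sum(w),
                   center = ctr, rank = NA_integer_),
              class = "pocket_cluster")
  })
  ord <- order(vapply(pockets, `[[`, numeric(1), "score"), decreasing = TRUE)
  pockets <- pockets[ord]
  for (k in seq_along(pockets)) pockets[[k]]$rank <- k
  pockets
}

#' @export
print.pocket_cluster <- function(x, ...) {
  cat(sprintf("<pocket_cluster> rank %s: %d points, score %.2f, center (%.2f, %.2f, %.2f)\n",
              ifelse(is.na(x$rank), "?", x$rank), length(x$member_indices),
              x$score, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Keep the top-n ranked pockets
#'
#' Evaluation uses the structure's known site count as the rank cutoff. A
#' shortfall (fewer pockets than sites) feeds the count of sites with no
#' prediction.
#'
#' @param pockets Ranked pockets from [cluster_pockets()].
#' @param n Known binding-site count (>= 1).
#' @return List with `pockets` (first `min(n, length)`) and `shortfall`.
#' @export
select_top_n <- function(pockets, n) {
  stopifnot(n >= 1)
  keep <- pockets[seq_len(min(n, length(pockets)))]
  list(pockets = keep,
       shortfall = max(0L, as.integer(n) - length(pockets)))
}

#' Tabulate pockets
#'
#' @param pockets List of pockets.
#' @return data.frame: rank, score, n_points, cx, cy, cz.
#' @export
pockets_to_df <- function(pockets) {
  if (length(pockets) == 0L) {
    return(data.frame(rank = integer(0), score = numeric(0),
                      n_points = integer(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0)))
  }
  df <- do.call(rbind, lapply(pockets, function(p) {
    data.frame(rank = p$rank, score = p$score,
               n_points = length(p$member_indices),
               cx = p$center[1], cy = p$center[2], cz = p$center[3])
  }))
  rownames(df) <- NULL
  df
}

#' Write pocket member points as pseudo-atoms for visualization
#'
#' HETATM records, residue name `PCK`, one residue per pocket.
#'
#' @param pockets List of pockets.
#' @param coords The vertex coordinate matrix the member indices refer to.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_pockets_pdb <- function(pockets, coords, path) {
  fmt <- "HETATM%5d  C   PCK P%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C"
  lines <- character(0)
  serial <- 0L
  for (p in pockets) {
    for (ix in p$member_indices) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(fmt, serial %% 100000L, p$rank %% 10000L,
                                coords[ix, 1], coords[ix, 2], coords[ix, 3],
                                1, mean(p$member_probs)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
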