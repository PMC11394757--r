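# Pocket-level evaluation: center-center distance (DCC), success rate,
# discretized volume overlap (DVO), and pocket-level precision/recall/F1.
# A prediction is correct when DCC <= 4 Angstrom (inclusive). TP/FP count
# matched predictions by that rule; FN counts sites with no prediction.

#' Center-center distance (DCC)
#'
#' @param pred_center,true_center Length-3 coordinates in Angstrom.
#' @return Euclidean distance in Angstrom.
#' @export
compute_dcc <- function(pred_center, true_center) {
  stopifnot(length(pred_center) == 3L, length(true_center) == 3L,
            all(is.finite(pred_center)), all(is.finite(true_center)))
  sqrt(sum((as.numeric(pred_center) - as.numeric(true_center))^2))
}

#' Greedy matching of predicted pockets to true sites
#'
#' Site/pocket pairs are assigned globally nearest-first: repeatedly match
#' the remaining (site, pocket) pair with the smallest DCC until sites or
#' pockets run out. Each pocket is used at most once; unmatched sites get
#' `dcc = NA` ("missing").
#'
#' @param pockets Top-n pockets (list; may be empty).
#' @param sites List of [ligand_site()].
#' @param structure_id Identifier recorded in the output.
#' @return data.frame with one row per site: structure_id, site_id, dcc,
#'   matched_rank (NA when missing), dvo (NA, filled by [compute_dvo()]
#'   workflows).
#' @export
match_sites <- function(pockets, sites, structure_id = "structure") {
  ns <- length(sites)
  stopifnot(ns >= 1L)
  np <- length(pockets)
  dcc <- rep(NA_real_, ns)
  matched <- rep(NA_integer_, ns)
  if (np > 0L) {
    D <- matrix(Inf, ns, np)
    for (s in seq_len(ns)) {
      for (p in seq_len(np)) {
        D[s, p] <- compute_dcc(pockets[[p]]$center, sites[[s]]$center)
      }
    }
    for (k in seq_len(min(ns, np))) {
      ix <- arrayInd(which.min(D), dim(D))
      s <- ix[1]; p <- ix[2]
      dcc[s] <- D[s, p]
      matched[s] <- pockets[[p]]$rank
      D[s, ] <- Inf
      D[, p] <- Inf
    }
  }
  data.frame(
    structure_id = structure_id,
    site_id = vapply(sites, `[[`, character(1), "ligand_id"),
    dcc = dcc, matched_rank = matched, dvo = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Discretized volume overlap (DVO)
#'
#' Both point sets are voxelized on an origin-anchored grid of edge `voxel`;
#' DVO is the Jaccard ratio of occupied-voxel sets.
#'
#' @param pred_points Predicted pocket member coordinates (n x 3).
#' @param true_points Surface coordinates labeled positive for the site
#'   (m x 3).
#' @param voxel Grid edge in Angstrom (default 2).
#' @return Fraction in `[0, 1]`, or `NA` if either set is empty.
#' @export
compute_dvo <- function(pred_points, true_points, voxel = 2) {
  if (is.null(pred_points) || is.null(true_points) ||
      NROW(pred_points) == 0L || NROW(true_points) == 0L) return(NA_real_)
  vox_key <- function(P) {
    v <- floor(as.matrix(P) / voxel)
    unique(paste(v[, 1], v[, 2], v[, 3], sep = ","))
  }
  a <- vox_key(pred_points)
  b <- vox_key(true_points)
  length(intersect(a, b)) / length(union(a, b))
}

#' Dataset-level evaluation summary
#'
#' TP: matched predictions with DCC <= threshold (inclusive). FP: matched
#' predictions with DCC > threshold. FN: sites with no prediction.
#' success rate = correct sites / total sites; F1 is the harmonic mean of
#' precision and recall; mean DVO averages sites where DVO is defined.
#'
#' @param records data.frame from [match_sites()] rows (possibly several
#'   structures bound together).
#' @param dcc_threshold Success cutoff in Angstrom (default 4, inclusive).
#' @return List of class `eval_summary`.
#' @export
summarize_eval <- function(records, dcc_threshold = 4) {
  stopifnot(nrow(records) >= 1L)
  matched <- !is.na(records$dcc)
  tp <- sum(matched & records$dcc <= dcc_threshold)
  fp <- sum(matched & records$dcc > dcc_threshold)
  fn <- sum(!matched)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  dvo_ok <- !is.na(records$dvo)
  structure(list(
    n_sites = nrow(records),
    n_correct = tp,
    n_missing = fn,
    TP = tp, FP = fp, FN = fn,
    precision = precision, recall = recall, f1 = f1,
    success_rate = tp / nrow(records),
    mean_dvo = if (any(dvo_ok)) mean(records$dvo[dvo_ok]) else NA_real_
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(paste0("<eval_summary> %d sites: success rate %.3f ",
                     "(TP %d / FP %d / FN %d), precision %.3f, recall %.3f, ",
                     "F1 %.3f, mean DVO %s\n"),
              x$n_sites, x$success_rate, x$TP, x$FP, x$FN, x$precision,
              x$recall, x$f1,
              ifelse(is.na(x$mean_dvo), "-", sprintf("%.3f", x$mean_dvo))))
  invisible(x)
}

#' Success rate as a function of the DCC threshold
#'
#' @param records Records as for [summarize_eval()].
#' @param thresholds Ascending numeric thresholds in Angstrom.
#' @return data.frame (threshold, rate); non-decreasing in threshold.
#' @export
success_curve <- function(records, thresholds) {
  if (length(thresholds) == 0L) {
    return(data.frame(threshold = numeric(0), rate = numeric(0)))
  }
  stopifnot(!is.unsorted(thresholds))
  rate <- vapply(thresholds, function(th) {
    sum(!is.na(records$dcc) & records$dcc <= th) / nrow(records)
  }, numeric(1))
  data.frame(threshold = thresholds, rate = rate)
}
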