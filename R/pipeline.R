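# End-to-end wiring: structure -> featurized surface -> graph -> model ->
# pockets -> evaluation, plus the structured pipeline configuration used by
# the command-line interface.

#' Default pipeline configuration
#'
#' Nested blocks: `surface` (probe radius, target point density, curvature
#' scales), `graph` ([graph_config()] fields), `model` (dimensions),
#' `train` ([train_config()] fields), `inference` (threshold + OPTICS
#' parameters), `evaluation` (DCC threshold, DVO voxel).
#'
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    surface = list(probe_radius = 1.5, target_density = 1.0,
                   scales = c(1.0, 2.0, 3.5, 6.0, 10.0), k_chem = 16L,
                   label_threshold = 4),
    graph = list(voxel_size = 1.0, r0 = 2.0, r = 4.0, max_edges = 32L,
                 state_dim = 300L),
    model = list(n_layers = 3L, offset_hidden = 64L, clf_hidden = c(128L, 64L)),
    train = list(batch_size = 4L, lr = 5e-4, weight_decay = 1e-5,
                 max_epochs = 50L, seed = 1L, pos_weight = "auto",
                 early_stop_patience = 10L),
    inference = list(threshold = 0.5, min_samples = 5L, max_eps = 6,
                     method = "eps", xi = 0.05, eps = 3.0),
    evaluation = list(dcc_threshold = 4, dvo_voxel = 2)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration against the defaults
#'
#' Unknown keys are rejected; missing keys inherit defaults.
#'
#' @param cfg Nested list (e.g. parsed from YAML).
#' @return Completed `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  def <- pipeline_config()
  if (is.null(cfg)) return(def)
  for (blk in names(cfg)) {
    if (!blk %in% names(def)) {
      stop("validate_config: unknown configuration block '", blk, "'", call. = FALSE)
    }
    for (key in names(cfg[[blk]])) {
      if (!key %in% names(def[[blk]])) {
        stop("validate_config: unknown key '", blk, ".", key, "'", call. = FALSE)
      }
      def[[blk]][[key]] <- cfg[[blk]][[key]]
    }
  }
  graph_config(def$graph$voxel_size, def$graph$r0, def$graph$r,
               def$graph$max_edges, def$graph$state_dim)  # validates radii
  def
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return `read_config()` the validated config; `write_config()` the path.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Prepare a structure for the model
#'
#' Samples the solvent-accessible surface, computes curvature features and
#' (given sites) binary labels, and builds the downsampled point graph with
#' its fixed geometry caches. Chemical features are evaluated inside the
#' model forward pass because their network is trainable.
#'
#' @param atoms An [atom_set()].
#' @param sites Optional list of [ligand_site()] for labeling/evaluation.
#' @param config A `pipeline_config` (see [pipeline_config()]).
#' @param downsample,aggregate Configuration ablations; see
#'   [build_point_graph()].
#' @param id Structure identifier carried through evaluation.
#' @return A prepared structure (list with `cloud`, `graph`, caches, `sites`).
#' @export
prepare_structure <- function(atoms, sites = NULL, config = pipeline_config(),
                              downsample = TRUE, aggregate = TRUE,
                              id = "structure") {
  config <- validate_config(config)
  cloud <- sample_surface(atoms, config$surface$probe_radius,
                          config$surface$target_density)
  cloud$geom_feat <- compute_curvature_features(
    cloud, curvature_scales(config$surface$scales))
  if (!is.null(sites) && length(sites) > 0L) {
    cloud$labels <- label_points(cloud, sites, config$surface$label_threshold)
  }
  gcfg <- graph_config(config$graph$voxel_size, config$graph$r0, config$graph$r,
                       config$graph$max_edges, config$graph$state_dim)
  prep <- prepare_graph_input(cloud, atoms, gcfg, config$surface$k_chem,
                              downsample = downsample, aggregate = aggregate)
  prep$cloud <- cloud
  prep$sites <- sites
  prep$id <- id
  prep
}

#' Predict ranked pockets for a prepared structure
#'
#' @param model A trained `pgnn_model`.
#' @param prep Output of [prepare_structure()].
#' @param config A `pipeline_config` (inference block is used).
#' @return List with `pockets` (ranked), `probs` (per-vertex) and
#'   `positive_idx`.
#' @export
predict_pockets <- function(model, prep, config = pipeline_config()) {
  config <- validate_config(config)
  probs <- predict_vertices(model, prep)
  pos <- threshold_points(probs, config$inference$threshold)
  pockets <- cluster_pockets(prep$graph$vertex_coords[pos, , drop = FALSE],
                             probs[pos],
                             min_samples = config$inference$min_samples,
                             max_eps = config$inference$max_eps,
                             method = config$inference$method,
                             xi = config$inference$xi,
                             eps = config$inference$eps)
  # member indices refer to positive-vertex rows; remap to vertex indices
  for (k in seq_along(pockets)) {
    pockets[[k]]$member_indices <- pos[pockets[[k]]$member_indices]
  }
  list(pockets = pockets, probs = probs, positive_idx = pos)
}

#' Evaluate predicted pockets against a structure's true sites
#'
#' Applies the top-n rule (n = number of known sites), greedy matching, DCC
#' and per-site DVO (predicted pocket member vertices vs the surface points
#' labeled positive for that site).
#'
#' @param pockets Ranked pockets from [predict_pockets()].
#' @param prep Prepared structure with `sites` and a labeled cloud.
#' @param config A `pipeline_config` (evaluation block is used).
#' @return data.frame of per-site records (structure_id, site_id, dcc,
#'   matched_rank, dvo).
#' @export
evaluate_structure <- function(pockets, prep, config = pipeline_config()) {
  config <- validate_config(config)
  sites <- prep$sites
  stopifnot(length(sites) >= 1L)
  top <- select_top_n(pockets, length(sites))
  rec <- match_sites(top$pockets, sites, structure_id = prep$id)
  for (s in seq_along(sites)) {
    if (is.na(rec$matched_rank[s])) next
    pk <- top$pockets[[which(vapply(top$pockets, `[[`, integer(1), "rank") ==
                               rec$matched_rank[s])]]
    d2 <- colSums((t(prep$cloud$coords) - sites[[s]]$center)^2)
    true_pts <- prep$cloud$coords[d2 <= config$surface$label_threshold^2, , drop = FALSE]
    rec$dvo[s] <- compute_dvo(
      prep$graph$vertex_coords[pk$member_indices, , drop = FALSE],
      true_pts, voxel = config$evaluation$dvo_voxel)
  }
  rec
}

#' Evaluate a model over a list of prepared structures
#'
#' @param model Trained model.
#' @param preps List of prepared structures with sites.
#' @param config A `pipeline_config`.
#' @return List with `records` (bound per-site rows), `summary`
#'   ([summarize_eval()]) and `vertex_auc` (per-vertex AUROC pooled over
#'   structures).
#' @export
evaluate_dataset <- function(model, preps, config = pipeline_config()) {
  config <- validate_config(config)
  records <- list()
  probs_all <- labels_all <- numeric(0)
  for (p in preps) {
    pr <- predict_pockets(model, p, config)
    records[[length(records) + 1L]] <- evaluate_structure(pr$pockets, p, config)
    if (!is.null(p$labels)) {
      probs_all <- c(probs_all, pr$probs)
      labels_all <- c(labels_all, p$labels)
    }
  }
  records <- do.call(rbind, records)
  list(records = records,
       summary = summarize_eval(records, config$evaluation$dcc_threshold),
       vertex_auc = auroc(probs_all, labels_all))
}
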