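# Oriented surface point cloud: solvent-accessible surface (SAS) sampling.

#' Construct a surface point cloud
#'
#' @param coords N x 3 point coordinates (Angstrom).
#' @param normals N x 3 outward unit normals.
#' @param chem_feat Optional N x 6 chemical features.
#' @param geom_feat Optional N x 10 geometric (curvature) features.
#' @param labels Optional length-N binary (0/1) binding-site labels.
#' @param owner Optional integer: index of the atom whose inflated sphere
#'   carries each point (kept for diagnostics).
#' @return Object of class `surface_cloud`.
#' @export
surface_cloud <- function(coords, normals, chem_feat = NULL, geom_feat = NULL,
                          labels = NULL, owner = NULL) {
  coords <- as.matrix(coords); normals <- as.matrix(normals)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            identical(dim(coords), dim(normals)))
  if (!all(is.finite(coords)) || !all(is.finite(normals))) {
    stop("surface_cloud: non-finite values", call. = FALSE)
  }
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) stop("surface_cloud: normals must be unit length", call. = FALSE)
  if (!is.null(chem_feat)) stopifnot(nrow(chem_feat) == nrow(coords), ncol(chem_feat) == 6L)
  if (!is.null(geom_feat)) stopifnot(nrow(geom_feat) == nrow(coords), ncol(geom_feat) == 10L)
  if (!is.null(labels)) stopifnot(length(labels) == nrow(coords), all(labels %in% c(0, 1)))
  structure(list(coords = coords, normals = normals, chem_feat = chem_feat,
                 geom_feat = geom_feat, labels = labels, owner = owner),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("<surface_cloud> %d points; chem:%s geom:%s labels:%s\n",
              nrow(x$coords),
              if (is.null(x$chem_feat)) "-" else "6",
              if (is.null(x$geom_feat)) "-" else "10",
              if (is.null(x$labels)) "-" else sprintf("%.3f+", mean(x$labels))))
  invisible(x)
}

#' Full 16-dimensional per-point feature matrix
#'
#' Chemical features (6) first, then geometric features (10).
#'
#' @param cloud A [surface_cloud()] with both feature blocks set.
#' @return N x 16 numeric matrix.
#' @export
full_features <- function(cloud) {
  if (is.null(cloud$chem_feat) || is.null(cloud$geom_feat)) {
    stop("full_features: chemical and geometric features must both be computed",
         call. = FALSE)
  }
  cbind(cloud$chem_feat, cloud$geom_feat)
}

# Deterministic near-uniform sphere covering (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) + 1) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Sample the solvent-accessible surface of a structure as an oriented cloud
#'
#' Each atom's van der Waals sphere is inflated by the probe radius and
#' covered with a near-uniform deterministic point lattice; points falling
#' strictly inside any other atom's inflated sphere are rejected. Normals
#' point away from the owning atom's center (outward for a convex body).
#'
#' @param atoms An [atom_set()]; only protein atoms contribute surface.
#' @param probe_radius Probe (solvent) radius in Angstrom; default 1.5.
#' @param target_density Requested points per square Angstrom of sphere area;
#'   default 1.0. The realized density of kept points is within a factor ~2.
#' @return A [surface_cloud()] with empty feature blocks.
#' @export
sample_surface <- function(atoms, probe_radius = 1.5, target_density = 1.0) {
  keep <- atoms$is_protein
  if (!any(keep)) stop("sample_surface: no protein atoms", call. = FALSE)
  centers <- atoms$coords[keep, , drop = FALSE]
  radii <- vdw_radius(atoms$elements[keep]) + probe_radius
  na <- nrow(centers)

  # atom-atom adjacency for rejection tests
  maxr <- max(radii)
  all_pts <- vector("list", na)
  all_nrm <- vector("list", na)
  all_own <- vector("list", na)
  for (i in seq_len(na)) {
    ri <- radii[i]
    npts <- max(8L, ceiling(4 * pi * ri^2 * target_density))
    sph <- fibonacci_sphere(npts)
    pts <- sweep(sph * ri, 2, centers[i, ], "+")
    # neighbors whose inflated sphere can swallow these points
    d2 <- colSums((t(centers) - centers[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(na) != i)
    ok <- rep(TRUE, npts)
    for (j in nb) {
      dj2 <- colSums((t(pts) - centers[j, ])^2)
      # boundary ties (coincident spheres) are owned by the lower-index atom
      thr <- if (j < i) (radii[j] + 1e-9)^2 else (radii[j] - 1e-9)^2
      ok <- ok & dj2 >= thr
      if (!any(ok)) break
    }
    if (any(ok)) {
      all_pts[[i]] <- pts[ok, , drop = FALSE]
      all_nrm[[i]] <- sph[ok, , drop = FALSE]
      all_own[[i]] <- rep(which(keep)[i], sum(ok))
    }
  }
  coords <- do.call(rbind, all_pts)
  if (is.null(coords) || nrow(coords) == 0L) {
    stop("sample_surface: no surface points survive (degenerate input)", call. = FALSE)
  }
  surface_cloud(coords, do.call(rbind, all_nrm), owner = unlist(all_own))
}

#' Binary binding-site labels for surface points
#'
#' A point is positive iff it lies within `threshold` Angstrom of the
#' geometric center of any ligand site.
#'
#' @param cloud A [surface_cloud()].
#' @param sites List of [ligand_site()]; must be non-empty.
#' @param threshold Distance cutoff in Angstrom (default 4).
#' @param use_atom_distance If `TRUE`, measure distance to the nearest ligand
#'   heavy atom instead of the site center.
#' @return Integer vector of 0/1 labels (also attached to the returned cloud
#'   when assigned by the caller).
#' @export
label_points <- function(cloud, sites, threshold = 4, use_atom_distance = FALSE) {
  stopifnot(length(sites) >= 1L)
  n <- nrow(cloud$coords)
  lab <- rep(0L, n)
  for (s in sites) {
    ref <- if (use_atom_distance) s$atom_coords else matrix(s$center, ncol = 3)
    for (k in seq_len(nrow(ref))) {
      d2 <- (cloud$coords[, 1] - ref[k, 1])^2 + (cloud$coords[, 2] - ref[k, 2])^2 +
        (cloud$coords[, 3] - ref[k, 3])^2
      lab[d2 <= threshold^2] <- 1L
    }
  }
  lab
}

#' Write a featurized point cloud to CSV
#'
#' Columns: x,y,z,nx,ny,nz,f1..f16,label (label -1 when absent). Header row
#' is mandatory.
#'
#' @param cloud A [surface_cloud()] with features.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  ff <- full_features(cloud)
  colnames(ff) <- paste0("f", 1:16)
  df <- data.frame(x = cloud$coords[, 1], y = cloud$coords[, 2], z = cloud$coords[, 3],
                   nx = cloud$normals[, 1], ny = cloud$normals[, 2], nz = cloud$normals[, 3])
  df <- cbind(df, as.data.frame(ff))
  df$label <- if (is.null(cloud$labels)) -1L else as.integer(cloud$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a point cloud written by [write_cloud_csv()]
#' @param path CSV path.
#' @return A [surface_cloud()].
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "nx", "ny", "nz", paste0("f", 1:16), "label")
  if (!all(need %in% names(df))) stop("read_cloud_csv: missing columns", call. = FALSE)
  labs <- if (all(df$label < 0)) NULL else as.integer(df$label)
  surface_cloud(as.matrix(df[, c("x", "y", "z")]),
                as.matrix(df[, c("nx", "ny", "nz")]),
                chem_feat = as.matrix(df[, paste0("f", 1:6)]),
                geom_feat = as.matrix(df[, paste0("f", 7:16)]),
                labels = labs)
}
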