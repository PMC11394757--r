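# Synthetic labeled structures: quasi-uniform pseudo-atom "blobs" with
# concave spherical-cap pockets carved out, pocket-lining atoms biased
# toward a chosen element, and a single-atom pseudo-ligand at each pocket
# mouth so the ground-truth site center is exact.

#' Specification for synthetic structure generation
#'
#' @param n_structures Number of structures (>= 10 for dataset generation).
#' @param radius_range Ball radius range in Angstrom (default 8.5-11).
#' @param n_pockets Pockets per structure (default 1).
#' @param pocket_cap_angle Half-angle of the carved spherical cap in radians
#'   (default 0.45); the bite radius is `R * sin(angle)`.
#' @param pocket_chem_bias Element enriched among pocket-lining atoms
#'   (default "O").
#' @param noise_sd Atom position jitter in Angstrom (default 0.35).
#' @param seed Base seed; structure `index` derives its own stream.
#' @param n_archetypes Number of geometry archetypes (= split groups).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_structures = 60L, radius_range = c(8.5, 11),
                           n_pockets = 1L, pocket_cap_angle = 0.45,
                           pocket_chem_bias = "O", noise_sd = 0.35,
                           seed = 1L, n_archetypes = 10L) {
  stopifnot(all(radius_range > 0), length(radius_range) == 2L,
            radius_range[1] <= radius_range[2],
            pocket_cap_angle > 0, pocket_cap_angle <= pi / 2, n_pockets >= 1)
  structure(list(n_structures = as.integer(n_structures),
                 radius_range = radius_range, n_pockets = as.integer(n_pockets),
                 pocket_cap_angle = pocket_cap_angle,
                 pocket_chem_bias = toupper(pocket_chem_bias),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_archetypes = as.integer(n_archetypes)),
            class = "synthetic_spec")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate one synthetic blob structure with planted pockets
#'
#' Pseudo-atoms are placed on a jittered grid inside a ball (100-400 atoms,
#' realistic C/N/O/S proportions). Each pocket is carved by removing atoms
#' inside a spherical bite centered on the ball surface; atoms lining the
#' bite are re-assigned the bias element with high probability, and a
#' single-heavy-atom pseudo-ligand is placed in the cavity mouth.
#'
#' @param spec A [synthetic_spec()].
#' @param index Structure index (deterministic stream per (seed, index)).
#' @return List with `atoms` ([atom_set()]), `sites` (list of
#'   [ligand_site()]), `group_key` (geometry archetype), `id`.
#' @export
make_blob_structure <- function(spec, index) {
  arch <- ((index - 1L) %% spec$n_archetypes) + 1L
  with_local_seed(spec$seed * 1009L + index, {
    # archetype fixes the radius band -> geometry groups for leak-free splits
    lo <- spec$radius_range[1]; hi <- spec$radius_range[2]
    band <- lo + (hi - lo) * c(arch - 1L, arch) / spec$n_archetypes
    R <- stats::runif(1, band[1], band[2])
    spacing <- max(2.1, ((4 / 3) * pi * R^3 / 380)^(1 / 3))
    g <- seq(-R, R, by = spacing)
    P <- as.matrix(expand.grid(x = g, y = g, z = g))
    P <- P + matrix(stats::rnorm(length(P), sd = spec$noise_sd), nrow(P), 3L)
    P <- P[rowSums(P^2) <= R^2, , drop = FALSE]
    if (nrow(P) < 100L) stop("make_blob_structure: too few atoms; increase radius",
                             call. = FALSE)
    if (nrow(P) > 400L) P <- P[sort(sample(nrow(P), 400L)), , drop = FALSE]
    elements <- sample(c("C", "N", "O", "S"), nrow(P), replace = TRUE,
                       prob = c(0.62, 0.17, 0.19, 0.02))

    rp <- R * sin(spec$pocket_cap_angle)
    dirs <- list()
    tries <- 0L
    while (length(dirs) < spec$n_pockets) {
      u <- random_unit()
      ok <- all(vapply(dirs, function(d) acos(pmin(1, sum(d * u))) > 1.5,
                       logical(1)))
      if (ok) dirs[[length(dirs) + 1L]] <- u
      tries <- tries + 1L
      if (tries > 200L) stop("make_blob_structure: cannot place ", spec$n_pockets,
                             " non-overlapping pockets", call. = FALSE)
    }
    sites <- list()
    for (k in seq_along(dirs)) {
      u <- dirs[[k]]
      q <- u * R  # bite center on the ball surface
      d2q <- colSums((t(P) - q)^2)
      keep <- d2q >= rp^2
      P <- P[keep, , drop = FALSE]
      elements <- elements[keep]
      d2q <- d2q[keep]
      lining <- d2q < (rp + 2.5)^2
      flip <- lining & stats::runif(length(lining)) < 0.85
      elements[flip] <- spec$pocket_chem_bias
      lig <- u * (R - rp + 2.2)  # inside the cavity, near its wall
      sites[[k]] <- ligand_site(sprintf("PCK_%d_%d", index, k),
                                matrix(lig, 1L, 3L))
    }
    if (nrow(P) < 50L) stop("make_blob_structure: pocket carving removed too many atoms",
                            call. = FALSE)
    list(atoms = atom_set(P, elements), sites = sites,
         group_key = paste0("arch", arch), id = sprintf("synth_%04d", index))
  })
}

#' Generate a split synthetic dataset
#'
#' Structures are generated for indices 1..n and split train/val/test with
#' geometry archetypes kept whole per split.
#'
#' @param spec A [synthetic_spec()] with `n_structures >= 10`.
#' @param split A [split_spec()].
#' @return List with `train`, `val`, `test` (lists of structures) and
#'   `manifest` (data.frame: id, group_key, split, n_sites).
#' @export
make_separable_dataset <- function(spec, split = split_spec()) {
  stopifnot(spec$n_structures >= 10L)
  structs <- lapply(seq_len(spec$n_structures), function(i) make_blob_structure(spec, i))
  ids <- vapply(structs, `[[`, character(1), "id")
  gk <- vapply(structs, `[[`, character(1), "group_key")
  sp <- make_splits(ids, gk, split, seed = spec$seed)
  pick <- function(which_ids) structs[ids %in% which_ids]
  manifest <- data.frame(
    id = ids, group_key = gk,
    split = ifelse(ids %in% sp$train, "train", ifelse(ids %in% sp$val, "val", "test")),
    n_sites = vapply(structs, function(s) length(s$sites), integer(1)),
    stringsAsFactors = FALSE
  )
  list(train = pick(sp$train), val = pick(sp$val), test = pick(sp$test),
       manifest = manifest)
}

#' Write a synthetic dataset as PDB files plus a manifest
#'
#' @param dataset Output of [make_separable_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (also written as `manifest.csv`), invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("train", "val", "test")) {
    for (s in dataset[[split]]) {
      write_structure_pdb(s$atoms, file.path(dir, paste0(s$id, ".pdb")), s$sites)
    }
  }
  mf <- dataset$manifest
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}
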