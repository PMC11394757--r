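# Shared fixtures, built in code. Heavy objects are memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A toy PDB: three CA carbons + one ATP-like HETATM group + one ZN ion + water
toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "HETATM    4  PA  ATP A 101      10.000   5.000   0.000  1.00  0.00           P",
    "HETATM    5  O1A ATP A 101      11.000   5.000   0.000  1.00  0.00           O",
    "HETATM    6  C5* ATP A 101      12.000   5.000   0.000  1.00  0.00           C",
    "HETATM    7  N1  ATP A 101      13.000   5.000   0.000  1.00  0.00           N",
    "HETATM    8 ZN    ZN A 201      20.000  20.000  20.000  1.00  0.00          ZN",
    "HETATM    9  O   HOH A 301      25.000  25.000  25.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# Small random protein-like atom set
random_atoms <- function(n = 12L, seed = 1L, sd = 3) {
  set.seed(seed)
  atom_set(matrix(rnorm(n * 3, sd = sd), n, 3),
           sample(c("C", "O", "N"), n, replace = TRUE))
}

# Fully prepared small structure + narrow model for GNN tests
small_model_fixture <- function() {
  memo("small_model_fixture", {
    set.seed(42)
    atoms <- random_atoms(12L, seed = 42L)
    cloud <- sample_surface(atoms, 1.5, 0.3)
    cloud$geom_feat <- compute_curvature_features(cloud)
    cloud$labels <- as.integer(runif(nrow(cloud$coords)) < 0.3)
    cfg <- graph_config(voxel_size = 1.5, r0 = 2, r = 4, max_edges = 8,
                        state_dim = 8L)
    prep <- pocketgnn:::prepare_graph_input(cloud, atoms, cfg, k_chem = 5L)
    model <- init_model(state_dim = 8L, offset_hidden = 5L,
                        clf_hidden = c(6L, 4L))
    list(atoms = atoms, cloud = cloud, cfg = cfg, prep = prep, model = model)
  })
}

# One synthetic blob structure prepared at benchmark settings
synth_prep_fixture <- function() {
  memo("synth_prep_fixture", {
    spec <- synthetic_spec(seed = 7L)
    st <- make_blob_structure(spec, 1L)
    cfg <- benchmark_config()
    prep <- prepare_structure(st$atoms, st$sites, cfg, id = st$id)
    list(st = st, cfg = cfg, prep = prep)
  })
}

# dense unit-normal sphere sample of radius R
sphere_cloud <- function(R, n = 2500L, seed = 1L) {
  set.seed(seed)
  P <- matrix(rnorm(n * 3), n, 3)
  P <- P / sqrt(rowSums(P^2))
  surface_cloud(P * R, P)
}

rotation_matrix <- function(axis = c(1, 2, 2) / 3, angle = 0.7) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
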