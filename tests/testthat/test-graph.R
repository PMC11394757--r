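test_that("voxel downsampling keeps one representative per occupied cube", {
  # 8 points inside one 1-Angstrom voxel
  set.seed(1)
  X <- matrix(runif(24, 0.1, 0.9), 8, 3)
  expect_length(voxel_downsample(X, 1.0), 1L)
  # points >= 2 voxel sizes apart are all kept
  Y <- cbind(seq(0, 18, by = 2.5), 0, 0)
  expect_identical(voxel_downsample(Y, 1.0), seq_len(nrow(Y)))
})

test_that("voxel selection matches a brute-force hash on random clouds", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:300, 1)
    X <- matrix(runif(n * 3, -2.5, 2.5), n, 3)
    sel <- voxel_downsample(X, 1.0)
    # oracle: group by voxel key, pick the point nearest the group centroid
    key <- apply(floor(X / 1.0), 1, paste, collapse = "/")
    expected <- sort(unname(vapply(split(seq_len(n), key), function(ix) {
      ctr <- colMeans(X[ix, , drop = FALSE])
      d2 <- colSums((t(X[ix, , drop = FALSE]) - ctr)^2)
      # same documented tie rule: lowest index among (near-)equidistant points
      ix[which(d2 <= min(d2) + 1e-9)[1]]
    }, integer(1))))
    expect_identical(sel, expected)
    # one representative per occupied voxel
    expect_identical(length(sel), length(unique(key)))
  }
})

test_that("larger voxels never select more points", {
  set.seed(3)
  X <- matrix(runif(600, -8, 8), 200, 3)
  counts <- vapply(c(0.5, 1, 2, 4), function(v) length(voxel_downsample(X, v)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("radius graph applies the strict-inequality and nearest-truncation rules", {
  e <- build_radius_graph(rbind(c(0, 0, 0), c(3, 0, 0)), r = 4)
  expect_equal(e[, c("i", "j")], cbind(i = c(1, 2), j = c(2, 1)),
               ignore_attr = TRUE)
  expect_equal(nrow(build_radius_graph(rbind(c(0, 0, 0), c(5, 0, 0)), r = 4)), 0L)
  # boundary: exactly r is excluded (strict <)
  expect_equal(nrow(build_radius_graph(rbind(c(0, 0, 0), c(4, 0, 0)), r = 4)), 0L)
  # truncation keeps the max_edges nearest
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, 0), c(2, 0, 0))
  e <- build_radius_graph(X, r = 4, max_edges = 2L)
  out0 <- e[e[, "i"] == 1, "j"]
  expect_identical(sort(out0), c(2, 3))  # 4th neighbor (2 A) dropped
})

test_that("radius graph matches an all-pairs oracle on random clouds", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(50:300, 1)
    X <- matrix(runif(n * 3, 0, 20), n, 3)
    me <- sample(c(4L, 8L, 32L), 1)
    e <- build_radius_graph(X, r = 4, max_edges = me)
    D <- as.matrix(dist(X))
    oracle <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- which(D[i, ] < 4 & seq_len(n) != i)
      if (length(nb) > me) nb <- nb[order(D[i, nb], nb)][seq_len(me)]
      if (length(nb) == 0L) return(NULL)
      cbind(i = i, j = sort(nb))
    }))
    if (is.null(oracle)) oracle <- matrix(numeric(0), 0, 2)
    expect_equal(e[, c("i", "j")], oracle, ignore_attr = TRUE)
    expect_equal(e[, "dist"], D[e[, c("i", "j"), drop = FALSE]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("initial-state aggregation obeys singleton and idempotence rules", {
  set.seed(5)
  embed <- pocketgnn:::init_mlp(c(19, 8, 8))
  # an isolated point aggregates only itself: state = MLP([h, 0])
  feats <- matrix(rnorm(2 * 16), 2, 16)
  cl <- surface_cloud(rbind(c(0, 0, 0), c(50, 0, 0)),
                      rbind(c(0, 0, 1), c(0, 0, 1)))
  cl$chem_feat <- feats[, 1:6]; cl$geom_feat <- feats[, 7:16]
  st <- aggregate_initial_states(cl, c(1L, 2L), r0 = 2, embed)
  direct <- pocketgnn:::mlp_forward(embed, cbind(feats, matrix(0, 2, 3)))
  expect_equal(st, direct, tolerance = 1e-12)
  # duplicating a neighbor exactly leaves the Max unchanged
  cl2 <- surface_cloud(rbind(cl$coords, c(0.5, 0, 0), c(0.5, 0, 0)),
                       matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE))
  f2 <- rbind(feats, feats[1, ], feats[1, ])
  cl2$chem_feat <- f2[, 1:6]; cl2$geom_feat <- f2[, 7:16]
  st2 <- aggregate_initial_states(cl2, c(1L, 2L), r0 = 2, embed)
  cl3 <- surface_cloud(cl2$coords[1:3, ], cl2$normals[1:3, ])
  cl3$chem_feat <- f2[1:3, 1:6]; cl3$geom_feat <- f2[1:3, 7:16]
  st3 <- aggregate_initial_states(cl3, c(1L, 2L), r0 = 2, embed)
  expect_equal(st2, st3, tolerance = 1e-12)
})

test_that("aggregated states match a brute-force per-vertex loop", {
  set.seed(6)
  n <- 50L
  cl <- surface_cloud(matrix(runif(n * 3, 0, 8), n, 3),
                      matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE))
  cl$chem_feat <- matrix(rnorm(n * 6), n, 6)
  cl$geom_feat <- matrix(rnorm(n * 10), n, 10)
  embed <- pocketgnn:::init_mlp(c(19, 12, 12))
  sel <- voxel_downsample(cl, 2.0)
  st <- aggregate_initial_states(cl, sel, r0 = 2, embed)
  ff <- full_features(cl)
  for (v in seq_along(sel)) {
    xv <- cl$coords[sel[v], ]
    d <- sqrt(colSums((t(cl$coords) - xv)^2))
    nb <- which(d <= 2 + 1e-12)
    emb <- pocketgnn:::mlp_forward(
      embed, cbind(ff[nb, , drop = FALSE],
                   sweep(cl$coords[nb, , drop = FALSE], 2, xv, "-")))
    expect_equal(st[v, ], apply(emb, 2, max), tolerance = 1e-10)
  }
})

test_that("graph construction is translation invariant for voxel-multiple shifts", {
  set.seed(8)
  n <- 120L
  cl <- surface_cloud(matrix(runif(n * 3, 0, 10), n, 3),
                      matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE))
  cl$chem_feat <- matrix(rnorm(n * 6), n, 6)
  cl$geom_feat <- matrix(rnorm(n * 10), n, 10)
  shift <- c(50, -30, 20)  # integer multiple of the 1-Angstrom voxel
  cl2 <- cl
  cl2$coords <- sweep(cl$coords, 2, shift, "+")
  sel1 <- voxel_downsample(cl, 1.0)
  sel2 <- voxel_downsample(cl2, 1.0)
  expect_identical(sel1, sel2)
  e1 <- build_radius_graph(cl$coords[sel1, ], 4)
  e2 <- build_radius_graph(cl2$coords[sel2, ], 4)
  expect_equal(e1[, c("i", "j")], e2[, c("i", "j")], ignore_attr = TRUE)
  embed <- pocketgnn:::init_mlp(c(19, 8, 8))
  s1 <- aggregate_initial_states(cl, sel1, 2, embed)
  s2 <- aggregate_initial_states(cl2, sel2, 2, embed)
  expect_equal(s1, s2, tolerance = 1e-9)  # relative coordinates only
})

test_that("every point lies within r0 of a vertex when the voxel diagonal bound holds", {
  # representatives are real points, so the worst case inside one voxel is the
  # full diagonal: the guarantee needs sqrt(3) * voxel <= r0
  r0 <- 2
  vox <- r0 / sqrt(3) - 0.05
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 150L
    X <- matrix(runif(n * 3, 0, 12), n, 3)
    sel <- voxel_downsample(X, vox)
    D <- as.matrix(dist(X))[, sel, drop = FALSE]
    expect_true(all(apply(D, 1, min) <= r0))
  }
})
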