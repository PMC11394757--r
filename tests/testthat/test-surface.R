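test_that("single-atom surface lies on the inflated sphere with outward normals", {
  a <- atom_set(matrix(c(0, 0, 0), 1, 3), "C")
  cl <- sample_surface(a, probe_radius = 1.5, target_density = 1.0)
  d <- sqrt(rowSums(cl$coords^2))
  expect_true(all(abs(d - 3.2) < 0.01))  # vdW 1.7 + probe 1.5
  # normals point away from the atom center
  expect_true(all(rowSums(cl$normals * cl$coords) > 0))
  expect_true(all(abs(sqrt(rowSums(cl$normals^2)) - 1) < 1e-6))
  # realized density within 2x of target: sphere area 4*pi*3.2^2
  area <- 4 * pi * 3.2^2
  expect_gt(nrow(cl$coords) / area, 0.5)
  expect_lt(nrow(cl$coords) / area, 2)
})

test_that("coincident atoms add no surface; distant atoms add a full shell", {
  a1 <- atom_set(matrix(c(0, 0, 0), 1, 3), "C")
  a2 <- atom_set(rbind(c(0, 0, 0), c(0, 0, 0)), c("C", "C"))
  a3 <- atom_set(rbind(c(0, 0, 0), c(20, 0, 0)), c("C", "C"))
  n1 <- nrow(sample_surface(a1, 1.5, 1)$coords)
  n2 <- nrow(sample_surface(a2, 1.5, 1)$coords)
  n3 <- nrow(sample_surface(a3, 1.5, 1)$coords)
  expect_equal(n2, n1, tolerance = 0.1)   # degenerate union
  expect_equal(n3, 2 * n1, tolerance = 0.1)  # two disjoint shells
})

test_that("point labels follow the 4 Angstrom any-site center rule", {
  cl <- surface_cloud(rbind(c(3.9, 0, 0), c(4.1, 0, 0), c(100, 0, 0)),
                      rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  s1 <- ligand_site("A", matrix(c(0, 0, 0), 1, 3))
  s2 <- ligand_site("B", matrix(c(100, 2, 0), 1, 3))
  lab <- label_points(cl, list(s1, s2), threshold = 4)
  expect_identical(lab, c(1L, 0L, 1L))  # 3.9 in, 4.1 out, second site only
})

test_that("chemical features have the contracted shape and bias behavior", {
  fx <- small_model_fixture()
  params <- init_chem_net()
  feat <- compute_chemical_features(fx$cloud, fx$atoms, params, k = 16L)
  expect_identical(dim(feat), c(nrow(fx$cloud$coords), 6L))
  expect_true(all(is.finite(feat)))
  # all weights zero -> every point's features equal the post-map bias
  zero <- rapply(params, function(x) x * 0, classes = "ANY", how = "replace")
  zero$post$b <- c(1, -2, 0.5, 0, 3, -1)
  f0 <- compute_chemical_features(fx$cloud, fx$atoms,
                                  structure(zero, class = "chem_net_params"))
  expect_equal(f0, matrix(rep(zero$post$b, each = nrow(f0)), ncol = 6),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("chemical features match a per-point brute-force loop", {
  fx <- small_model_fixture()
  set.seed(11)
  params <- init_chem_net()
  feat <- compute_chemical_features(fx$cloud, fx$atoms, params, k = 4L)
  # independent loop oracle using plain dense algebra per point
  elig <- which(fx$atoms$is_protein & !is.na(fx$atoms$chem_index))
  bn_eval <- function(X, bn) {
    xh <- sweep(sweep(X, 2, bn$run_mean, "-"), 2, sqrt(bn$run_var + 1e-5), "/")
    sweep(sweep(xh, 2, bn$gamma, "*"), 2, bn$beta, "+")
  }
  for (i in sample(nrow(fx$cloud$coords), 5)) {
    d <- sqrt(colSums((t(fx$atoms$coords[elig, ]) - fx$cloud$coords[i, ])^2))
    nb <- elig[order(d)][1:4]
    dd <- sort(d)[1:4]
    acc <- numeric(6)
    for (k in 1:4) {
      x <- numeric(7)
      x[fx$atoms$chem_index[nb[k]] + 1] <- 1
      x[7] <- 1 / dd[k]
      h <- x %*% params$l1$W + params$l1$b
      h <- bn_eval(h, params$bn)
      h[h < 0] <- 0
      acc <- acc + as.vector(h %*% params$l2$W + params$l2$b)
    }
    expected <- as.vector(acc %*% params$post$W + params$post$b)
    expect_equal(as.vector(feat[i, ]), expected, tolerance = 1e-8)
  }
})

test_that("duplicating atoms doubles the summed pre-linear representation", {
  fx <- small_model_fixture()
  set.seed(13)
  params <- init_chem_net()
  # identity post map isolates the atom-contribution sum
  params$post$W <- diag(6)
  params$post$b <- numeric(6)
  f1 <- compute_chemical_features(fx$cloud, fx$atoms, params, k = 16L)
  dup <- atom_set(rbind(fx$atoms$coords, fx$atoms$coords),
                  c(fx$atoms$elements, fx$atoms$elements))
  f2 <- compute_chemical_features(fx$cloud, dup, params, k = 32L)
  expect_equal(f2, 2 * f1, tolerance = 1e-8)
})

test_that("features are invariant and normals covariant under rigid motion", {
  fx <- small_model_fixture()
  set.seed(17)
  params <- init_chem_net()
  Rm <- rotation_matrix()
  tv <- c(12, -7, 4)
  move <- function(X) sweep(X %*% t(Rm), 2, tv, "+")
  atoms2 <- atom_set(move(fx$atoms$coords), fx$atoms$elements)
  cl2 <- surface_cloud(move(fx$cloud$coords), fx$cloud$normals %*% t(Rm),
                       geom_feat = NULL)
  chem1 <- compute_chemical_features(fx$cloud, fx$atoms, params)
  chem2 <- compute_chemical_features(cl2, atoms2, params)
  expect_equal(chem2, chem1, tolerance = 1e-4)
  geom1 <- compute_curvature_features(fx$cloud)
  geom2 <- compute_curvature_features(cl2)
  expect_equal(geom2, geom1, tolerance = 1e-4)
})

test_that("point-cloud CSV round trip preserves coordinates, features, labels", {
  fx <- small_model_fixture()
  cl <- fx$cloud
  set.seed(19)
  cl$chem_feat <- compute_chemical_features(cl, fx$atoms, init_chem_net())
  path <- tempfile(fileext = ".csv")
  write_cloud_csv(cl, path)
  cl2 <- read_cloud_csv(path)
  expect_equal(cl2$coords, cl$coords, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(full_features(cl2), full_features(cl), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(cl2$labels, cl$labels)
})
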