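test_that("thresholding is strictly greater-than", {
  expect_identical(threshold_points(c(0.4, 0.5, 0.6)), 3L)
  expect_identical(threshold_points(rep(0.1, 5)), integer(0))
  expect_identical(threshold_points(c(0.2, 0.8), threshold = 0), 1:2)
})

test_that("OPTICS ordering and reachability match scikit-learn", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(5)
  X <- rbind(matrix(rnorm(60, sd = 1.2), 20, 3),
             sweep(matrix(rnorm(60, sd = 1.2), 20, 3), 2, c(15, 0, 0), "+"),
             matrix(runif(15, -5, 20), 5, 3))
  pts <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  utils::write.csv(X, pts, row.names = FALSE)
  script <- sprintf('
import numpy as np, pandas as pd
from sklearn.cluster import compute_optics_graph
X = pd.read_csv(%s).values
o, core, reach, pred = compute_optics_graph(X, min_samples=5, max_eps=6,
    metric="euclidean", p=2, metric_params=None, algorithm="brute",
    leaf_size=30, n_jobs=None)
pd.DataFrame({"order": o, "reach": reach, "core": core}).to_csv(%s, index=False)
', deparse(pts), deparse(out))
  status <- system2("python", "-", input = script, stdout = FALSE, stderr = FALSE)
  skip_if(status != 0L || !file.exists(out), "scikit-learn unavailable")
  ref <- utils::read.csv(out)
  opt <- pocketgnn:::optics_order(X, min_samples = 5L, max_eps = 6)
  expect_identical(opt$order - 1L, as.integer(ref$order))
  finite <- is.finite(ref$reach)
  expect_identical(is.finite(opt$reachability), finite)
  expect_equal(opt$reachability[finite], ref$reach[finite], tolerance = 1e-8)
  cfin <- is.finite(ref$core)
  expect_equal(opt$core_dist[cfin], ref$core[cfin], tolerance = 1e-8)
})

test_that("two well-separated blobs form exactly two clusters with true centers", {
  for (s in 1:5) {
    set.seed(s)
    c1 <- c(0, 0, 0)
    c2 <- c(30, 0, 0)
    X <- rbind(sweep(matrix(rnorm(60, sd = 1.5), 20, 3), 2, c1, "+"),
               sweep(matrix(rnorm(60, sd = 1.5), 20, 3), 2, c2, "+"))
    probs <- runif(40, 0.6, 0.99)
    pockets <- cluster_pockets(X, probs)
    expect_length(pockets, 2L)
    ctrs <- t(vapply(pockets, `[[`, numeric(3), "center"))
    d1 <- min(sqrt(colSums((t(ctrs) - c1)^2)))
    d2 <- min(sqrt(colSums((t(ctrs) - c2)^2)))
    expect_lt(d1, 1)
    expect_lt(d2, 1)
  }
})

test_that("isolated points are noise when fewer than min_samples", {
  X <- rbind(c(0, 0, 0), c(25, 0, 0), c(0, 25, 0))
  expect_length(cluster_pockets(X, rep(0.9, 3), min_samples = 5L), 0L)
})

test_that("pocket scores are additive and invariants hold", {
  set.seed(31)
  X <- matrix(rnorm(90, sd = 1.5), 30, 3)
  probs <- runif(30, 0.55, 0.95)
  p1 <- cluster_pockets(X, probs)
  expect_length(p1, 1L)
  expect_equal(p1[[1]]$score, sum(p1[[1]]$member_probs), tolerance = 1e-9)
  expect_true(all(p1[[1]]$member_probs > 0.5))
  # duplicating the blob point-for-point doubles the score, same cluster count
  p2 <- cluster_pockets(rbind(X, X), c(probs, probs))
  expect_length(p2, 1L)
  expect_equal(p2[[1]]$score, 2 * p1[[1]]$score, tolerance = 1e-9)
})

test_that("ranks are a permutation of 1..k with non-increasing scores", {
  set.seed(32)
  X <- rbind(sweep(matrix(rnorm(90, sd = 1.2), 30, 3), 2, c(0, 0, 0), "+"),
             sweep(matrix(rnorm(36, sd = 1.2), 12, 3), 2, c(25, 0, 0), "+"))
  probs <- c(runif(30, 0.8, 0.99), runif(12, 0.51, 0.6))
  pk <- cluster_pockets(X, probs)
  expect_identical(vapply(pk, `[[`, integer(1), "rank"), seq_along(pk))
  scores <- vapply(pk, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
})

test_that("top-n selection reports shortfalls", {
  set.seed(33)
  X <- matrix(rnorm(90, sd = 1.5), 30, 3)
  pk <- cluster_pockets(X, runif(30, 0.6, 0.9))
  expect_length(select_top_n(pk, 1)$pockets, 1L)
  s <- select_top_n(pk, 3)
  expect_length(s$pockets, 1L)
  expect_identical(s$shortfall, 2L)
  s0 <- select_top_n(list(), 1)
  expect_length(s0$pockets, 0L)
  expect_identical(s0$shortfall, 1L)
})

test_that("xi extraction also separates distant blobs", {
  set.seed(34)
  X <- rbind(matrix(rnorm(60, sd = 1.5), 20, 3),
             sweep(matrix(rnorm(60, sd = 1.5), 20, 3), 2, c(30, 0, 0), "+"))
  labels <- optics_cluster(X, method = "xi")
  expect_gte(length(unique(labels[labels > 0])), 2L)
  # no cluster spans both blobs
  blob <- rep(1:2, each = 20)
  for (id in unique(labels[labels > 0])) {
    expect_length(unique(blob[labels == id]), 1L)
  }
})
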