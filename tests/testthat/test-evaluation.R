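mk_pocket <- function(center, rank = 1L, score = 1) {
  structure(list(member_indices = 1L, member_probs = score, score = score,
                 center = center, rank = rank), class = "pocket_cluster")
}

test_that("DCC is the Euclidean center-center distance", {
  expect_equal(compute_dcc(c(0, 0, 0), c(3, 0, 0)), 3)
  expect_equal(compute_dcc(c(1, 2, 2), c(0, 0, 0)), 3)
  expect_equal(compute_dcc(c(5, 5, 5), c(5, 5, 5)), 0)
})

test_that("greedy matching pairs globally nearest site/pocket pairs first", {
  s1 <- ligand_site("s1", matrix(c(0, 0, 0), 1, 3))
  s2 <- ligand_site("s2", matrix(c(10, 0, 0), 1, 3))
  # crossed distances: pocket A at 1 of s1 / 9 of s2; pocket B at 9 / 1
  pA <- mk_pocket(c(1, 0, 0), rank = 1L)
  pB <- mk_pocket(c(9, 0, 0), rank = 2L)
  rec <- match_sites(list(pA, pB), list(s1, s2))
  expect_equal(rec$dcc, c(1, 1))
  expect_identical(rec$matched_rank, c(1L, 2L))
  # exhaustive check against all assignments for small cases
  perms <- list(c(1, 2), c(2, 1))
  best <- min(vapply(perms, function(p) {
    sum(c(compute_dcc(list(pA, pB)[[p[1]]]$center, s1$center),
          compute_dcc(list(pA, pB)[[p[2]]]$center, s2$center)))
  }, numeric(1)))
  expect_equal(sum(rec$dcc), best)
})

test_that("shortfalls leave sites unmatched", {
  s1 <- ligand_site("s1", matrix(c(0, 0, 0), 1, 3))
  s2 <- ligand_site("s2", matrix(c(30, 0, 0), 1, 3))
  rec <- match_sites(list(mk_pocket(c(2, 0, 0))), list(s1, s2))
  expect_equal(sum(is.na(rec$dcc)), 1L)
  expect_equal(rec$dcc[1], 2)
  rec0 <- match_sites(list(), list(s1))
  expect_true(all(is.na(rec0$dcc)))
})

test_that("DVO is the Jaccard ratio of occupied voxel sets", {
  A <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5))  # two voxels at edge 2
  B <- rbind(c(1.0, 1.0, 1.0))                     # one of them
  expect_equal(compute_dvo(A, B, voxel = 2), 0.5)
  expect_equal(compute_dvo(A, A, voxel = 2), 1)
  far <- sweep(A, 2, c(100, 0, 0), "+")
  expect_equal(compute_dvo(A, far, voxel = 2), 0)
  # symmetry and empty handling
  expect_equal(compute_dvo(A, B), compute_dvo(B, A))
  expect_true(is.na(compute_dvo(A, matrix(numeric(0), 0, 3))))
})

test_that("summary reproduces the TP/FP/FN and F1 arithmetic", {
  rec <- data.frame(structure_id = "x", site_id = c("a", "b", "c"),
                    dcc = c(3, 5, NA), matched_rank = c(1L, 2L, NA),
                    dvo = c(0.4, 0.1, NA))
  s <- summarize_eval(rec)
  expect_identical(c(s$TP, s$FP, s$FN), c(1L, 1L, 1L))
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.5)
  expect_equal(s$f1, 0.5)
  expect_equal(s$success_rate, 1 / 3)
  expect_equal(s$mean_dvo, 0.25)
})

test_that("a DCC of exactly 4 Angstrom counts as a success (inclusive rule)", {
  rec <- data.frame(structure_id = "x", site_id = "a", dcc = 4.0,
                    matched_rank = 1L, dvo = NA_real_)
  s <- summarize_eval(rec)
  expect_identical(s$TP, 1L)
  expect_equal(s$success_rate, 1)
  expect_equal(s$f1, 1)
})

test_that("success curve counts thresholds cumulatively and monotonically", {
  rec <- data.frame(structure_id = "x", site_id = c("a", "b", "c"),
                    dcc = c(1, 3, 5), matched_rank = 1:3, dvo = NA_real_)
  cv <- success_curve(rec, c(2, 4, 6))
  expect_equal(cv$rate, c(1, 2, 3) / 3)
  expect_identical(nrow(success_curve(rec, numeric(0))), 0L)
  # property: non-decreasing for arbitrary records
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    r <- data.frame(structure_id = "x", site_id = as.character(seq_len(n)),
                    dcc = ifelse(runif(n) < 0.2, NA, runif(n, 0, 12)),
                    matched_rank = seq_len(n), dvo = NA_real_)
    cv <- success_curve(r, seq(0, 14, by = 0.5))
    expect_true(all(diff(cv$rate) >= 0))
    s4 <- summarize_eval(r)
    expect_equal(cv$rate[cv$threshold == 4], s4$success_rate)
  }
})

test_that("bookkeeping identity: TP + FP + FN covers predictions and misses", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(2:15, 1)
    r <- data.frame(structure_id = "x", site_id = as.character(seq_len(n)),
                    dcc = ifelse(runif(n) < 0.3, NA, runif(n, 0, 10)),
                    matched_rank = seq_len(n), dvo = NA_real_)
    s <- summarize_eval(r)
    expect_identical(s$TP + s$FP + s$FN, n)
    expect_identical(s$FN, sum(is.na(r$dcc)))
  }
})
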