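test_that("similarity profiles are the sorted pairwise correlations", {
  # three identical profiles: all pairwise r = 1
  x <- rbind(a = c(1, 5, 2), b = c(1, 5, 2), c = c(1, 5, 2))
  expect_equal(similarity_profile(x), c(1, 1, 1))
  # two members give a single-element profile
  expect_length(similarity_profile(x[1:2, ]), 1)
  # 4-member group equals brute-force enumeration of all pairs
  set.seed(3)
  y <- matrix(rnorm(4 * 6), 4, 6)
  brute <- sort(apply(combn(4, 2), 2, function(ij)
    cor(y[ij[1], ], y[ij[2], ])))
  expect_equal(similarity_profile(y), brute)
  # constant member excluded before profiling
  z <- rbind(y, k = rep(2, 6))
  expect_warning(pr <- similarity_profile(z), "zero-variance")
  expect_equal(pr, brute)
})

test_that("permutation-invariant data yields pi = 0 and p = 1", {
  # identical rows: within-column permutation cannot change anything
  x <- matrix(rep(c(3, 9, 1, 7), each = 5), 5, 4)
  res <- simprof_single(x, B1 = 200, B2 = 199, seed = 1)
  expect_equal(res$pi, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("groups below three members are declared homogeneous untested", {
  res <- simprof_single(matrix(rnorm(8), 2, 4), seed = 1)
  expect_false(res$tested)
  expect_false(res$significant)
  expect_true(is.na(res$p_value))
})

test_that("the p-value respects the add-one lower bound", {
  # strongly structured group: two tight blocks
  set.seed(8)
  base1 <- rnorm(6); base2 <- rnorm(6)
  x <- rbind(base1 + rnorm(6, sd = 0.01), base1 + rnorm(6, sd = 0.01),
             base2 + rnorm(6, sd = 0.01), base2 + rnorm(6, sd = 0.01))
  res <- simprof_single(x, B1 = 200, B2 = 199, seed = 2)
  expect_true(res$significant)
  # add-one estimator: p can never reach zero
  expect_gte(res$p_value, 1 / (1 + 199))
  expect_gte(min(1 + sum(res$perm_pi >= res$pi)) / (1 + 199), 1 / 200)
})

test_that("the kernel's pi equals a naive recomputation from its profiles", {
  set.seed(21)
  x <- matrix(rexp(6 * 5), 6, 5)
  res <- simprof_single(x, B1 = 150, B2 = 149, seed = 4)
  expect_equal(res$pi, sum(abs(res$obs_profile - res$mean_profile)))
  expect_equal(res$obs_profile, similarity_profile(x))
})

test_that("Monte-Carlo pi null converges to the exact 36-permutation distribution", {
  x <- rbind(c(1, 5), c(2, 4), c(7, 3))
  exact <- exact_simprof_null_3x2(x)
  res <- simprof_single(x, B1 = 2000, B2 = 6000, seed = 9)
  expect_equal(res$mean_profile, exact$mean_profile, tolerance = 0.05)
  tv_big <- tv_to_atoms(res$perm_pi, exact$pi_values)
  expect_lt(tv_big, 0.05)
})

test_that("recursive SIMPROF recovers planted blocks and is order-invariant", {
  set.seed(14)
  b1 <- rnorm(8); b2 <- rnorm(8)
  m <- rbind(
    A1 = b1 + rnorm(8, sd = 0.05), A2 = b1 + rnorm(8, sd = 0.05),
    A3 = b1 + rnorm(8, sd = 0.05),
    B1 = b2 + rnorm(8, sd = 0.05), B2 = b2 + rnorm(8, sd = 0.05),
    B3 = b2 + rnorm(8, sd = 0.05))
  rck <- make_rck(m, samples = tiny_samples(8))
  cfg <- pipeline_config(n_perm_mean = 300, n_perm_null = 299, rng_seed = 5)
  tree <- upgma_cluster(pearson_similarity(rck, cfg))
  out <- simprof_recursive(tree, rck, cfg)
  cl <- setNames(out$assignments$cluster, out$assignments$contig_id)
  expect_length(unique(cl[c("A1", "A2", "A3")]), 1)
  expect_length(unique(cl[c("B1", "B2", "B3")]), 1)
  expect_false(cl[["A1"]] == cl[["B1"]])
  # the root must have been tested and found significant
  root <- out$nodes[out$nodes$size == 6, ]
  expect_true(root$significant)

  # contig input order does not change the partition (seeds hash member ids)
  perm <- c(4, 1, 6, 2, 5, 3)
  rck2 <- make_rck(m[perm, ], samples = tiny_samples(8))
  tree2 <- upgma_cluster(pearson_similarity(rck2, cfg))
  out2 <- simprof_recursive(tree2, rck2, cfg)
  cl2 <- setNames(out2$assignments$cluster, out2$assignments$contig_id)
  split1 <- unname(split(names(cl), cl))
  split2 <- unname(split(names(cl2), cl2))
  expect_setequal(lapply(split1, sort), lapply(split2, sort))
})

test_that("node seeds derive deterministically from member ids", {
  s1 <- derive_seed(c("x", "y", "z"), 42)
  expect_identical(s1, derive_seed(c("z", "x", "y"), 42))
  expect_false(s1 == derive_seed(c("x", "y"), 42))
  expect_false(s1 == derive_seed(c("x", "y", "z"), 43))
})
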