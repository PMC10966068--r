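test_that("pattern correlation matches the two-pass oracle", {
  expect_equal(pattern_correlation(1:5, 1:5), 1)
  expect_equal(pattern_correlation(1:5, -(1:5)), -1)
  expect_equal(pattern_correlation(c(1, 2, 3), c(1, 2, 4)),
               oracle_pearson(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_error(pattern_correlation(c(1, 1, 1), 1:3), "variance")
  expect_error(pattern_correlation(1:3, 1:4), "length")
})

test_that("random rotations are orthogonal with determinant +1", {
  set.seed(33)
  for (i in 1:25) {
    R <- asymkit:::random_rotation()
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("spin null respects tissue classes and covers cortex", {
  atlas <- default_atlas()
  nulls <- spin_null(atlas, n_spin = 200L, seed = 4L)
  cort <- which(atlas$tissue == "cortical")
  sub <- which(atlas$tissue == "subcortical")
  cer <- which(atlas$tissue == "cerebellar")
  for (s in c(1L, 50L, 200L)) {
    expect_true(all(nulls[s, cort] %in% cort))
    expect_setequal(nulls[s, sub], sub)     # within-class permutation
    expect_setequal(nulls[s, cer], cer)
    # values entering the null come from the original map (with duplicates)
    expect_true(all(nulls[s, ] %in% seq_len(nrow(atlas))))
  }
  # every cortical region is selected with positive frequency
  expect_setequal(sort(unique(as.vector(nulls[, cort]))), cort)
  # determinism
  expect_identical(nulls, spin_null(atlas, n_spin = 200L, seed = 4L))
})

test_that("mirror-conjugate rotation reproduces the left assignment", {
  atlas <- default_atlas()
  cort <- which(atlas$tissue == "cortical")
  CL <- as.matrix(atlas[cort, c("lx", "ly", "lz")])
  CR <- as.matrix(atlas[cort, c("rx", "ry", "rz")])
  M <- diag(c(-1, 1, 1))
  set.seed(77)
  for (i in 1:10) {
    R <- asymkit:::random_rotation()
    left_assign <- apply(CL %*% t(R) %*% t(CL), 2, which.max)
    Rm <- M %*% R %*% M
    right_assign <- apply(CR %*% t(Rm) %*% t(CR), 2, which.max)
    expect_identical(left_assign, right_assign)
  }
})

test_that("spin test p-values are bounded, smoothed, and deterministic", {
  atlas <- default_atlas()
  nulls <- spin_null(atlas, n_spin = 150L, seed = 5L)
  a <- as.numeric(scale(atlas$lz))  # smooth spatial signal
  st <- spin_test(a, a, nulls)
  expect_equal(st$r_obs, 1)
  expect_gte(st$p, 1 / 151)
  expect_gt(st$p, 0)
  expect_equal(length(st$null_r), 150L)
  expect_error(spin_null(atlas, n_spin = 0L), "n_spin")
  expect_error(spin_test(a[1:10], a[1:10], nulls), "match the atlas")
  # determinism of the full test given one null table
  b <- as.numeric(scale(atlas$lx))
  expect_identical(spin_test(a, b, nulls)$p, spin_test(a, b, nulls)$p)
})

test_that("fdr_correct agrees with the step-up oracle", {
  p <- c(0.01, 0.02, 0.04, 0.05)
  res <- fdr_correct(p, q = 0.05)
  expect_identical(res$significant, oracle_bh_reject(p, 0.05))
  expect_equal(res$p_fdr, oracle_bh_adjust(p), tolerance = 1e-12)
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  # all strong p-values rejected
  expect_true(all(fdr_correct(rep(0.001, 65))$significant))
})

test_that("ward clustering matches the Lance-Williams oracle", {
  # duplicates merge first at height zero
  pats <- list(a = c(0, 0), b = c(0, 0), c = c(10, 10), d = c(10, 10))
  wc <- ward_cluster(pats)
  expect_equal(wc$hclust$height[1:2], c(0, 0), tolerance = 1e-12)
  # 1-D toy
  wc2 <- ward_cluster(list(x = 0, y = 1, z = 10))
  expect_equal(wc2$hclust$height,
               oracle_ward_heights(matrix(c(0, 1, 10))), tolerance = 1e-10)
  expect_true(all(diff(wc2$hclust$height) >= -1e-12))
  # order invariance of topology and heights
  pats3 <- list(a = c(1, 0, 2), b = c(1.1, 0, 2), c = c(5, 5, 5),
                d = c(-3, 2, 0))
  h1 <- sort(ward_cluster(pats3)$hclust$height)
  h2 <- sort(ward_cluster(rev(pats3))$hclust$height)
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_error(ward_cluster(setNames(pats3, c("a", "a", "b", "c"))),
               "unique")
  expect_error(ward_cluster(pats3[1]), ">= 2")
})

test_that("pairwise similarity matrices are symmetric with FDR flags", {
  atlas <- default_atlas()
  nulls <- spin_null(atlas, n_spin = 100L, seed = 6L)
  set.seed(8)
  pats <- list(a = rnorm(65), b = rnorm(65), c = rnorm(65))
  pats$d <- pats$a + rnorm(65, sd = 0.1)  # strongly similar pair
  sim <- pattern_similarity_matrix(pats, nulls)
  expect_equal(sim$r, t(sim$r))
  expect_equal(sim$p, t(sim$p))
  expect_gt(sim$r["a", "d"], 0.9)
  expect_equal(sim$r["a", "b"],
               pattern_correlation(pats$a, pats$b), tolerance = 1e-12)
})
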