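test_that("roc_auc reproduces enumerated pair counts", {
  expect_equal(roc_auc(c(1, 2), c(0, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # agreement with explicit pair enumeration on random inputs
  set.seed(2)
  for (i in 1:20) {
    s <- rnorm(12)
    y <- sample(c(0, 1), 12, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                         ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
  }
})

test_that("coefficients follow the closed form solve(Sigma, delta-mu)", {
  set.seed(5)
  n <- 10000L
  sigma <- c(1, 2)
  mu1 <- c(0.5, -0.3)
  X <- rbind(sweep(matrix(rnorm(n * 2), n, 2) %*% diag(sigma), 2, mu1, `+`),
             matrix(rnorm(n * 2), n, 2) %*% diag(sigma))
  colnames(X) <- c("a", "b")
  am <- structure(list(ai = X, group = rep(c("16p11.2del", "control"),
                                           each = n),
                       subject_id = as.character(seq_len(2L * n)),
                       scaling = "pooled_z", center = NULL, scale = NULL,
                       reference = NULL), class = "asym_matrix")
  fit <- fit_lda(am, "16p11.2del", shrinkage = 0)
  w <- fit$coefficients
  truth <- solve(diag(sigma^2), mu1)
  cosine <- sum(w * truth) / sqrt(sum(w^2) * sum(truth^2))
  expect_gte(abs(cosine), 0.999)
})

test_that("fitted direction agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 2000L
  S <- matrix(c(1, 0.5, 0.2, 0.5, 1.5, 0.3, 0.2, 0.3, 0.8), 3, 3)
  L <- chol(S)
  X <- rbind(sweep(matrix(rnorm(n * 3), n, 3) %*% L, 2, c(0.4, 0, -0.2), `+`),
             matrix(rnorm(n * 3), n, 3) %*% L)
  colnames(X) <- c("a", "b", "c")
  y <- rep(c("16p11.2del", "control"), each = n)
  am <- structure(list(ai = X, group = y,
                       subject_id = as.character(seq_len(2L * n)),
                       scaling = "pooled_z", center = NULL, scale = NULL,
                       reference = NULL), class = "asym_matrix")
  fit <- fit_lda(am, "16p11.2del", shrinkage = 0)
  ref <- MASS::lda(X, grouping = y)$scaling[, 1]
  cosine <- sum(fit$coefficients * ref) /
    sqrt(sum(fit$coefficients^2) * sum(ref^2))
  expect_gte(abs(cosine), 0.999)
})

test_that("no-signal data yields chance-level AUC; separation yields 1", {
  atlas <- tiny_atlas()
  aucs <- vapply(1:6, function(s) {
    am <- zscore_ai(compute_asymmetry(
      generate_cohort(tiny_spec(n_control = 100L, n_case = 100L,
                                seed = 600L + s), atlas), atlas), "pooled_z")
    fit_lda(am, "16p11.2del")$auc
  }, numeric(1))
  expect_lt(mean(aucs), 0.65)  # in-sample optimism only
  # perfectly separated one-feature problem
  X <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "a"))
  am <- structure(list(ai = X, group = rep(c("control", "16p11.2del"),
                                           each = 20),
                       subject_id = as.character(1:40), scaling = "pooled_z",
                       center = NULL, scale = NULL, reference = NULL),
                  class = "asym_matrix")
  expect_equal(fit_lda(am, "16p11.2del")$auc, 1.0)
})

test_that("cohens_d_map obeys its symmetries", {
  atlas <- tiny_atlas()
  cohort <- generate_cohort(tiny_spec(seed = 21L), atlas)
  am <- compute_asymmetry(cohort, atlas)
  d1 <- cohens_d_map(am, "16p11.2del", "control")
  d2 <- cohens_d_map(am, "control", "16p11.2del")
  expect_equal(d1, -d2, tolerance = 1e-12)
  # identical groups: zero map
  am2 <- am
  am2$ai <- rbind(am$ai[1:10, ], am$ai[1:10, ])
  am2$group <- rep(c("control", "16p11.2del"), each = 10)
  am2$subject_id <- as.character(1:20)
  expect_equal(unname(cohens_d_map(am2, "16p11.2del")),
               rep(0, ncol(am$ai)))
})

test_that("bootstrap draws honor the sign-alignment contract", {
  atlas <- tiny_atlas()
  am <- zscore_ai(compute_asymmetry(
    generate_cohort(tiny_spec(n_control = 40L, n_case = 25L, seed = 31L,
                              effect_map = list("16p11.2del" = c(r01 = 1))),
                    atlas), atlas), "pooled_z")
  boot <- bootstrap_significance(am, "16p11.2del", B = 150L, seed = 8L)
  al <- apply(boot$draws, 2, function(w) cor(w, boot$d_map))
  expect_true(all(al >= 0 | !is.finite(al)))
  med <- apply(boot$draws, 1, stats::median)
  expect_true(all(boot$ci_low <= med + 1e-12))
  expect_true(all(med <= boot$ci_high + 1e-12))
  expect_identical(boot$significant,
                   boot$ci_low > 0 | boot$ci_high < 0)
  # determinism
  boot2 <- bootstrap_significance(am, "16p11.2del", B = 150L, seed = 8L)
  expect_identical(boot$draws, boot2$draws)
  # unstratified mode keeps both classes present in every draw
  boot3 <- bootstrap_significance(am, "16p11.2del", B = 50L, seed = 9L,
                                  stratified = FALSE)
  expect_equal(dim(boot3$draws), c(ncol(am$ai), 50L))
})

test_that("multiclass LDA has classes-1 axes and matches two-class fits", {
  atlas <- tiny_atlas()
  spec <- synthetic_spec(n_control = 20L,
                         n_per_cnv = c("16p11.2del" = 15L,
                                       "22q11.2del" = 15L,
                                       "1q21.1dup" = 15L),
                         effect_map = list("16p11.2del" = c(r01 = 1),
                                           "22q11.2del" = c(r03 = 1)),
                         site_labels = "site1", site_offset_sd = 0,
                         seed = 12L)
  am <- compute_asymmetry(generate_cohort(spec, atlas), atlas)
  mc <- fit_multiclass_lda(zscore_ai(subset_asymmetry(
    am, c("16p11.2del", "22q11.2del", "1q21.1dup")), "pooled_z"))
  expect_equal(ncol(mc$axes), 2L)
  expect_error(fit_multiclass_lda(zscore_ai(am, "pooled_z"),
                                  groups = "control"), ">= 2 classes")
  # two classes: single axis collinear with the two-class fit
  am2 <- zscore_ai(subset_asymmetry(am, c("16p11.2del", "control")),
                   "pooled_z")
  fit <- fit_lda(am2, "16p11.2del")
  mc2 <- fit_multiclass_lda(am2, groups = c("16p11.2del", "control"))
  expect_equal(ncol(mc2$axes), 1L)
  cosine <- sum(mc2$axes[, 1] * fit$coefficients) /
    sqrt(sum(mc2$axes[, 1]^2) * sum(fit$coefficients^2))
  expect_gte(abs(cosine), 0.999)
  # identical class means: no discriminability
  amn <- am
  amn$group <- rep(c("16p11.2del", "control"), length.out = nrow(amn$ai))
  mcn <- fit_multiclass_lda(zscore_ai(subset_asymmetry(
    amn, c("16p11.2del", "control")), "pooled_z"))
  expect_lt(mcn$eigenvalues[1], 0.25)
})

test_that("fits are invariant to subject order", {
  atlas <- tiny_atlas()
  am <- zscore_ai(compute_asymmetry(
    generate_cohort(tiny_spec(seed = 17L), atlas), atlas), "pooled_z")
  set.seed(4)
  perm <- sample(seq_len(nrow(am$ai)))
  am2 <- am
  am2$ai <- am$ai[perm, ]
  am2$group <- am$group[perm]
  am2$subject_id <- am$subject_id[perm]
  f1 <- fit_lda(am, "16p11.2del")
  f2 <- fit_lda(am2, "16p11.2del")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_equal(f1$auc, f2$auc, tolerance = 1e-12)
})

test_that("patterns and bootstraps serialize to TSV + JSON", {
  atlas <- tiny_atlas()
  am <- zscore_ai(compute_asymmetry(
    generate_cohort(tiny_spec(seed = 19L), atlas), atlas), "pooled_z")
  fit <- fit_lda(am, "16p11.2del")
  boot <- bootstrap_significance(am, "16p11.2del", B = 50L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern(fit, path, boot = boot)
  df <- read.delim(path)
  expect_equal(df$coefficient, unname(fit$coefficients), tolerance = 1e-12)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$B, 50L)
})
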