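test_that("default atlas has the expected pair structure", {
  atlas <- default_atlas()
  expect_equal(nrow(atlas), 65L)
  expect_equal(as.vector(table(atlas$tissue)[c("cortical", "subcortical",
                                               "cerebellar")]),
               c(48L, 7L, 10L))
  expect_false(anyDuplicated(atlas$region) > 0)
  expect_true(all(abs(sqrt(atlas$lx^2 + atlas$ly^2 + atlas$lz^2) - 1) < 1e-12))
  expect_true(all(abs(sqrt(atlas$rx^2 + atlas$ry^2 + atlas$rz^2) - 1) < 1e-12))
})

test_that("atlas JSON round-trips", {
  atlas <- default_atlas()
  path <- withr::local_tempfile(fileext = ".json")
  write_atlas(atlas, path)
  back <- read_atlas(path)
  expect_equal(back$region, atlas$region)
  expect_equal(back$lx, atlas$lx, tolerance = 1e-12)
})

test_that("cohort generation is deterministic and well-formed", {
  atlas <- tiny_atlas()
  spec <- tiny_spec(seed = 11L, n_control = 10L, n_case = 8L)
  a <- generate_cohort(spec, atlas)
  b <- generate_cohort(spec, atlas)
  expect_identical(a, b)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_equal(nrow(a), 18L)
  expect_true(all(as.matrix(a[asymkit:::volume_columns(atlas)]) > 0))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(spec, atlas)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("unknown effect-map region is rejected", {
  expect_error(generate_cohort(tiny_spec(
    effect_map = list("16p11.2del" = c(not_a_region = 1))), tiny_atlas()),
    "unknown region")
})

test_that("null cohorts show nominal per-region false-positive rates", {
  atlas <- tiny_atlas(8L, 1L, 1L)
  n_sig <- 0L
  n_tot <- 0L
  for (s in 1:12) {
    cohort <- generate_cohort(tiny_spec(n_control = 60L, n_case = 60L,
                                        seed = 100L + s), atlas)
    am <- compute_asymmetry(cohort, atlas)
    case <- am$group == "16p11.2del"
    for (j in seq_len(ncol(am$ai))) {
      p <- t.test(am$ai[case, j], am$ai[!case, j])$p.value
      n_sig <- n_sig + (p < 0.05)
      n_tot <- n_tot + 1L
    }
  }
  # 120 tests at alpha = .05: binomial 99% bounds around 6 expected hits
  expect_gte(n_sig, 0L)
  expect_lte(n_sig, 15L)
})

test_that("a planted 1-SD shift is realized as Cohen's d close to 1", {
  atlas <- default_atlas()
  d <- numeric(4)
  for (s in seq_along(d)) {
    spec <- tiny_spec(n_control = 200L, n_case = 200L,
                      effect_map = list("16p11.2del" =
                                          c(planum_temporale = 1.0)),
                      seed = 40L + s)
    am <- compute_asymmetry(generate_cohort(spec, atlas), atlas)
    d[s] <- cohens_d_map(am, "16p11.2del")["planum_temporale"]
  }
  expect_true(all(abs(d - 1) < 0.25))
  expect_lt(abs(mean(d) - 1), 0.15)
})

test_that("planted shifts can target the right hemisphere or both", {
  atlas <- default_atlas()
  for (side in c("right", "both")) {
    spec <- tiny_spec(n_control = 150L, n_case = 150L,
                      effect_map = list("16p11.2del" =
                                          c(planum_temporale = 1.0)),
                      seed = 7L, effect_side = side)
    am <- compute_asymmetry(generate_cohort(spec, atlas), atlas)
    expect_gt(cohens_d_map(am, "16p11.2del")["planum_temporale"], 0.5)
  }
})

test_that("term maps are deterministic and carry planted signal", {
  atlas <- tiny_atlas()
  units <- asymkit:::volume_columns(atlas)
  loading <- setNames(rep(c(2, 0), c(4, length(units) - 4)), units)
  a <- generate_term_maps(atlas, 5L, signal_terms = list(sig = loading),
                          noise_sd = 0.1, seed = 2L)
  b <- generate_term_maps(atlas, 5L, signal_terms = list(sig = loading),
                          noise_sd = 0.1, seed = 2L)
  expect_identical(a, b)
  expect_equal(ncol(a), 1L + length(units))
  expect_gt(mean(as.numeric(a[1, units[1:4]])), 1)
})

test_that("cohort and spec files round-trip", {
  atlas <- tiny_atlas()
  spec <- tiny_spec(seed = 5L,
                    effect_map = list("16p11.2del" = c(r01 = 0.5)))
  cohort <- generate_cohort(spec, atlas)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, cpath)
  back <- read_cohort(cpath)
  expect_equal(back$subject_id, cohort$subject_id)
  expect_equal(as.matrix(back[asymkit:::volume_columns(atlas)]),
               as.matrix(cohort[asymkit:::volume_columns(atlas)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  spath <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, spath)
  spec2 <- read_synthetic_spec(spath)
  expect_identical(generate_cohort(spec2, atlas), cohort)
})
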