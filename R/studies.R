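# Simulation studies used to calibrate and stress the pipeline: type-I error
# of the bootstrap significance procedure, power and parameter recovery with
# a planted effect, spin-test p-value uniformity, and decoding recovery.
# These run the same code paths as a real analysis on generated cohorts.

# single-site spec for calibration studies: site effects are exactly
# removable and orthogonal to these questions, so they are left out
calibration_spec <- function(n_case, n_control, effect_map, group, seed) {
  synthetic_spec(n_control = n_control,
                 n_per_cnv = setNames(as.integer(n_case), group),
                 effect_map = effect_map, site_labels = "site1",
                 site_offset_sd = 0, seed = seed)
}

#' Type-I error of bootstrap coefficient significance on null cohorts
#'
#' Generates replicate cohorts with no planted effects, runs the full
#' preprocess + fit + bootstrap path on each, and reports the fraction of
#' region coefficients flagged significant — nominally 5% for 95% percentile
#' intervals.
#'
#' @param n_rep number of replicate cohorts.
#' @param n_case,n_control group sizes per cohort.
#' @param B bootstrap draws per cohort.
#' @param seed integer master seed.
#' @param atlas atlas.
#' @return list: overall `flag_rate`, per-replicate `rates`, `n_flags`.
#' @export
study_null_flag_rate <- function(n_rep = 50L, n_case = 60L, n_control = 200L,
                                 B = 1000L, seed = 1L,
                                 atlas = default_atlas()) {
  group <- "16p11.2del"
  rates <- vapply(seq_len(n_rep), function(i) {
    spec <- calibration_spec(n_case, n_control, list(), group,
                             child_seed(seed, i))
    cohort <- generate_cohort(spec, atlas)
    am <- zscore_ai(compute_asymmetry(cohort, atlas), "pooled_z")
    boot <- bootstrap_significance(am, group, B = B,
                                   seed = child_seed(seed, 10000L + i))
    mean(boot$significant)
  }, numeric(1))
  list(flag_rate = mean(rates), rates = rates,
       n_flags = round(mean(rates) * n_rep * nrow(atlas)))
}

#' Power and parameter recovery with one planted regional effect
#'
#' Plants a shift of `shift` control-SD units of asymmetry in a single
#' region, and over replicate cohorts records how often that region is
#' flagged significant by the bootstrap and how often it carries the largest
#' absolute coefficient of the fitted pattern.
#'
#' @param n_seeds number of replicate cohorts.
#' @param shift planted AI shift in control-SD units.
#' @param region planted region name.
#' @param n_case,n_control group sizes.
#' @param B bootstrap draws.
#' @param seed integer master seed.
#' @param atlas atlas.
#' @return list: `flag_rate`, `top_coef_rate`, per-replicate logicals, and
#'   the realized per-replicate Cohen's d of the planted region's AI.
#' @export
study_planted_recovery <- function(n_seeds = 25L, shift = 1.0,
                                   region = "planum_temporale",
                                   n_case = 60L, n_control = 200L,
                                   B = 1000L, seed = 1L,
                                   atlas = default_atlas()) {
  group <- "16p11.2del"
  effect <- list(setNames(shift, region))
  names(effect) <- group
  flagged <- top <- logical(n_seeds)
  realized_d <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    spec <- calibration_spec(n_case, n_control, effect, group,
                             child_seed(seed, 500L + i))
    cohort <- generate_cohort(spec, atlas)
    am_raw <- compute_asymmetry(cohort, atlas)
    realized_d[i] <- cohens_d_map(am_raw, group)[region]
    am <- zscore_ai(am_raw, "pooled_z")
    fit <- fit_lda(am, group)
    boot <- bootstrap_significance(am, group, B = B,
                                   seed = child_seed(seed, 20000L + i))
    flagged[i] <- boot$significant[region]
    top[i] <- names(which.max(abs(fit$coefficients))) == region
  }
  list(flag_rate = mean(flagged), top_coef_rate = mean(top),
       flagged = flagged, top = top, realized_d = realized_d)
}

#' Spin-test p-value calibration on independent random maps
#'
#' Correlates pairs of independent Gaussian maps under one spin-permutation
#' null table and tests the resulting empirical p-values for uniformity.
#'
#' @param n_rep number of independent map pairs.
#' @param n_spin spins in the null table.
#' @param seed integer master seed.
#' @param atlas atlas.
#' @return list: `p_values`, and `ks_p` from a Kolmogorov-Smirnov test
#'   against the uniform distribution.
#' @export
study_spin_calibration <- function(n_rep = 200L, n_spin = 1000L, seed = 1L,
                                   atlas = default_atlas()) {
  nulls <- spin_null(atlas, n_spin = n_spin, seed = child_seed(seed, 1L))
  p <- with_seed(child_seed(seed, 2L), {
    vapply(seq_len(n_rep), function(i) {
      a <- rnorm(nrow(atlas))
      b <- rnorm(nrow(atlas))
      spin_test(a, b, nulls)$p
    }, numeric(1))
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  list(p_values = p, ks_p = ks$p.value)
}

#' Recovery of a planted term location in binned decoding
#'
#' For replicate random coefficient patterns, plants one term whose
#' activation loads on the most negative fifth of the signed bilateral map
#' and checks that its weighted-mean location lands in the low bins (1-5).
#' Also verifies that a term identical to the absolute map decodes with
#' correlation 1.
#'
#' @param n_seeds replicates.
#' @param n_terms terms per replicate table (1 planted + noise).
#' @param noise_sd activation noise SD relative to unit loading.
#' @param seed integer master seed.
#' @param atlas atlas.
#' @return list: `low_bin_rate`, per-replicate `locations`, and
#'   `identity_r` (correlation-decoding of the identity term, per replicate).
#' @export
study_decoding_recovery <- function(n_seeds = 20L, n_terms = 30L,
                                    noise_sd = 0.25, seed = 1L,
                                    atlas = default_atlas()) {
  locations <- identity_r <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    w <- with_seed(child_seed(seed, 300L + i),
                   setNames(rnorm(nrow(atlas)), atlas$region))
    signed <- bilateral_map(w, "signed")
    absolute <- bilateral_map(w, "absolute")
    k <- length(signed)
    neg_units <- names(sort(signed))[seq_len(floor(k / 5))]
    loading <- setNames(rep(1, length(neg_units)), neg_units)
    terms <- generate_term_maps(atlas, n_terms = n_terms,
                                signal_terms = list(
                                  planted_language = loading,
                                  identity = absolute),
                                noise_sd = noise_sd,
                                seed = child_seed(seed, 400L + i))
    # identity term must decode with r ~ 1 when noise-free
    terms0 <- generate_term_maps(atlas, n_terms = 1L,
                                 signal_terms = list(identity = absolute),
                                 noise_sd = 0, seed = 1L)
    identity_r[i] <- correlation_decode(absolute, terms0)$r[1]
    bd <- binned_weighted_decode(signed, terms)
    locations[i] <-
      bd$locations$location[bd$locations$term == "planted_language"]
  }
  list(low_bin_rate = mean(!is.na(locations) & locations <= 5),
       locations = locations, identity_r = identity_r)
}
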