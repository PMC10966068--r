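#' Specify a synthetic CNV cohort
#'
#' Bundles the parameters of the synthetic-cohort generator. Volumes are drawn
#' lognormal (guaranteeing the positivity the asymmetry index requires) with a
#' within-pair left/right correlation on the log scale, so that the asymmetry
#' index of an unaffected region has standard deviation close to
#' `sqrt(2 * (1 - corr_lr) * log(1 + baseline_cv^2))`. Planted effects are
#' expressed in units of that control-level AI standard deviation and applied
#' by shifting the left log-volume (the hemisphere where case-control effects
#' concentrate in this literature); `effect_side` can move the shift to the
#' right hemisphere or split it across both. Site effects are additive
#' per-(site, region, hemisphere) constants drawn once per site, the simplest
#' model that the linear site-adjustment step removes exactly.
#'
#' @param n_control number of control subjects (>= 2).
#' @param n_per_cnv named integer vector, carriers per CNV label (each >= 2).
#' @param effect_map named list: CNV label -> named numeric vector of planted
#'   AI shifts (control-SD units) keyed by atlas region name. Empty list means
#'   a null cohort.
#' @param baseline_mean mean regional volume in volume units (scalar or one
#'   value per region).
#' @param baseline_cv coefficient of variation of volumes (> 0).
#' @param corr_lr within-pair L/R log-volume correlation, in `[0, 1)`.
#' @param site_labels character vector of scanning-site labels.
#' @param site_offset_sd SD (volume units) of the additive site offsets.
#' @param age_range numeric length-2, uniform age range in years.
#' @param prop_male proportion of male subjects.
#' @param effect_side `"left"`, `"right"`, or `"both"`.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a list of class `synthetic_spec`.
#' @seealso [generate_cohort()], [demo_synthetic_spec()]
#' @export
synthetic_spec <- function(n_control = 290L,
                           n_per_cnv = c("1q21.1del" = 32L, "1q21.1dup" = 27L,
                                         "15q11.2del" = 110L, "15q11.2dup" = 144L,
                                         "16p11.2del" = 82L, "16p11.2dup" = 69L,
                                         "22q11.2del" = 66L, "22q11.2dup" = 22L),
                           effect_map = list(),
                           baseline_mean = 5000,
                           baseline_cv = 0.12,
                           corr_lr = 0.9,
                           site_labels = c("site1", "site2", "site3"),
                           site_offset_sd = 150,
                           age_range = c(6, 73),
                           prop_male = 0.55,
                           effect_side = c("left", "right", "both"),
                           seed = 1L) {
  effect_side <- match.arg(effect_side)
  spec <- list(n_control = as.integer(n_control),
               n_per_cnv = n_per_cnv, effect_map = effect_map,
               baseline_mean = baseline_mean, baseline_cv = baseline_cv,
               corr_lr = corr_lr, site_labels = site_labels,
               site_offset_sd = site_offset_sd, age_range = age_range,
               prop_male = prop_male, effect_side = effect_side,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Demonstration cohort spec with planted effects
#'
#' The packaged demo: Table-1-sized groups with planted planum temporale,
#' fusiform, and parahippocampal shifts qualitatively matching the directions
#' the per-CNV analyses are designed to recover.
#'
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
demo_synthetic_spec <- function(seed = 1L) {
  synthetic_spec(
    effect_map = list(
      "16p11.2del" = c(planum_temporale = 1.0,
                       temporal_fusiform_cortex_posterior = -0.6,
                       parahippocampal_gyrus_anterior = -0.4,
                       cerebellum_viiib = -0.5,
                       putamen = -0.4),
      "22q11.2del" = c(planum_temporale = 0.75,
                       temporal_fusiform_cortex_posterior = -0.4,
                       parahippocampal_gyrus_anterior = -0.4),
      "15q11.2dup" = c(planum_temporale = 0.5),
      "1q21.1del"  = c(planum_temporale = -0.5)),
    seed = seed)
}

validate_synthetic_spec <- function(spec, atlas) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_control < 2L) stop("n_control must be >= 2", call. = FALSE)
  if (length(spec$n_per_cnv) < 1L || any(spec$n_per_cnv < 2L)) {
    stop("every CNV group needs >= 2 subjects", call. = FALSE)
  }
  if (is.null(names(spec$n_per_cnv)) ||
      !all(names(spec$n_per_cnv) %in% setdiff(cnv_labels(), "control"))) {
    stop("n_per_cnv must be named with CNV labels from cnv_labels()",
         call. = FALSE)
  }
  if (spec$corr_lr < 0 || spec$corr_lr >= 1) {
    stop("corr_lr must lie in [0, 1)", call. = FALSE)
  }
  if (spec$baseline_cv <= 0) stop("baseline_cv must be > 0", call. = FALSE)
  if (length(spec$effect_map)) {
    if (!all(names(spec$effect_map) %in% names(spec$n_per_cnv))) {
      stop("effect_map refers to groups absent from n_per_cnv", call. = FALSE)
    }
    regions <- unique(unlist(lapply(spec$effect_map, names)))
    bad <- setdiff(regions, atlas$region)
    if (length(bad)) {
      stop("effect_map refers to unknown regions: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(spec)
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject with group label, covariates (age, sex, site),
#' and 130 paired regional volumes following the model described in
#' [synthetic_spec()]. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param atlas an atlas, e.g. [default_atlas()].
#' @return a data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `site`, then `<region>_L`, `<region>_R` for every atlas region.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_control = 20,
#'   n_per_cnv = c("16p11.2del" = 10), seed = 7), default_atlas())
#' table(cohort$group)
#' @export
generate_cohort <- function(spec, atlas = default_atlas()) {
  validate_synthetic_spec(spec, atlas)
  p <- nrow(atlas)
  sigma <- sqrt(log(1 + spec$baseline_cv^2))
  mu_log <- log(rep_len(spec$baseline_mean, p)) - sigma^2 / 2
  sd_ai <- sqrt(2 * (1 - spec$corr_lr)) * sigma
  rho <- spec$corr_lr
  groups <- c("control", names(spec$n_per_cnv))
  sizes <- c(spec$n_control, unname(spec$n_per_cnv))

  with_seed(spec$seed, {
    n_site <- length(spec$site_labels)
    # additive offsets, one per (site, region, hemisphere)
    site_off_L <- matrix(rnorm(n_site * p, 0, spec$site_offset_sd), n_site, p)
    site_off_R <- matrix(rnorm(n_site * p, 0, spec$site_offset_sd), n_site, p)
    rows <- vector("list", length(groups))
    id0 <- 0L
    for (g in seq_along(groups)) {
      n <- sizes[g]
      grp <- groups[g]
      age <- runif(n, spec$age_range[1], spec$age_range[2])
      sex <- ifelse(runif(n) < spec$prop_male, "M", "F")
      site <- spec$site_labels[sample.int(n_site, n, replace = TRUE)]
      site_idx <- match(site, spec$site_labels)
      # correlated L/R log deviates per region
      z_shared <- matrix(rnorm(n * p), n, p)
      z_l <- sqrt(rho) * z_shared + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      z_r <- sqrt(rho) * z_shared + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
      delta <- numeric(p)
      eff <- spec$effect_map[[grp]]
      if (!is.null(eff)) delta[match(names(eff), atlas$region)] <- eff * sd_ai
      shift_l <- if (spec$effect_side == "right") 0 else
        if (spec$effect_side == "both") delta / 2 else delta
      shift_r <- if (spec$effect_side == "right") -delta else
        if (spec$effect_side == "both") -delta / 2 else 0
      vol_l <- exp(sweep(sigma * z_l, 2, mu_log + shift_l, `+`)) +
        site_off_L[site_idx, , drop = FALSE]
      vol_r <- exp(sweep(sigma * z_r, 2, mu_log + shift_r, `+`)) +
        site_off_R[site_idx, , drop = FALSE]
      vols <- matrix(0, n, 2L * p)
      vols[, seq(1L, 2L * p, by = 2L)] <- vol_l
      vols[, seq(2L, 2L * p, by = 2L)] <- vol_r
      df <- data.frame(subject_id = sprintf("S%05d", id0 + seq_len(n)),
                       group = grp, age = age, sex = sex, site = site,
                       stringsAsFactors = FALSE)
      df[volume_columns(atlas)] <- vols
      rows[[g]] <- df
      id0 <- id0 + n
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    if (any(as.matrix(cohort[volume_columns(atlas)]) <= 0)) {
      stop("synthetic volumes must be strictly positive; ",
           "reduce site_offset_sd or baseline_cv", call. = FALSE)
    }
    cohort
  })
}

#' Generate synthetic term-activation maps
#'
#' Builds a term x (region, hemisphere) activation table for the decoding
#' module. Signal terms carry a user-specified spatial loading plus Gaussian
#' noise; the remaining terms are pure noise.
#'
#' @param atlas atlas defining the 2 x nrow(atlas) spatial units.
#' @param n_terms total number of terms (>= number of signal terms).
#' @param signal_terms named list: term -> named numeric loading vector keyed
#'   by `<region>_L` / `<region>_R` unit names (missing units load 0).
#' @param noise_sd SD of the additive activation noise.
#' @param seed integer seed.
#' @return a data.frame with column `term` followed by 130 activation columns.
#' @export
generate_term_maps <- function(atlas, n_terms, signal_terms = list(),
                               noise_sd = 1, seed = 1L) {
  stopifnot(n_terms >= 1L, n_terms >= length(signal_terms))
  units <- volume_columns(atlas)
  k <- length(units)
  n_noise <- n_terms - length(signal_terms)
  terms <- c(names(signal_terms),
             if (n_noise > 0) sprintf("noise_term_%03d", seq_len(n_noise)))
  with_seed(seed, {
    vals <- matrix(rnorm(n_terms * k, 0, noise_sd), n_terms, k,
                   dimnames = list(NULL, units))
    for (i in seq_along(signal_terms)) {
      loading <- signal_terms[[i]]
      idx <- match(names(loading), units)
      if (anyNA(idx)) stop("signal term '", terms[i],
                           "' refers to unknown units", call. = FALSE)
      base <- numeric(k)
      base[idx] <- loading
      vals[i, ] <- base + vals[i, ]
    }
    out <- data.frame(term = terms, stringsAsFactors = FALSE)
    out[units] <- vals
    out
  })
}

#' Cohort and term-map file I/O
#'
#' Cohorts are CSV with the column layout produced by [generate_cohort()];
#' term maps are TSV with a leading `term` column. Synthetic specs round-trip
#' through YAML.
#'
#' @param cohort,terms,spec objects to write.
#' @param path file path.
#' @return readers return the parsed object; writers return `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_cohort
#' @export
write_term_maps <- function(terms, path) {
  utils::write.table(terms, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_term_maps <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname write_cohort
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  x <- unclass(spec)
  x$n_per_cnv <- as.list(x$n_per_cnv)
  x$effect_map <- lapply(x$effect_map, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_synthetic_spec <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_spec(n_control = x$n_control,
                 n_per_cnv = unlist(x$n_per_cnv),
                 effect_map = lapply(x$effect_map, unlist),
                 baseline_mean = x$baseline_mean,
                 baseline_cv = x$baseline_cv,
                 corr_lr = x$corr_lr,
                 site_labels = unlist(x$site_labels),
                 site_offset_sd = x$site_offset_sd,
                 age_range = unlist(x$age_range),
                 prop_male = x$prop_male,
                 effect_side = x$effect_side,
                 seed = x$seed)
}
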