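#' Cohen's d standardized mean difference
#'
#' `d = (mean(x1) - mean(x2)) / sqrt((s1^2 + s2^2) / 2)` with sample SDs
#' (n-1 denominator). The denominator averages the two group variances
#' without sample-size weighting.
#'
#' @param x1,x2 numeric samples with at least two finite values each.
#' @return Cohen's d.
#' @examples
#' cohens_d(c(0, 2), c(-1, 1))  # 1 / sqrt(2)
#' @export
cohens_d <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L ||
      any(!is.finite(x1)) || any(!is.finite(x2))) {
    stop("each sample needs >= 2 finite values", call. = FALSE)
  }
  s1 <- var(x1)
  s2 <- var(x2)
  if (s1 == 0 && s2 == 0) stop("both samples have zero variance",
                               call. = FALSE)
  (mean(x1) - mean(x2)) / sqrt((s1 + s2) / 2)
}

#' Bootstrap percentile confidence interval for Cohen's d
#'
#' Resamples the two groups separately with replacement (each at its original
#' size), recomputes d on every draw, and reports the 2.5% and 97.5%
#' percentiles of the resampled distribution. Draws in which both resampled
#' groups are constant are redrawn and counted.
#'
#' @inheritParams cohens_d
#' @param B number of bootstrap draws.
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)` with attributes `B`, `seed`, and
#'   `redrawn` (degenerate draw count).
#' @export
cohens_d_bootstrap_ci <- function(x1, x2, B = 1000L, seed = 1L) {
  stopifnot(B >= 1L)
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  n1 <- length(x1)
  n2 <- length(x2)
  with_seed(seed, {
    draw_block <- function(nb) {
      i1 <- matrix(sample.int(n1, n1 * nb, replace = TRUE), n1, nb)
      i2 <- matrix(sample.int(n2, n2 * nb, replace = TRUE), n2, nb)
      X1 <- matrix(x1[i1], n1, nb)
      X2 <- matrix(x2[i2], n2, nb)
      m1 <- colMeans(X1)
      m2 <- colMeans(X2)
      v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
      v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
      v1 <- pmax(v1, 0)
      v2 <- pmax(v2, 0)
      list(d = (m1 - m2) / sqrt((v1 + v2) / 2), bad = v1 + v2 == 0)
    }
    blk <- draw_block(B)
    d <- blk$d
    bad <- blk$bad | !is.finite(d)
    redrawn <- 0L
    while (any(bad)) {
      redrawn <- redrawn + sum(bad)
      repl <- draw_block(sum(bad))
      d[bad] <- repl$d
      bad[bad] <- repl$bad | !is.finite(repl$d)
    }
    ci <- quantile(d, c(0.025, 0.975), names = FALSE)
    structure(ci, B = B, seed = seed, redrawn = redrawn)
  })
}

#' Residualize regional volumes on covariates
#'
#' Adjusts each of the 130 volume columns for intracranial volume (when
#' present), age, centered age squared, sex, and scanning site by linear
#' least squares, re-adding the grand mean so volumes keep their scale. This
#' path serves the raw-volume hemispheric effect sizes only; asymmetry
#' indices are deliberately never covariate-adjusted (the index itself is the
#' phenotype of interest and ratio-based adjustment is left to the site
#' step). Collinear design columns are dropped with a warning.
#'
#' @param cohort cohort data.frame; column `icv` is used when present and
#'   skipped with a warning otherwise.
#' @param atlas atlas defining the volume columns.
#' @return the cohort with residualized volume columns (idempotent).
#' @export
covariate_adjust_volumes <- function(cohort, atlas = default_atlas()) {
  vcols <- volume_columns(atlas)
  stopifnot(all(vcols %in% names(cohort)))
  age_c <- cohort$age - mean(cohort$age)
  design <- cbind(intercept = 1, age = age_c, age2 = age_c^2,
                  sex = as.numeric(cohort$sex == "M"))
  if ("icv" %in% names(cohort)) {
    design <- cbind(design, icv = cohort$icv - mean(cohort$icv))
  } else {
    warning("no `icv` column; adjusting without intracranial volume",
            call. = FALSE)
  }
  site <- factor(cohort$site)
  if (nlevels(site) > 1L) {
    sm <- stats::model.matrix(~ site)[, -1, drop = FALSE]
    design <- cbind(design, sm)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    warning("dropping collinear covariate column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  V <- as.matrix(cohort[vcols])
  fitted <- qr.fitted(qrd, V)
  resid <- V - fitted
  cohort[vcols] <- sweep(resid, 2, colMeans(V), `+`)
  cohort
}

#' Per-region group tests on control-referenced asymmetry
#'
#' Welch two-sided t-test of every region's control-z asymmetry index between
#' one CNV group and controls, with Benjamini-Hochberg correction across the
#' regions of the contrast. The direction label reports the sign of the mean
#' difference for regions passing the FDR threshold.
#'
#' @param am an `asym_matrix`, `control_z`-scaled.
#' @param case_label CNV group label.
#' @param control_label control label.
#' @param alpha FDR threshold for the direction call.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return data.frame with `region`, `t`, `p`, `p_fdr`, `direction`.
#' @export
ai_group_tests <- function(am, case_label, control_label = "control",
                           alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(am, "asym_matrix"))
  if (am$scaling != "control_z") {
    message("ai_group_tests: input scaling is '", am$scaling,
            "'; control_z is the intended convention")
  }
  X1 <- am$ai[am$group == case_label, , drop = FALSE]
  X0 <- am$ai[am$group == control_label, , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X0) < 2L) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  res <- vapply(seq_len(ncol(X1)), function(j) {
    tt <- t.test(X1[, j], X0[, j], var.equal = var_equal)
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  p_fdr <- p.adjust(res[2, ], method = "BH")
  delta <- colMeans(X1) - colMeans(X0)
  direction <- ifelse(p_fdr < alpha,
                      ifelse(delta > 0, "increase", "decrease"), "none")
  data.frame(region = colnames(am$ai), t = res[1, ], p = res[2, ],
             p_fdr = p_fdr, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hemispheric effect sizes with bootstrap confidence intervals
#'
#' For each atlas region, Cohen's d between carriers and controls computed
#' separately on the left and right raw volumes (typically after
#' [covariate_adjust_volumes()]), with stratified bootstrap percentile CIs.
#'
#' @param cohort cohort data.frame (volumes already adjusted as desired).
#' @param case_label,control_label group labels.
#' @param atlas atlas.
#' @param B bootstrap draws per region/hemisphere.
#' @param seed integer seed.
#' @return data.frame with `region`, `hemisphere`, `d`, `ci_low`, `ci_high`,
#'   `n_case`, `n_control`.
#' @export
hemispheric_effects <- function(cohort, case_label,
                                control_label = "control",
                                atlas = default_atlas(), B = 1000L,
                                seed = 1L) {
  case <- cohort$group == case_label
  ctrl <- cohort$group == control_label
  if (sum(case) < 2L || sum(ctrl) < 2L) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  rows <- expand.grid(region = atlas$region, hemisphere = c("L", "R"),
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$region, atlas$region)), ]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    col <- paste0(rows$region[i], "_", rows$hemisphere[i])
    x1 <- cohort[[col]][case]
    x2 <- cohort[[col]][ctrl]
    ci <- cohens_d_bootstrap_ci(x1, x2, B = B, seed = child_seed(seed, i))
    data.frame(region = rows$region[i], hemisphere = rows$hemisphere[i],
               d = cohens_d(x1, x2), ci_low = ci[1], ci_high = ci[2],
               n_case = length(x1), n_control = length(x2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation of pattern coefficients with control asymmetry
#'
#' Pearson correlation (with two-sided p-value) between a fitted pattern's
#' 65 coefficients and the control group's mean raw asymmetry index per
#' region — the check that learned CNV effects are not simply recapitulating
#' baseline regional asymmetry.
#'
#' @param pattern an `lda_pattern`.
#' @param am_raw an `asym_matrix` with `raw` scaling containing controls.
#' @param control_label control label.
#' @return list with `r`, `p`, and the control mean-AI vector.
#' @export
coef_vs_control_asymmetry <- function(pattern, am_raw,
                                      control_label = "control") {
  stopifnot(inherits(pattern, "lda_pattern"), inherits(am_raw, "asym_matrix"))
  ctrl <- am_raw$group == control_label
  if (!any(ctrl)) stop("control group is empty", call. = FALSE)
  m <- colMeans(am_raw$ai[ctrl, , drop = FALSE])
  w <- pattern$coefficients[names(m)]
  if (sd(w) == 0 || sd(m) == 0) stop("zero variance input", call. = FALSE)
  ct <- cor.test(w, m)
  list(r = unname(ct$estimate), p = ct$p.value, control_mean_ai = m)
}
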