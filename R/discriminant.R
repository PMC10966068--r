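# Core pattern-learning stage: two-class and multiclass linear discriminant
# analysis on asymmetry indices, with analytic shrinkage of the pooled
# within-class covariance toward its diagonal (65 features against as few as
# 22 carriers makes the plain estimator unstable).

# pooled within-class covariance with analytic diagonal shrinkage.
# Returns list(S = shrunken covariance, lambda, ridge_used).
shrunken_within_cov <- function(X, y, shrinkage = NULL, extra_ridge = 0) {
  classes <- unique(y)
  n <- nrow(X)
  p <- ncol(X)
  Xc <- X
  for (cl in classes) {
    idx <- y == cl
    Xc[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                       colMeans(X[idx, , drop = FALSE]))
  }
  dof <- n - length(classes)
  S <- crossprod(Xc) / dof
  if (is.null(shrinkage)) {
    # variance of the off-diagonal entries estimated from the centered
    # cross-products (Schaefer-Strimmer-style target: the diagonal of S)
    W2 <- crossprod(Xc^2)
    Wbar <- crossprod(Xc) / n
    varS <- (n / (n - 1)^3) * (W2 - n * Wbar^2)
    Su <- crossprod(Xc) / (n - 1)
    off <- !diag(p)
    denom <- sum(Su[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(varS[off]) / denom))
  } else {
    lambda <- shrinkage
  }
  St <- (1 - lambda) * S
  diag(St) <- diag(S)
  ridge_used <- 0
  if (any(diag(St) <= 0) || extra_ridge > 0) {
    ridge_used <- max(extra_ridge, 1e-8) * mean(pmax(diag(St), 1e-12))
    diag(St) <- diag(St) + ridge_used
  }
  list(S = St, lambda = lambda, ridge = ridge_used)
}

# solve S w = b with a minimal-ridge fallback for singular S
solve_spd <- function(S, b, warn = TRUE) {
  w <- tryCatch(drop(solve(S, b)), error = function(e) NULL)
  if (is.null(w)) {
    if (warn) warning("singular covariance; applying minimal ridge",
                      call. = FALSE)
    eps <- 1e-8 * mean(diag(S))
    repeat {
      w <- tryCatch(drop(solve(S + diag(eps, nrow(S)), b)),
                    error = function(e) NULL)
      if (!is.null(w)) break
      eps <- eps * 10
    }
  }
  w
}

# coefficient vector of the two-class discriminant: solve(Sigma, mu1 - mu0)
lda_coefficients <- function(X, case_idx, shrinkage = NULL, extra_ridge = 0,
                             warn = TRUE) {
  mu1 <- colMeans(X[case_idx, , drop = FALSE])
  mu0 <- colMeans(X[!case_idx, , drop = FALSE])
  cov <- shrunken_within_cov(X, as.integer(case_idx), shrinkage = shrinkage,
                             extra_ridge = extra_ridge)
  w <- solve_spd(cov$S, mu1 - mu0, warn = warn)
  list(w = w, mu1 = mu1, mu0 = mu0, lambda = cov$lambda)
}

#' Fit a two-class discriminant asymmetry pattern
#'
#' Learns the linear pattern separating carriers of one CNV from controls on
#' z-scored asymmetry indices. Coefficients are the closed-form discriminant
#' direction `solve(Sigma, mu_case - mu_control)` with `Sigma` the pooled
#' within-class covariance shrunk toward its diagonal (intensity chosen
#' analytically from the data unless fixed via `shrinkage`). The fitted
#' vector is canonically oriented so that it correlates non-negatively with
#' the per-region Cohen's d map of the same contrast — the same reflection
#' convention the bootstrap uses — and the in-sample ROC AUC of the
#' discriminant scores is reported.
#'
#' @param am an `asym_matrix`, ideally `pooled_z`-scaled over exactly the two
#'   classes entering the fit (see [zscore_ai()]).
#' @param case_label CNV group label.
#' @param control_label control group label.
#' @param shrinkage optional fixed shrinkage intensity in `[0, 1]`.
#' @return an object of class `lda_pattern`: named 65-coefficient vector,
#'   intercept, in-sample `auc`, discriminant `scores`, class sizes, the
#'   shrinkage used, and the Cohen's d map used for orientation.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_control = 60,
#'   n_per_cnv = c("16p11.2del" = 30),
#'   effect_map = list("16p11.2del" = c(planum_temporale = 1)),
#'   site_labels = "site1", seed = 3))
#' am <- zscore_ai(compute_asymmetry(cohort), "pooled_z")
#' fit <- fit_lda(am, "16p11.2del")
#' head(sort(abs(fit$coefficients), decreasing = TRUE))
#' @export
fit_lda <- function(am, case_label, control_label = "control",
                    shrinkage = NULL) {
  stopifnot(inherits(am, "asym_matrix"))
  stop_if_not_scalar_label(case_label, "case_label")
  keep <- am$group %in% c(case_label, control_label)
  X <- am$ai[keep, , drop = FALSE]
  y <- am$group[keep]
  n1 <- sum(y == case_label)
  n0 <- sum(y == control_label)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 subjects per class", call. = FALSE)
  if (am$scaling != "pooled_z") {
    message("fit_lda: input scaling is '", am$scaling,
            "'; pooled_z over the two classes is the intended convention")
  }
  fit <- lda_coefficients(X, y == case_label, shrinkage = shrinkage)
  w <- fit$w
  dmap <- cohens_d_map(am, case_label, control_label)
  r <- suppressWarnings(cor(w, dmap))
  if (is.finite(r) && r < 0) w <- -w
  intercept <- -0.5 * sum((fit$mu1 + fit$mu0) * w)
  scores <- drop(X %*% w) + intercept
  auc <- roc_auc(scores, as.integer(y == case_label))
  structure(list(group = case_label, control = control_label,
                 coefficients = setNames(w, colnames(am$ai)),
                 intercept = intercept, auc = auc,
                 scores = setNames(scores, am$subject_id[keep]),
                 labels = y, n_case = n1, n_control = n0,
                 shrinkage = fit$lambda, d_map = dmap),
            class = "lda_pattern")
}

#' @export
print.lda_pattern <- function(x, ...) {
  cat(sprintf("LDA asymmetry pattern: %s vs %s (n = %d / %d)\n",
              x$group, x$control, x$n_case, x$n_control))
  cat(sprintf("  in-sample AUC %.3f, shrinkage %.3f\n", x$auc, x$shrinkage))
  top <- sort(abs(x$coefficients), decreasing = TRUE)[1:5]
  cat("  strongest |coefficients|:",
      paste(sprintf("%s (%.2f)", names(top),
                    x$coefficients[names(top)]), collapse = ", "), "\n")
  invisible(x)
}

#' Per-region Cohen's d map for a case-control contrast
#'
#' Computes `d = (mean_case - mean_control) / sqrt((s1^2 + s2^2) / 2)` for
#' every region of an asymmetry matrix (sample SDs). This is the map used to
#' resolve the sign invariance of discriminant fits.
#'
#' @inheritParams fit_lda
#' @return a named numeric vector, one d per region.
#' @export
cohens_d_map <- function(am, case_label, control_label = "control") {
  stopifnot(inherits(am, "asym_matrix"))
  X1 <- am$ai[am$group == case_label, , drop = FALSE]
  X0 <- am$ai[am$group == control_label, , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X0) < 2L) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  m1 <- colMeans(X1)
  m0 <- colMeans(X0)
  v1 <- apply(X1, 2, var)
  v0 <- apply(X0, 2, var)
  denom <- sqrt((v1 + v0) / 2)
  if (any(denom == 0)) stop("zero pooled SD for region(s): ",
                            paste(colnames(am$ai)[denom == 0], collapse = ", "),
                            call. = FALSE)
  (m1 - m0) / denom
}

#' Bootstrap significance of discriminant coefficients
#'
#' Refits the two-class discriminant on `B` bootstrap draws of the cohort and
#' flags coefficients whose 2.5/97.5% percentile interval excludes zero.
#' Because a discriminant direction is only identified up to reflection, each
#' draw's coefficient vector is multiplied by +1 or -1 so that its Pearson
#' correlation with the full-sample Cohen's d map is non-negative before
#' percentiles are taken. By default resampling is stratified: carriers and
#' controls are resampled separately at their original sizes, which keeps the
#' overall sample size fixed and guarantees both classes are present; with
#' `stratified = FALSE` the pooled cohort is resampled and draws missing a
#' class are redrawn. Draws with a zero-variance region are refit with
#' increased shrinkage rather than discarded.
#'
#' @inheritParams fit_lda
#' @param B number of bootstrap draws.
#' @param seed integer seed (results are deterministic given the seed).
#' @param stratified resample within class (default) or pooled.
#' @return an object of class `lda_bootstrap`: `draws` (regions x B matrix of
#'   sign-aligned coefficients), `ci_low`, `ci_high`, `significant`,
#'   `d_map`, `B`, `seed`, and the count of degenerate draws repaired.
#' @export
bootstrap_significance <- function(am, case_label, control_label = "control",
                                   B = 1000L, seed = 1L, shrinkage = NULL,
                                   stratified = TRUE) {
  stopifnot(inherits(am, "asym_matrix"), B >= 1L)
  keep <- am$group %in% c(case_label, control_label)
  X <- am$ai[keep, , drop = FALSE]
  case <- am$group[keep] == case_label
  idx1 <- which(case)
  idx0 <- which(!case)
  if (length(idx1) < 2L || length(idx0) < 2L) {
    stop("need >= 2 subjects per class", call. = FALSE)
  }
  dmap <- cohens_d_map(am, case_label, control_label)
  p <- ncol(X)
  draws <- matrix(NA_real_, p, B, dimnames = list(colnames(X), NULL))
  degenerate <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      if (stratified) {
        rows <- c(idx1[sample.int(length(idx1), replace = TRUE)],
                  idx0[sample.int(length(idx0), replace = TRUE)])
      } else {
        repeat {
          rows <- sample.int(nrow(X), replace = TRUE)
          if (any(case[rows]) && any(!case[rows])) break
        }
      }
      Xb <- X[rows, , drop = FALSE]
      yb <- case[rows]
      zero_var <- any(apply(Xb[yb, , drop = FALSE], 2, var) +
                        apply(Xb[!yb, , drop = FALSE], 2, var) == 0)
      w <- if (zero_var) {
        degenerate <- degenerate + 1L
        lda_coefficients(Xb, yb, shrinkage = 1, extra_ridge = 1e-4,
                         warn = FALSE)$w
      } else {
        lda_coefficients(Xb, yb, shrinkage = shrinkage, warn = FALSE)$w
      }
      r <- suppressWarnings(cor(w, dmap))
      if (is.finite(r) && r < 0) w <- -w
      draws[, b] <- w
    }
  })
  ci <- apply(draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(draws = draws, ci_low = ci[1, ], ci_high = ci[2, ],
                 significant = ci[1, ] > 0 | ci[2, ] < 0,
                 d_map = dmap, B = B, seed = seed,
                 degenerate_draws = degenerate,
                 group = case_label, control = control_label),
            class = "lda_bootstrap")
}

#' @export
print.lda_bootstrap <- function(x, ...) {
  cat(sprintf("bootstrap of LDA coefficients: %s vs %s, B = %d\n",
              x$group, x$control, x$B))
  sig <- names(x$significant)[x$significant]
  cat(sprintf("  %d/%d regions significant (95%% percentile CI excluding 0)\n",
              length(sig), length(x$significant)))
  if (length(sig)) cat("  ", paste(utils::head(sig, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Multiclass discriminant projection across CNV groups
#'
#' Fits one discriminant model separating all supplied classes simultaneously
#' by eigen-decomposition of the within-class-whitened between-class scatter
#' (within-class covariance shrunk exactly as in [fit_lda()]). The number of
#' discriminant axes equals the number of classes minus one; axes are ordered
#' by decreasing discriminability (eigenvalue) and the loadings of the two
#' leading axes are the usual plotting coordinates for region effects.
#'
#' @param am an `asym_matrix`, ideally `pooled_z`-scaled over all classes.
#' @param groups labels to include (default: every group in the matrix).
#' @param shrinkage optional fixed shrinkage intensity.
#' @return an object of class `multiclass_lda`: `axes` (regions x (k-1)
#'   matrix), `eigenvalues`, `class_means` (latent coordinates of each class),
#'   `classes`, and `loadings` (leading two axes).
#' @export
fit_multiclass_lda <- function(am, groups = NULL, shrinkage = NULL) {
  stopifnot(inherits(am, "asym_matrix"))
  groups <- groups %||% sort(unique(am$group))
  am <- subset_asymmetry(am, groups)
  y <- factor(am$group, levels = groups)
  k <- nlevels(y)
  if (k < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < 2L)) stop("need >= 2 subjects per class", call. = FALSE)
  X <- am$ai
  p <- ncol(X)
  cov <- shrunken_within_cov(X, as.integer(y), shrinkage = shrinkage)
  M <- rowsum(X, y) / as.vector(table(y))
  grand <- colMeans(X)
  Mc <- sweep(M, 2, grand)
  nb <- as.vector(table(y))
  Sb <- crossprod(Mc * sqrt(nb)) / nrow(X)
  R <- tryCatch(chol(cov$S), error = function(e) {
    warning("singular covariance; applying minimal ridge", call. = FALSE)
    chol(cov$S + diag(1e-8 * mean(diag(cov$S)), p))
  })
  # symmetric whitened between-class scatter: R^-T Sb R^-1
  A <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)), transpose = TRUE)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  n_axes <- k - 1L
  V <- backsolve(R, eig$vectors[, seq_len(n_axes), drop = FALSE])
  # unit-norm axes with a deterministic sign convention
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("LD", seq_len(n_axes)))
  structure(list(axes = V, eigenvalues = pmax(eig$values[seq_len(n_axes)], 0),
                 class_means = M %*% V, classes = groups,
                 loadings = V[, seq_len(min(2L, n_axes)), drop = FALSE]),
            class = "multiclass_lda")
}

#' @export
print.multiclass_lda <- function(x, ...) {
  cat(sprintf("multiclass LDA: %d classes, %d discriminant axes\n",
              length(x$classes), ncol(x$axes)))
  cat("  discriminability (leading axes):",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)), collapse = ", "),
      "\n")
  invisible(x)
}

#' ROC area under the curve by rank statistic
#'
#' Computes the probability that a randomly chosen case scores higher than a
#' randomly chosen control, with ties counted half (the Mann-Whitney
#' formulation of the AUC).
#'
#' @param scores numeric discriminant scores.
#' @param labels binary labels (1/TRUE = case).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write a fitted pattern and its bootstrap as TSV + JSON metadata
#'
#' @param pattern an `lda_pattern`.
#' @param boot optional matching `lda_bootstrap`.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path, boot = NULL) {
  stopifnot(inherits(pattern, "lda_pattern"))
  df <- data.frame(region = names(pattern$coefficients),
                   coefficient = unname(pattern$coefficients),
                   stringsAsFactors = FALSE)
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "lda_bootstrap"))
    df$ci_low <- unname(boot$ci_low)
    df$ci_high <- unname(boot$ci_high)
    df$significant <- unname(boot$significant)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(group = pattern$group, control = pattern$control,
               n_case = pattern$n_case, n_control = pattern$n_control,
               auc = pattern$auc, shrinkage = pattern$shrinkage,
               B = if (!is.null(boot)) boot$B,
               seed = if (!is.null(boot)) boot$seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
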