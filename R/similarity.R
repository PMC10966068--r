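# Comparison of whole-brain coefficient maps: Pearson similarity with
# spin-permutation spatial nulls, BH-FDR across pairs, and Ward clustering.

#' Pearson correlation between two region-wise patterns
#'
#' @param a,b equal-length numeric vectors with nonzero variance.
#' @return Pearson r.
#' @export
pattern_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("patterns differ in length", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance pattern", call. = FALSE)
  cor(a, b)
}

# uniform random rotation on SO(3) from a normalized Gaussian quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Spatial null permutations for parcellated brain maps
#'
#' Builds `n_spin` region reassignments for the spin-permutation test. Each
#' spin applies one uniform random rotation (normalized-quaternion sampling,
#' exactly uniform on SO(3)) to the left-hemisphere cortical centroids — with
#' its x-flip conjugate implicitly applied to the mirror-symmetric right
#' hemisphere — and reassigns every cortical region the index of the nearest
#' rotated centroid (duplicate assignments are permitted, as usual for
#' parcel-level spins). Spherical rotation is not geometrically meaningful
#' for subcortex and cerebellum, so those regions are instead permuted
#' uniformly at random within their tissue class. Ties in the
#' nearest-centroid search resolve to the lowest region index.
#'
#' @param atlas atlas with unit-sphere centroids.
#' @param n_spin number of spins (>= 1).
#' @param seed integer seed.
#' @return an `n_spin` x nregions integer matrix of class `spin_null`;
#'   row `s` maps each region to the region whose value it receives.
#' @export
spin_null <- function(atlas = default_atlas(), n_spin = 1000L, seed = 1L) {
  validate_atlas(atlas)
  if (n_spin < 1L) stop("n_spin must be >= 1", call. = FALSE)
  cort <- which(atlas$tissue == "cortical")
  other <- split(which(atlas$tissue != "cortical"),
                 atlas$tissue[atlas$tissue != "cortical"])
  C <- as.matrix(atlas[cort, c("lx", "ly", "lz")])
  perms <- matrix(NA_integer_, n_spin, nrow(atlas))
  with_seed(seed, {
    for (s in seq_len(n_spin)) {
      R <- random_rotation()
      rotated <- C %*% t(R)
      # cosine similarity doubles as negative distance on the unit sphere
      sim <- C %*% t(rotated)
      nearest <- apply(sim, 1, which.max)
      row <- seq_len(nrow(atlas))
      row[cort] <- cort[nearest]
      for (idx in other) row[idx] <- idx[sample.int(length(idx))]
      perms[s, ] <- row
    }
  })
  structure(perms, class = c("spin_null", "matrix"),
            seed = seed, n_spin = n_spin)
}

#' Spin-permutation test of map similarity
#'
#' Compares the observed Pearson correlation of two region-wise maps against
#' the distribution obtained by re-correlating `a` with spatially rotated
#' versions of `b`. The empirical p-value is two-sided with add-one
#' smoothing, `p = (1 + #{|r_null| >= |r_obs|}) / (1 + n_spin)`, so the
#' smallest attainable p is `1 / (n_spin + 1)` and p is never zero.
#'
#' @param a,b numeric vectors in atlas region order.
#' @param null_table a [spin_null()] permutation table.
#' @return list of class `spin_test`: `r_obs`, `null_r`, `p`, `n_spin`.
#' @export
spin_test <- function(a, b, null_table) {
  stopifnot(inherits(null_table, "spin_null"))
  n_spin <- nrow(null_table)
  if (length(a) != ncol(null_table) || length(b) != ncol(null_table)) {
    stop("maps must match the atlas the null was built for", call. = FALSE)
  }
  r_obs <- pattern_correlation(a, b)
  B <- matrix(b[t(null_table)], ncol = n_spin)  # regions x spins
  sds <- apply(B, 2, sd)
  null_r <- rep(0, n_spin)
  ok <- sds > 0
  if (!all(ok)) warning(sum(!ok), " degenerate spin(s) set to r = 0",
                        call. = FALSE)
  if (any(ok)) null_r[ok] <- drop(cor(a, B[, ok, drop = FALSE]))
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (1 + n_spin)
  structure(list(r_obs = r_obs, null_r = null_r, p = p, n_spin = n_spin),
            class = "spin_test")
}

#' Benjamini-Hochberg adjusted p-values with rejection flags
#'
#' Thin wrapper over the standard step-up procedure, returned together with
#' the flags at level `q` so callers get one consistent FDR routine. The
#' rejection rule is `p_fdr <= q`, matching the step-up definition at the
#' boundary.
#'
#' @param p numeric vector of p-values.
#' @param q FDR level.
#' @return data.frame with `p`, `p_fdr`, `significant`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  p_fdr <- p.adjust(p, method = "BH")
  data.frame(p = p, p_fdr = p_fdr, significant = p_fdr <= q)
}

#' Pairwise similarity of coefficient patterns with spin p-values
#'
#' Convenience wrapper: Pearson r for every pattern pair, spin-permutation
#' empirical p-values, and BH-FDR across the pairs.
#'
#' @param patterns named list of equal-length coefficient vectors.
#' @param null_table a [spin_null()] table matching the vectors' atlas.
#' @param q FDR level.
#' @return list with matrices `r`, `p`, `p_fdr` (labels on dimnames).
#' @export
pattern_similarity_matrix <- function(patterns, null_table, q = 0.05) {
  k <- length(patterns)
  stopifnot(k >= 2L, !is.null(names(patterns)))
  labs <- names(patterns)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(r) <- 1
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  for (i in seq_len(nrow(pairs))) {
    st <- spin_test(patterns[[pairs[i, 1]]], patterns[[pairs[i, 2]]],
                    null_table)
    r[pairs[i, 1], pairs[i, 2]] <- r[pairs[i, 2], pairs[i, 1]] <- st$r_obs
    p[pairs[i, 1], pairs[i, 2]] <- p[pairs[i, 2], pairs[i, 1]] <- st$p
  }
  p_fdr <- p
  p_fdr[upper.tri(p_fdr)] <- p.adjust(p[upper.tri(p)], method = "BH")
  p_fdr[lower.tri(p_fdr)] <- t(p_fdr)[lower.tri(p_fdr)]
  list(r = r, p = p, p_fdr = p_fdr)
}

#' Ward hierarchical clustering of coefficient patterns
#'
#' Agglomerative clustering of pattern vectors with Ward's minimum-variance
#' linkage on Euclidean distances (the `ward.D2` criterion, whose merge
#' heights are non-decreasing).
#'
#' @param patterns named list of equal-length numeric vectors with unique
#'   labels.
#' @param k optional number of flat clusters to cut.
#' @return list of class `ward_clust`: the `hclust` object, `labels`, and
#'   optionally `clusters` (named membership vector at `k`).
#' @export
ward_cluster <- function(patterns, k = NULL) {
  if (length(patterns) < 2L) stop("need >= 2 patterns", call. = FALSE)
  labs <- names(patterns)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("patterns must carry unique labels", call. = FALSE)
  }
  X <- do.call(rbind, patterns)
  rownames(X) <- labs
  hc <- hclust(dist(X), method = "ward.D2")
  out <- list(hclust = hc, labels = labs,
              clusters = if (!is.null(k)) stats::cutree(hc, k = k))
  class(out) <- "ward_clust"
  out
}

#' @export
print.ward_clust <- function(x, ...) {
  cat("Ward clustering of", length(x$labels), "patterns; merge heights:",
      paste(sprintf("%.3f", x$hclust$height), collapse = ", "), "\n")
  invisible(x)
}
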