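# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorized shortcuts) so that agreement is evidence,
# not tautology.

oracle_ai <- function(l, r) {
  out <- numeric(length(l))
  for (i in seq_along(l)) out[i] <- (l[i] - r[i]) / ((l[i] + r[i]) / 2)
  out
}

# two-pass Cohen's d with explicit loops
oracle_cohens_d <- function(x1, x2) {
  m1 <- 0; for (v in x1) m1 <- m1 + v; m1 <- m1 / length(x1)
  m2 <- 0; for (v in x2) m2 <- m2 + v; m2 <- m2 / length(x2)
  s1 <- 0; for (v in x1) s1 <- s1 + (v - m1)^2; s1 <- s1 / (length(x1) - 1)
  s2 <- 0; for (v in x2) s2 <- s2 + (v - m2)^2; s2 <- s2 / (length(x2) - 1)
  (m1 - m2) / sqrt((s1 + s2) / 2)
}

# two-pass Pearson correlation
oracle_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# Benjamini-Hochberg by the step-up definition: find the largest k with
# p_(k) <= k q / m, reject all p <= p_(k); adjusted p by the cummin identity
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

oracle_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    adj[o[i]] <- min(1, best)
  }
  adj
}

# Ward merge heights by the Lance-Williams recurrence on squared Euclidean
# distances (heights reported on the distance scale, as ward.D2 does)
oracle_ward_heights <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    for (k in active) {
      if (k != i && k != j) {
        newd <- ((sizes[i] + sizes[k]) * d2[i, k] +
                   (sizes[j] + sizes[k]) * d2[j, k] -
                   sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
        d2[i, k] <- d2[k, i] <- newd
      }
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# small atlas for cheap cohorts in module tests
tiny_atlas <- function(n_cort = 6L, n_sub = 2L, n_cer = 2L) {
  pts <- asymkit:::fibonacci_sphere(n_cort + n_sub + n_cer)
  atlas <- data.frame(
    region = sprintf("r%02d", seq_len(n_cort + n_sub + n_cer)),
    tissue = rep(c("cortical", "subcortical", "cerebellar"),
                 c(n_cort, n_sub, n_cer)),
    lx = pts[, 1], ly = pts[, 2], lz = pts[, 3],
    rx = -pts[, 1], ry = pts[, 2], rz = pts[, 3],
    stringsAsFactors = FALSE)
  class(atlas) <- c("asym_atlas", "data.frame")
  atlas
}

tiny_spec <- function(n_control = 30L, n_case = 20L, effect_map = list(),
                      seed = 1L, group = "16p11.2del", ...) {
  synthetic_spec(n_control = n_control,
                 n_per_cnv = setNames(as.integer(n_case), group),
                 effect_map = effect_map, site_labels = "site1",
                 site_offset_sd = 0, seed = seed, ...)
}
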