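#' Remove scanning-site offsets from regional volumes
#'
#' Adjusts every regional volume column for additive site effects by
#' least-squares on site indicator variables: each volume is replaced by its
#' residual from the site-mean fit plus the grand mean, so post-adjustment
#' site means are equal while the overall level is retained. The fit pools
#' all subjects (controls and carriers); when group composition differs
#' strongly across sites this can absorb some group signal, so a message is
#' emitted when sites are unbalanced in group composition. Sites contributing
#' a single subject cannot be adjusted and are passed through with a warning.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param atlas atlas defining the volume columns.
#' @return the cohort with adjusted volume columns (idempotent).
#' @export
adjust_site <- function(cohort, atlas = default_atlas()) {
  vcols <- volume_columns(atlas)
  stopifnot(all(vcols %in% names(cohort)), "site" %in% names(cohort))
  site <- as.character(cohort$site)
  counts <- table(site)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons)) {
    warning("site(s) with a single subject passed through unadjusted: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  adjustable <- !(site %in% singletons)
  if (length(unique(site[adjustable])) < 2L) return(cohort)
  if ("group" %in% names(cohort)) {
    tab <- table(site[adjustable], cohort$group[adjustable])
    if (nrow(tab) > 1L && ncol(tab) > 1L) {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (max(abs(tab - expected) / pmax(expected, 1)) > 0.5) {
        message("adjust_site: sites are unbalanced in group composition; ",
                "joint site fit may absorb group signal")
      }
    }
  }
  V <- as.matrix(cohort[vcols])
  sub <- V[adjustable, , drop = FALSE]
  f <- factor(site[adjustable])
  grand <- colMeans(sub)
  site_means <- rowsum(sub, f) / as.vector(table(f))
  adj <- sub - site_means[as.integer(f), , drop = FALSE] +
    matrix(grand, nrow(sub), ncol(sub), byrow = TRUE)
  V[adjustable, ] <- adj
  if (any(V <= 0)) {
    warning("site adjustment produced nonpositive volumes; check offsets",
            call. = FALSE)
  }
  cohort[vcols] <- V
  cohort
}

#' Asymmetry index of a left/right volume pair
#'
#' `AI = (L - R) / ((L + R) / 2)`; a positive value signifies leftward
#' asymmetry (larger left volume), a negative value rightward asymmetry.
#' For strictly positive volumes AI lies in (-2, 2), and it is invariant to
#' rescaling both volumes by the same positive factor.
#'
#' @param left,right strictly positive volumes (vectorized).
#' @return numeric AI values.
#' @examples
#' asymmetry_index(1.5, 0.5)  # 1: strongly leftward
#' @export
asymmetry_index <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right)) ||
      any(left <= 0) || any(right <= 0)) {
    stop("volumes must be finite and strictly positive", call. = FALSE)
  }
  (left - right) / ((left + right) / 2)
}

#' Compute the subjects x regions asymmetry matrix
#'
#' Applies [asymmetry_index()] to every homologous pair, keeping subject
#' grouping alongside so downstream stages can subset by label.
#'
#' @param cohort cohort data.frame.
#' @param atlas atlas defining the pairs.
#' @return an object of class `asym_matrix`: list with `ai` (subjects x
#'   regions matrix), `group` (character), `subject_id`, `scaling`
#'   (`"raw"`, `"control_z"`, or `"pooled_z"`), and when scaled the
#'   per-region reference `center`/`scale` and `reference` description.
#' @export
compute_asymmetry <- function(cohort, atlas = default_atlas()) {
  vcols <- volume_columns(atlas)
  stopifnot(all(vcols %in% names(cohort)))
  L <- as.matrix(cohort[paste0(atlas$region, "_L")])
  R <- as.matrix(cohort[paste0(atlas$region, "_R")])
  ai <- asymmetry_index(L, R)
  dimnames(ai) <- list(cohort$subject_id, atlas$region)
  structure(list(ai = ai, group = as.character(cohort$group),
                 subject_id = cohort$subject_id, scaling = "raw",
                 center = NULL, scale = NULL, reference = NULL),
            class = "asym_matrix")
}

#' @export
print.asym_matrix <- function(x, ...) {
  cat(sprintf("asymmetry matrix: %d subjects x %d regions (scaling: %s)\n",
              nrow(x$ai), ncol(x$ai), x$scaling))
  tab <- table(x$group)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset an asymmetry matrix by group label
#'
#' @param am an `asym_matrix`.
#' @param groups labels to keep.
#' @return an `asym_matrix` restricted to the requested groups.
#' @export
subset_asymmetry <- function(am, groups) {
  stopifnot(inherits(am, "asym_matrix"))
  keep <- am$group %in% groups
  if (!any(keep)) stop("no subjects in requested groups", call. = FALSE)
  am$ai <- am$ai[keep, , drop = FALSE]
  am$group <- am$group[keep]
  am$subject_id <- am$subject_id[keep]
  am
}

#' Z-score asymmetry indices
#'
#' Two conventions are supported. `control_z` standardizes every region by
#' the control group's mean and SD, putting all groups on the control
#' reference scale (used for the univariate group tests). `pooled_z`
#' standardizes by the mean and SD of all subjects currently in the matrix —
#' for model fitting the matrix should first be subset to the target CNV
#' group plus controls, so scaling spans exactly the participants entering
#' the fit. Sample SDs (n-1 denominator) are used throughout. Applying the
#' same call twice is idempotent because reference statistics are recomputed
#' from already-standardized values.
#'
#' @param am an `asym_matrix` (any scaling).
#' @param mode `"control_z"` or `"pooled_z"`.
#' @param reference_group label of the reference group for `control_z`.
#' @return the rescaled `asym_matrix` with provenance recorded.
#' @export
zscore_ai <- function(am, mode = c("control_z", "pooled_z"),
                      reference_group = "control") {
  stopifnot(inherits(am, "asym_matrix"))
  mode <- match.arg(mode)
  if (mode == "control_z") {
    ref <- am$group == reference_group
    if (!any(ref)) stop("reference group '", reference_group,
                        "' is empty", call. = FALSE)
    X <- am$ai[ref, , drop = FALSE]
  } else {
    X <- am$ai
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale == 0)) {
    stop("zero reference SD for region(s): ",
         paste(colnames(X)[scale == 0], collapse = ", "), call. = FALSE)
  }
  am$ai <- sweep(sweep(am$ai, 2, center), 2, scale, `/`)
  am$scaling <- mode
  am$center <- center
  am$scale <- scale
  am$reference <- if (mode == "control_z") reference_group else
    paste(sort(unique(am$group)), collapse = "+")
  am
}

#' Write / read an asymmetry matrix as TSV plus JSON sidecar
#'
#' The TSV holds `subject_id`, `group`, then one column per region; the
#' sidecar (`<path>.json`) records the scaling mode and reference statistics
#' so the provenance travels with the file.
#'
#' @param am an `asym_matrix`.
#' @param path TSV path.
#' @return `write_asymmetry()` returns `path` invisibly; `read_asymmetry()`
#'   rebuilds the `asym_matrix`.
#' @export
write_asymmetry <- function(am, path) {
  stopifnot(inherits(am, "asym_matrix"))
  df <- data.frame(subject_id = am$subject_id, group = am$group,
                   stringsAsFactors = FALSE)
  df[colnames(am$ai)] <- am$ai
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(scaling = am$scaling, reference = am$reference,
               center = as.list(am$center %||% list()),
               scale = as.list(am$scale %||% list()))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_asymmetry
#' @export
read_asymmetry <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  ai <- as.matrix(df[setdiff(names(df), c("subject_id", "group"))])
  rownames(ai) <- df$subject_id
  structure(list(ai = ai, group = df$group, subject_id = df$subject_id,
                 scaling = meta$scaling,
                 center = if (length(meta$center)) unlist(meta$center),
                 scale = if (length(meta$scale)) unlist(meta$scale),
                 reference = meta$reference),
            class = "asym_matrix")
}
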