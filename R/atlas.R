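#' Packaged 65-pair brain atlas fixture
#'
#' Returns the default parcellation used throughout the package: 65 homologous
#' left/right region pairs (48 cortical regions following Harvard-Oxford
#' naming, 7 subcortical structures, and 10 cerebellar lobules following
#' Diedrichsen naming). Each hemisphere's parcel carries a synthetic centroid
#' on the unit sphere: cortical centroids are placed quasi-uniformly with a
#' Fibonacci lattice (right-hemisphere centroids are the x-mirror of the left),
#' which is what the spin-permutation null rotates. Subcortical and cerebellar
#' centroids are stored for completeness but are permuted, not rotated, by the
#' spatial null because spherical rotation is only geometrically meaningful
#' for the cortical sheet.
#'
#' @return a data.frame of class `asym_atlas` with columns `region`,
#'   `tissue` (one of `"cortical"`, `"subcortical"`, `"cerebellar"`), and unit
#'   centroid coordinates `lx, ly, lz, rx, ry, rz`.
#' @examples
#' atlas <- default_atlas()
#' table(atlas$tissue)
#' @export
default_atlas <- function() {
  cortical <- c(
    "frontal_pole", "insular_cortex", "superior_frontal_gyrus",
    "middle_frontal_gyrus", "inferior_frontal_gyrus_pars_triangularis",
    "inferior_frontal_gyrus_pars_opercularis", "precentral_gyrus",
    "temporal_pole", "superior_temporal_gyrus_anterior",
    "superior_temporal_gyrus_posterior", "middle_temporal_gyrus_anterior",
    "middle_temporal_gyrus_posterior", "middle_temporal_gyrus_temporooccipital",
    "inferior_temporal_gyrus_anterior", "inferior_temporal_gyrus_posterior",
    "inferior_temporal_gyrus_temporooccipital", "postcentral_gyrus",
    "superior_parietal_lobule", "supramarginal_gyrus_anterior",
    "supramarginal_gyrus_posterior", "angular_gyrus",
    "lateral_occipital_cortex_superior", "lateral_occipital_cortex_inferior",
    "intracalcarine_cortex", "frontal_medial_cortex",
    "juxtapositional_lobule_cortex", "subcallosal_cortex",
    "paracingulate_gyrus", "cingulate_gyrus_anterior",
    "cingulate_gyrus_posterior", "precuneous_cortex", "cuneal_cortex",
    "frontal_orbital_cortex", "parahippocampal_gyrus_anterior",
    "parahippocampal_gyrus_posterior", "lingual_gyrus",
    "temporal_fusiform_cortex_anterior", "temporal_fusiform_cortex_posterior",
    "temporal_occipital_fusiform_cortex", "occipital_fusiform_gyrus",
    "frontal_operculum_cortex", "central_opercular_cortex",
    "parietal_operculum_cortex", "planum_polare", "heschls_gyrus",
    "planum_temporale", "supracalcarine_cortex", "occipital_pole")
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                   "hippocampus", "amygdala", "accumbens")
  cerebellar <- c("cerebellum_i_iv", "cerebellum_v", "cerebellum_vi",
                  "cerebellum_crus_i", "cerebellum_crus_ii", "cerebellum_viib",
                  "cerebellum_viiia", "cerebellum_viiib", "cerebellum_ix",
                  "cerebellum_x")
  region <- c(cortical, subcortical, cerebellar)
  tissue <- rep(c("cortical", "subcortical", "cerebellar"),
                c(length(cortical), length(subcortical), length(cerebellar)))
  # one lattice per tissue class so each class covers its own sphere
  left <- rbind(fibonacci_sphere(48L), fibonacci_sphere(7L),
                fibonacci_sphere(10L))
  atlas <- data.frame(region = region, tissue = tissue,
                      lx = left[, 1], ly = left[, 2], lz = left[, 3],
                      rx = -left[, 1], ry = left[, 2], rz = left[, 3],
                      stringsAsFactors = FALSE)
  class(atlas) <- c("asym_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @return an `n` x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Validate an atlas table
#'
#' Checks region-name uniqueness, tissue labels, and unit-norm centroids.
#'
#' @param atlas an atlas data.frame as returned by [default_atlas()].
#' @param tol tolerance on the centroid norms.
#' @return the atlas, invisibly; errors describe the first violation found.
#' @export
validate_atlas <- function(atlas, tol = 1e-8) {
  need <- c("region", "tissue", "lx", "ly", "lz", "rx", "ry", "rz")
  if (!all(need %in% names(atlas))) {
    stop("atlas is missing columns: ",
         paste(setdiff(need, names(atlas)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(atlas$region)) stop("duplicate region names in atlas",
                                        call. = FALSE)
  if (!all(atlas$tissue %in% c("cortical", "subcortical", "cerebellar"))) {
    stop("unknown tissue class in atlas", call. = FALSE)
  }
  ln <- sqrt(atlas$lx^2 + atlas$ly^2 + atlas$lz^2)
  rn <- sqrt(atlas$rx^2 + atlas$ry^2 + atlas$rz^2)
  if (any(abs(ln - 1) > tol) || any(abs(rn - 1) > tol)) {
    stop("atlas centroids must have unit norm", call. = FALSE)
  }
  invisible(atlas)
}

#' Read / write an atlas as JSON
#'
#' @param atlas atlas data.frame.
#' @param path file path.
#' @return `write_atlas()` returns `path` invisibly; `read_atlas()` returns
#'   a validated atlas.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  jsonlite::write_json(as.data.frame(atlas), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- jsonlite::fromJSON(path)
  class(atlas) <- c("asym_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

# column names of the 130 paired volume columns for an atlas
volume_columns <- function(atlas) {
  as.vector(rbind(paste0(atlas$region, "_L"), paste0(atlas$region, "_R")))
}
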