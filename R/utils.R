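#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a base seed; keeps values inside 32-bit range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_label <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("`%s` must be a single non-empty label", what), call. = FALSE)
  }
  invisible(x)
}

#' CNV group labels recognized by the pipeline
#'
#' The eight recurrent deletions/duplications at four genomic loci plus the
#' control label.
#'
#' @return character vector of the nine valid group labels.
#' @export
cnv_labels <- function() {
  c("control",
    "1q21.1del", "1q21.1dup",
    "15q11.2del", "15q11.2dup",
    "16p11.2del", "16p11.2dup",
    "22q11.2del", "22q11.2dup")
}
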