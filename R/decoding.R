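# Functional annotation of coefficient maps against term-activation tables:
# absolute-map correlation decoding and the signed, binned weighted-score
# procedure.

#' Project a 65-coefficient pattern onto both hemispheres
#'
#' Expands a fitted pattern to the 130 `(region, hemisphere)` units used by
#' the decoding routines. In `absolute` mode the magnitude `|c|` is assigned
#' to both hemispheres (the whole-brain mask used for correlation decoding).
#' In `signed` mode the original coefficient goes to the right-hemisphere
#' unit and its negation to the left-hemisphere unit, so the sign structure
#' of the asymmetry pattern survives on the bilateral map.
#'
#' @param pattern an `lda_pattern` or named 65-coefficient vector.
#' @param mode `"absolute"` or `"signed"`.
#' @return a named 130-vector keyed `<region>_L` / `<region>_R`, ordered
#'   region-major to match term-map columns.
#' @export
bilateral_map <- function(pattern, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  w <- if (inherits(pattern, "lda_pattern")) pattern$coefficients else pattern
  if (is.null(names(w))) stop("pattern must be named by region", call. = FALSE)
  keys <- as.vector(rbind(paste0(names(w), "_L"), paste0(names(w), "_R")))
  vals <- if (mode == "absolute") {
    as.vector(rbind(abs(w), abs(w)))
  } else {
    as.vector(rbind(-w, w))
  }
  setNames(vals, keys)
}

#' Correlation decoding against term-activation maps
#'
#' Pearson-correlates a bilateral brain map with each term's activation map
#' and ranks terms by decreasing similarity. Terms with constant activation
#' have no defined correlation and are skipped with a warning. The result is
#' invariant to affine rescaling of the input map.
#'
#' @param map named 130-vector (see [bilateral_map()]).
#' @param terms term-map data.frame from [generate_term_maps()] or
#'   [read_term_maps()].
#' @return data.frame with `term` and `r`, sorted by decreasing `r`.
#' @export
correlation_decode <- function(map, terms) {
  units <- setdiff(names(terms), "term")
  if (!all(names(map) %in% units) || length(map) != length(units)) {
    stop("map units do not match term-map columns", call. = FALSE)
  }
  A <- as.matrix(terms[units])[, names(map), drop = FALSE]
  sds <- apply(A, 1, sd)
  if (any(sds == 0)) {
    warning("skipping constant term map(s): ",
            paste(terms$term[sds == 0], collapse = ", "), call. = FALSE)
  }
  keep <- sds > 0
  r <- drop(cor(map, t(A[keep, , drop = FALSE])))
  out <- data.frame(term = terms$term[keep], r = r, stringsAsFactors = FALSE)
  out[order(-out$r), , drop = FALSE]
}

# contiguous rank bins whose sizes differ by at most one unit, with the
# leftover units distributed palindromically (1, n, 2, n-1, ...) so that
# reversing the ranking maps bin b exactly onto bin n_bins + 1 - b
bin_sizes <- function(k, n_bins) {
  base <- rep(k %/% n_bins, n_bins)
  extra <- k %% n_bins
  if (extra > 0) {
    order_ends <- as.vector(rbind(seq_len(n_bins),
                                  rev(seq_len(n_bins))))[seq_len(n_bins)]
    base[order_ends[seq_len(extra)]] <- base[order_ends[seq_len(extra)]] + 1L
  }
  base
}

#' Binned weighted-score decoding along the coefficient spectrum
#'
#' Implements the signed decoding procedure: (1) spatial units are ranked by
#' signed coefficient (ties broken by unit index) and partitioned into
#' `n_bins` contiguous five-percentile bins; (2) for each term, activation is
#' averaged within every coefficient-ranked bin; (3) the binned activations
#' are z-scored within term and bins below `z_thresh` are set to zero;
#' (4) each surviving bin's weighted score is the product of its thresholded
#' activation and its mean coefficient; (5) the term's location on the
#' coefficient spectrum is the score-weighted mean bin index,
#' `sum(bin * score) / sum(score)`. Terms whose bins are all zeroed have no
#' defined location and are flagged. Bin means (not sums) are used for
#' within-bin aggregation so unequal bin sizes do not bias the scores.
#'
#' @param map signed named 130-vector (see [bilateral_map()] `signed` mode);
#'   denser unit tables are accepted transparently as long as names match the
#'   term table.
#' @param terms term-map data.frame.
#' @param n_bins number of rank bins (20 = five-percentile increments).
#' @param z_thresh z-score threshold below which binned activations are
#'   zeroed.
#' @return object of class `decoding_result`: data.frame `locations` with
#'   `term`, `location`, `flagged`; matrix `scores` (terms x bins); the
#'   `bin_coefficients`; and the parameters used.
#' @export
binned_weighted_decode <- function(map, terms, n_bins = 20L, z_thresh = 0.5) {
  units <- setdiff(names(terms), "term")
  if (length(map) < n_bins) stop("need at least as many spatial units as bins",
                                 call. = FALSE)
  if (!all(names(map) %in% units) || length(map) != length(units)) {
    stop("map units do not match term-map columns", call. = FALSE)
  }
  k <- length(map)
  ord <- order(map, seq_len(k))  # ascending; ties by unit index
  sizes <- bin_sizes(k, n_bins)
  bin_of <- rep(seq_len(n_bins), sizes)
  A <- as.matrix(terms[units])[, names(map), drop = FALSE]
  coef_sorted <- map[ord]
  bin_coef <- as.vector(rowsum(coef_sorted, bin_of) / sizes)
  act_sorted <- A[, ord, drop = FALSE]
  bin_act <- t(rowsum(t(act_sorted), bin_of) / sizes)  # terms x bins
  mu <- rowMeans(bin_act)
  sdv <- apply(bin_act, 1, sd)
  z <- (bin_act - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z[z < z_thresh] <- 0
  scores <- sweep(z, 2, bin_coef, `*`)
  total <- rowSums(scores)
  flagged <- rowSums(z > 0) == 0 | total == 0
  location <- ifelse(flagged, NA_real_,
                     as.vector(scores %*% seq_len(n_bins)) / total)
  structure(list(locations = data.frame(term = terms$term,
                                        location = location,
                                        flagged = flagged,
                                        stringsAsFactors = FALSE),
                 scores = `dimnames<-`(scores,
                                       list(terms$term,
                                            paste0("bin", seq_len(n_bins)))),
                 bin_coefficients = bin_coef, n_bins = n_bins,
                 z_thresh = z_thresh, bin_sizes = sizes),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("binned weighted decoding: %d terms, %d bins (z >= %.2f)\n",
              nrow(x$locations), x$n_bins, x$z_thresh))
  ok <- x$locations[!x$locations$flagged, ]
  ok <- ok[order(ok$location), ]
  cat("  lowest-located terms:",
      paste(sprintf("%s (%.1f)", utils::head(ok$term, 3),
                    utils::head(ok$location, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Write decoding results as TSV
#'
#' @param x a `decoding_result` or correlation-decoding data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_decoding <- function(x, path) {
  df <- if (inherits(x, "decoding_result")) {
    cbind(x$locations, as.data.frame(x$scores))
  } else {
    x
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
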