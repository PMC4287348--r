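#' Drop transcripts with low total counts
#'
#' Keeps transcripts whose count summed over all samples combined is at
#' least `min_total`; row order is preserved.  The default of 30 matches
#' common practice for transcript-level atlases built from
#' expectation-maximization abundance estimates.
#'
#' @param cm An `atlas_counts` object.
#' @param min_total Minimum summed count across all samples.
#' @return A filtered `atlas_counts` object.
#' @export
filter_low_counts <- function(cm, min_total = 30) {
  stopifnot(inherits(cm, "atlas_counts"))
  if (!is.numeric(min_total) || min_total < 0) stop("min_total must be >= 0")
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) warning("no transcripts pass the count filter")
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out
}

# 75th-percentile count fraction per sample; used to pick the TMM reference.
.upper_quartile_fraction <- function(counts, lib) {
  vapply(seq_len(ncol(counts)),
         function(j) quantile(counts[, j] / lib[j], 0.75, names = FALSE),
         numeric(1))
}

# TMM factor of one sample against the reference (Robinson-Oshlack):
# two-sided trim of 30% on M and 5% on A, inverse-variance weighting.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                      do_weighting) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (length(obs) == 0L) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
  rm <- rank(m); ra <- rank(a)
  keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  f <- if (do_weighting) {
    sum(m[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    mean(m[keep])
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' method: each sample is compared to a reference sample through
#' per-transcript log2 count-proportion ratios (M) and mean log2 abundances
#' (A) over transcripts nonzero in both; the most extreme 30% of M values
#' and 5% of A values (two-sided) are trimmed and the factor is 2 raised to
#' the precision-weighted mean of the remaining M values.  Factors are
#' rescaled to geometric mean 1.
#'
#' @param cm An `atlas_counts` object (typically after
#'   [filter_low_counts()]); at least two samples, all with positive
#'   library size.
#' @param ref_sample Optional sample ID to use as the reference; by default
#'   the sample whose 75th-percentile count fraction is closest to the mean
#'   of those quantiles.
#' @param logratio_trim Two-sided trim fraction on M values.
#' @param sum_trim Two-sided trim fraction on A values.
#' @param do_weighting Weight M values by inverse asymptotic variance.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(cm, ref_sample = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05, do_weighting = TRUE) {
  stopifnot(inherits(cm, "atlas_counts"))
  counts <- cm$counts
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample with zero library size: ",
         colnames(counts)[which(lib <= 0)[1L]])
  if (is.null(ref_sample)) {
    f75 <- .upper_quartile_fraction(counts, lib)
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown ref_sample: ", ref_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Normalized counts per million
#'
#' `value[t, s] = counts[t, s] / (library_size[s] * factor[s]) * 1e6`.
#'
#' @param cm An `atlas_counts` object.
#' @param factors Positive per-sample normalization factors (defaults to
#'   [tmm_factors()] of `cm`).
#' @return An `atlas_norm` object: list with `values` (matrix), `factors`,
#'   `library_sizes`, and the `sample_sheet`.
#' @export
cpm <- function(cm, factors = NULL) {
  stopifnot(inherits(cm, "atlas_counts"))
  if (is.null(factors)) factors <- tmm_factors(cm)
  factors <- factors[colnames(cm$counts)]
  if (any(is.na(factors) | factors <= 0))
    stop("factors must be positive and cover every sample")
  lib <- colSums(cm$counts)
  values <- sweep(cm$counts, 2L, lib * factors, "/") * 1e6
  structure(list(values = values, factors = factors, library_sizes = lib,
                 sample_sheet = cm$sample_sheet),
            class = "atlas_norm")
}

#' @export
print.atlas_norm <- function(x, ...) {
  cat(sprintf("atlas_norm: %d transcripts x %d samples (CPM)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
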