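#' Equalize library sizes for exact testing
#'
#' Scales every sample's counts to the geometric mean of the effective
#' (factor-adjusted) library sizes and rounds to integers, so the exact
#' negative-binomial test can condition on pooled counts.
#'
#' @param cm An `atlas_counts` object.
#' @param factors Optional TMM factors (default all 1).
#' @return An `atlas_counts` object with equalized integer counts.
#' @export
equalize_libraries <- function(cm, factors = NULL) {
  stopifnot(inherits(cm, "atlas_counts"))
  lib <- colSums(cm$counts)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(cm$counts)),
                                            colnames(cm$counts))
  eff <- lib * factors[colnames(cm$counts)]
  target <- exp(mean(log(eff)))
  out <- cm
  out$counts <- round(sweep(cm$counts, 2L, target / eff, "*"))
  out
}

# Conditional NB log-likelihood of all genes given group totals, including
# the count-factorial constants so the Poisson (phi -> 0) limit is
# comparable.  `mats` is a list of gene x replicate matrices, one per group.
.cond_nb_ll <- function(phi, mats) {
  r <- 1 / phi
  ll <- 0
  for (y in mats) {
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) -
                     rowSums(lgamma(y + 1)) -
                     (lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1)))
  }
  ll
}

# Poisson limit of the conditional likelihood: multinomial with equal cell
# probabilities within each group.
.cond_pois_ll <- function(mats) {
  ll <- 0
  for (y in mats) {
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    ll <- ll + sum(lgamma(z + 1) - rowSums(lgamma(y + 1)) - z * log(n))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional (quantile-adjusted) NB likelihood over a
#' log-spaced grid of dispersions, refined by golden-section search, after
#' equalizing library sizes.  Returns 0 when the data are sub-Poisson
#' (the Poisson limit of the conditional likelihood dominates).
#'
#' @param cm An `atlas_counts` object.
#' @param groups Group label per sample (defaults to the pseudo-organ of
#'   each sample from the sample sheet).
#' @param factors Optional TMM factors used for library equalization.
#' @param phi_max Upper bound of the dispersion search.
#' @return List of class `atlas_dispersion` with elements
#'   `common_dispersion` and `n_genes`.
#' @export
estimate_common_dispersion <- function(cm, groups = NULL, factors = NULL,
                                       phi_max = 5) {
  stopifnot(inherits(cm, "atlas_counts"))
  if (is.null(groups)) groups <- sample_organs(cm)
  groups <- groups[colnames(cm$counts)]
  eq <- equalize_libraries(cm, factors)
  mats <- lapply(split(seq_along(groups), groups),
                 function(j) eq$counts[, j, drop = FALSE])
  if (!any(vapply(mats, ncol, integer(1)) >= 2L))
    stop("no group has >= 2 replicates; supply a fixed dispersion instead")
  grid <- exp(seq(log(1e-4), log(phi_max), length.out = 30))
  ll <- vapply(grid, .cond_nb_ll, numeric(1), mats = mats)
  best <- which.max(ll)
  ll0 <- .cond_pois_ll(mats)
  if (best == 1L && ll0 >= ll[1L]) {
    phi <- 0
  } else {
    lower <- grid[max(1L, best - 1L)]
    upper <- grid[min(length(grid), best + 1L)]
    opt <- optimize(.cond_nb_ll, c(lower, upper), mats = mats,
                    maximum = TRUE, tol = 1e-6)
    phi <- opt$maximum
    if (opt$objective <= ll0 && phi <= grid[2L]) phi <- 0
  }
  structure(list(common_dispersion = phi, n_genes = nrow(cm$counts)),
            class = "atlas_dispersion")
}

# Conditional two-sided p for one gene: split (za, zb) of pooled z between
# nA and nB equalized libraries under a common NB dispersion.
.exact_p_one <- function(za, zb, n_a, n_b, phi) {
  z <- za + zb
  if (z == 0) return(1)
  if (phi == 0) {
    pr <- n_a / (n_a + n_b)
    p_low <- pbinom(za, z, pr)
    p_high <- pbinom(za - 1, z, pr, lower.tail = FALSE)
  } else {
    r_a <- n_a / phi
    r_b <- n_b / phi
    a <- 0:z
    lw <- lgamma(a + r_a) - lgamma(a + 1) + lgamma(z - a + r_b) -
      lgamma(z - a + 1)
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- w / sum(w)
    p_low <- sum(w[1:(za + 1)])
    p_high <- sum(w[(za + 1):(z + 1)])
  }
  min(1, 2 * min(p_low, p_high))
}

#' Negative-binomial exact test for one pseudo-organ pair
#'
#' Two-sided exact-style test per transcript: under an NB model with equal
#' means and the given common dispersion, the conditional probability of a
#' split of the pooled count at least as extreme as observed, doubling the
#' smaller tail (capped at 1).  Counts must come from equalized libraries.
#'
#' @param group_a,group_b Integer count matrices (transcripts x replicates)
#'   with equalized library sizes, same transcripts in the same order.
#' @param dispersion Common NB dispersion (>= 0; 0 is the Poisson limit,
#'   where the test reduces to a conditional binomial test).
#' @return Data frame with `transcript_id`, `log_fc` (log2 fold change,
#'   B over A with a 0.5 pseudocount), and `p_value`.
#' @export
nb_exact_test <- function(group_a, group_b, dispersion) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) != nrow(group_b))
    stop("group matrices must have the same transcripts")
  za <- rowSums(group_a); zb <- rowSums(group_b)
  n_a <- ncol(group_a); n_b <- ncol(group_b)
  p <- vapply(seq_along(za), function(i)
    .exact_p_one(za[i], zb[i], n_a, n_b, dispersion), numeric(1))
  log_fc <- log2(((zb + 0.5) / n_b) / ((za + 0.5) / n_a))
  data.frame(transcript_id = rownames(group_a) %||% as.character(seq_along(za)),
             log_fc = log_fc, p_value = p, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min over j >= rank(i) of (m/j) p_(j)`,
#' capped at 1 (delegated to [stats::p.adjust()] after validation).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pairwise differential abundance across all pseudo-organ pairs
#'
#' Runs the NB exact test for every unordered pair of organs on
#' library-equalized counts under one common dispersion, adjusting p-values
#' per pair with Benjamini-Hochberg.
#'
#' @param cm A filtered `atlas_counts` object.
#' @param factors Optional TMM factors for equalization.
#' @param dispersion Common dispersion; estimated with
#'   [estimate_common_dispersion()] when `NULL`.
#' @param threshold FDR significance threshold.
#' @return Named list of per-pair data frames (`transcript_id`, `log_fc`,
#'   `p_value`, `fdr`, `significant`), names `"organA|organB"`; attributes
#'   `organs`, `dispersion`, `threshold`.
#' @export
pairwise_de <- function(cm, factors = NULL, dispersion = NULL,
                        threshold = 0.05) {
  stopifnot(inherits(cm, "atlas_counts"))
  organs <- unique(cm$sample_sheet$organ)
  if (length(organs) < 2L) stop("need >= 2 pseudo-organs")
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(cm, factors = factors)$common_dispersion
  eq <- equalize_libraries(cm, factors)
  org <- sample_organs(cm)
  pairs <- combn(sort(organs), 2L, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    a <- eq$counts[, org == pr[1L], drop = FALSE]
    b <- eq$counts[, org == pr[2L], drop = FALSE]
    tab <- nb_exact_test(a, b, dispersion)
    tab$fdr <- bh_fdr(tab$p_value)
    tab$significant <- tab$fdr < threshold
    tab
  })
  names(res) <- vapply(pairs, paste, character(1), collapse = "|")
  attr(res, "organs") <- sort(organs)
  attr(res, "dispersion") <- dispersion
  attr(res, "threshold") <- threshold
  res
}

#' Union of differentially abundant transcripts
#'
#' Transcripts significant (FDR below the threshold) in at least one
#' pseudo-organ pair.  All `k(k-1)/2` pairwise results must be present.
#'
#' @param results List of per-pair result data frames as returned by
#'   [pairwise_de()] (names `"organA|organB"`).
#' @param threshold FDR threshold.
#' @param organs Organ label set; taken from the `organs` attribute of
#'   `results` when `NULL`.
#' @return Character vector of transcript IDs.
#' @export
de_union <- function(results, threshold = 0.05, organs = NULL) {
  if (is.null(organs)) organs <- attr(results, "organs")
  if (is.null(organs))
    stop("organ set unknown; pass `organs` explicitly")
  expected <- vapply(combn(sort(organs), 2L, simplify = FALSE),
                     paste, character(1), collapse = "|")
  missing <- setdiff(expected, names(results))
  if (length(missing) > 0L)
    stop("missing pairwise comparisons: ", paste(missing, collapse = ", "))
  ids <- unique(unlist(lapply(results[expected], function(tab)
    tab$transcript_id[tab$fdr < threshold])))
  if (length(ids) == 0L)
    warning("no transcript is differentially abundant in any pair")
  ids
}
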