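.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      out[[idx]] <- c(p[seq_len(i - 1L)], n,
                      if (i <= n - 1L) p[i:(n - 1L)])
    }
  }
  out
}

#' Best label-matched agreement between two clusterings
#'
#' Cluster labels are arbitrary, so recovered and planted partitions are
#' compared after matching labels: the fraction of observations agreeing
#' under the best one-to-one mapping of predicted labels to true labels
#' (exhaustive over all permutations; label sets up to size 8).
#'
#' @param pred,truth Vectors of cluster labels (same length; NAs dropped
#'   pairwise).
#' @return Fraction of observations in agreement under the best matching.
#' @export
label_agreement <- function(pred, truth) {
  keep <- !is.na(pred) & !is.na(truth)
  pred <- as.character(pred)[keep]
  truth <- as.character(truth)[keep]
  tab <- table(pred, truth)
  k <- max(dim(tab))
  if (k > 8L) stop("label matching supports at most 8 labels")
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (p in .permutations(k)) {
    s <- sum(m[cbind(seq_len(k), p)])
    if (s > best) best <- s
  }
  best / length(pred)
}
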