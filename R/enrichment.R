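#' Hypergeometric GO over-representation for one cluster
#'
#' For every GO term annotated to at least one universe member, tests
#' whether the cluster contains more term members than expected when
#' drawing `K` transcripts from a universe of `N` without replacement:
#' upper-tail p = P(X >= k | N, n, K).  P-values are Benjamini-Hochberg
#' adjusted across terms.
#'
#' @param node_members Character vector of cluster member transcript IDs
#'   (must be a subset of `universe`).
#' @param universe Character vector of all candidate transcript IDs.
#' @param annotation An `atlas_go` annotation (or data frame with
#'   `transcript_id`, `go_id`).
#' @param fdr Significance threshold recorded in the `significant` column.
#' @return Data frame with one row per term: `go_id`, `k` (members in
#'   cluster), `n` (term size in universe), `K` (cluster size), `N`
#'   (universe size), `p_value`, `fdr`, `significant`, `method`.
#' @export
hypergeom_enrich <- function(node_members, universe, annotation,
                             fdr = 0.05) {
  .enrich_core(node_members, universe, annotation, fdr, odds = NULL)
}

.enrich_core <- function(node_members, universe, annotation, fdr, odds) {
  node_members <- unique(node_members)
  universe <- unique(universe)
  outside <- setdiff(node_members, universe)
  if (length(outside) > 0L)
    stop("cluster members not in universe: ",
         paste(head(outside, 5L), collapse = ", "))
  ann <- as.data.frame(annotation)
  ann <- ann[ann$transcript_id %in% universe, , drop = FALSE]
  if (nrow(ann) == 0L) stop("annotation covers no universe member")
  N <- length(universe)
  K <- length(node_members)
  terms <- split(ann$transcript_id, ann$go_id)
  rows <- lapply(names(terms), function(tm) {
    members <- unique(terms[[tm]])
    n <- length(members)
    k <- sum(members %in% node_members)
    if (is.null(odds)) {
      p <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
      method <- "hypergeometric"
      w <- NA_real_
    } else {
      w <- odds[[tm]]
      p <- .wallenius_upper(k, n, N - n, K, w)
      method <- "wallenius"
    }
    data.frame(go_id = tm, k = k, n = n, K = K, N = N, odds = w,
               p_value = p, method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < fdr
  out <- out[order(out$p_value, out$go_id),
             c("go_id", "k", "n", "K", "N", "odds", "p_value", "fdr",
               "significant", "method")]
  rownames(out) <- NULL
  out
}

# Upper tail P(X >= k) of the Wallenius noncentral hypergeometric
# distribution: K sequential draws without replacement from n1 items of
# weight w and n2 items of weight 1.  Computed exactly by dynamic
# programming over draws (probability vector over the success count),
# which is numerically stable for any odds.
.wallenius_upper <- function(k, n1, n2, K, w) {
  lo <- max(0L, K - n2)
  hi <- min(n1, K)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  p <- numeric(hi + 1L)
  p[1L] <- 1
  for (j in seq_len(K)) {
    xm <- min(j - 1L, hi)
    xs <- 0:xm
    wrem <- n1 - xs
    orem <- n2 - (j - 1L - xs)
    valid <- wrem >= 0 & orem >= 0 & (wrem + orem) > 0
    pw <- ifelse(valid, w * pmax(wrem, 0) / (w * pmax(wrem, 0) +
                                               pmax(orem, 0)), 0)
    newp <- numeric(hi + 1L)
    stay <- p[xs + 1L] * (1 - pw)
    move <- p[xs + 1L] * pw
    newp[xs + 1L] <- stay
    ok <- xs + 1L <= hi
    newp[xs[ok] + 2L] <- newp[xs[ok] + 2L] + move[ok]
    p <- newp
  }
  min(1, sum(p[(k + 1L):(hi + 1L)]))
}

#' Length-aware probability weights for cluster membership
#'
#' Bins the universe into (up to) 20 length quantile bins, computes the
#' cluster-membership rate per bin, and smooths the rate monotonically in
#' length with isotonic regression (fitting both directions and keeping
#' the better one).  Each transcript receives its bin's smoothed rate as a
#' selection weight.
#'
#' @param universe Character vector of transcript IDs.
#' @param node_members Cluster members (subset of universe).
#' @param lengths Named vector of transcript lengths.
#' @param n_bins Number of quantile bins.
#' @return Named numeric weight per universe transcript.
#' @export
length_weights <- function(universe, node_members, lengths, n_bins = 20) {
  len <- lengths[universe]
  if (any(!is.finite(len) | len <= 0))
    stop("non-positive or missing lengths in universe")
  member <- as.numeric(universe %in% node_members)
  br <- unique(quantile(len, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) br <- c(br - 0.5, br + 0.5)  # all lengths equal
  bin <- cut(len, breaks = br, include.lowest = TRUE)
  bin <- droplevels(bin)
  rate <- tapply(member, bin, mean)
  mid <- tapply(len, bin, mean)
  ord <- order(mid)
  up <- isoreg(mid[ord], rate[ord])$yf
  dn <- rev(isoreg(mid[ord], rev(rate[ord]))$yf)  # decreasing fit
  fit <- if (sum((rate[ord] - up)^2) <= sum((rate[ord] - dn)^2)) up else dn
  smoothed <- setNames(fit, levels(bin)[ord])[as.character(bin)]
  w <- pmax(as.numeric(smoothed), 1e-6)
  setNames(w, universe)
}

#' Length-bias-corrected GO over-representation (Wallenius)
#'
#' Like [hypergeom_enrich()], but discounts transcript-length selection
#' bias: a probability-weighting function is fit by monotone binned
#' regression of cluster-membership rate on transcript length, each term's
#' odds is the mean weight inside the category over the mean weight
#' outside, and the upper-tail p-value comes from the Wallenius noncentral
#' hypergeometric distribution with that odds.  Falls back to the plain
#' hypergeometric test (with a warning) when lengths cover less than 90%
#' of the universe.
#'
#' @inheritParams hypergeom_enrich
#' @param lengths Named vector of transcript lengths in bp.
#' @return As [hypergeom_enrich()], with `method = "wallenius"` and the
#'   per-term `odds` filled in.
#' @export
wallenius_enrich <- function(node_members, universe, annotation, lengths,
                             fdr = 0.05) {
  universe <- unique(universe)
  if (any(lengths[!is.na(names(lengths))] <= 0, na.rm = TRUE))
    stop("non-positive lengths")
  cov <- mean(universe %in% names(lengths))
  if (cov < 0.9) {
    warning(sprintf(
      "lengths cover only %.0f%% of the universe; using hypergeometric test",
      100 * cov))
    return(hypergeom_enrich(node_members, universe, annotation, fdr))
  }
  w <- length_weights(universe, node_members, lengths)
  ann <- as.data.frame(annotation)
  ann <- ann[ann$transcript_id %in% universe, , drop = FALSE]
  terms <- split(ann$transcript_id, ann$go_id)
  odds <- lapply(terms, function(members) {
    inside <- universe %in% members
    if (all(inside) || !any(inside)) return(1)
    mean(w[inside]) / mean(w[!inside])
  })
  .enrich_core(node_members, universe, annotation, fdr, odds = odds)
}

#' GO enrichment for every SOM node
#'
#' @param model An `atlas_som` model.
#' @param annotation An `atlas_go` annotation.
#' @param lengths Optional named length vector; when given, the Wallenius
#'   length-corrected test is used.
#' @param fdr Significance threshold.
#' @return Named list (node) of enrichment data frames.
#' @export
enrich_nodes <- function(model, annotation, lengths = NULL, fdr = 0.05) {
  stopifnot(inherits(model, "atlas_som"))
  universe <- names(model$assignment)
  ks <- sort(unique(model$assignment))
  res <- lapply(ks, function(u) {
    members <- names(model$assignment)[model$assignment == u]
    if (is.null(lengths))
      hypergeom_enrich(members, universe, annotation, fdr)
    else
      wallenius_enrich(members, universe, annotation, lengths, fdr)
  })
  names(res) <- paste0("node", ks)
  res
}
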