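#' Assign foreign atlas nodes to source transcripts via best hits
#'
#' Each source transcript whose best hit subject has a node in the foreign
#' atlas membership table receives that node.  Transcripts without a hit,
#' or whose subject lacks a node, are excluded and tallied by reason.
#'
#' @param hits Best-hit table (one row per query; see [best_hits()]).
#' @param foreign_membership Data frame with columns `transcript_id` and
#'   `node` describing the foreign atlas, or a named vector.
#' @param queries Optional character vector of all source transcript IDs,
#'   used to count queries with no hit at all.
#' @return Data frame (`query_id`, `subject_id`, `foreign_node`,
#'   `percent_identity`, `e_value`, `bit_score`) with an `excluded`
#'   attribute (named counts: `no_hit`, `subject_without_node`).
#' @export
assign_foreign_nodes <- function(hits, foreign_membership, queries = NULL) {
  fm <- .membership_vector(foreign_membership)
  node <- fm[hits$subject_id]
  excluded <- c(
    no_hit = if (is.null(queries)) 0L
             else length(setdiff(queries, hits$query_id)),
    subject_without_node = sum(is.na(node)))
  out <- data.frame(query_id = hits$query_id,
                    subject_id = hits$subject_id,
                    foreign_node = as.character(node),
                    percent_identity = hits$percent_identity,
                    e_value = hits$e_value,
                    bit_score = hits$bit_score,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.membership_vector <- function(m) {
  if (is.data.frame(m)) {
    if (!all(c("transcript_id", "node") %in% names(m)))
      stop("membership table needs columns 'transcript_id' and 'node'")
    setNames(as.character(m$node), m$transcript_id)
  } else {
    setNames(as.character(m), names(m))
  }
}

#' Null distribution over foreign atlas nodes
#'
#' The proportion of all foreign transcripts assigned to each foreign
#' node; this background is the expected distribution of source-transcript
#' homologs under no association.
#'
#' @param foreign_membership As in [assign_foreign_nodes()].
#' @return Named numeric vector of proportions summing to 1.
#' @export
null_distribution <- function(foreign_membership) {
  fm <- .membership_vector(foreign_membership)
  if (length(fm) == 0L) stop("empty foreign membership")
  tab <- table(fm)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Chi-squared intersection of two expression atlases
#'
#' For each source node, compares the observed distribution of its
#' members' foreign-node assignments against the foreign null with a
#' Pearson chi-squared goodness-of-fit statistic
#' (`sum((O - E)^2 / E)`, df = number of foreign nodes - 1).
#'
#' @param gene_table Output of [assign_foreign_nodes()].
#' @param source_nodes Source node per source transcript: data frame
#'   (`transcript_id`, `node`) or named vector.
#' @param null_props Named proportions from [null_distribution()].
#' @return Object of class `atlas_intersection`: `summary` (source_node,
#'   n, chisq, df, p_value), `obs_exp` (long table of observed/expected/
#'   fold per source node and foreign node), `genes` (gene-level table
#'   with both node assignments).
#' @export
intersection_chisq <- function(gene_table, source_nodes, null_props) {
  sn <- .membership_vector(source_nodes)
  if (length(null_props) < 2L)
    stop("need >= 2 foreign nodes (df would be 0)")
  if (abs(sum(null_props) - 1) > 1e-8)
    stop("null proportions must sum to 1")
  genes <- gene_table
  genes$source_node <- as.character(sn[genes$query_id])
  genes <- genes[!is.na(genes$source_node), , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene has both a source and foreign node")
  cats <- names(null_props)
  unknown <- setdiff(unique(genes$foreign_node), cats)
  if (length(unknown) > 0L)
    stop("foreign node absent from null: ", paste(unknown, collapse = ", "))
  sum_rows <- list(); long_rows <- list()
  for (node in sort(unique(genes$source_node))) {
    sub <- genes$foreign_node[genes$source_node == node]
    obs <- as.numeric(table(factor(sub, levels = cats)))
    expd <- length(sub) * as.numeric(null_props)
    if (any(expd == 0 & obs > 0))
      stop("expected count 0 with observed > 0 for source node ", node,
           "; merge foreign categories")
    if (any(expd < 5))
      warning("expected count < 5 for source node ", node,
              "; chi-squared approximation may be poor")
    use <- expd > 0
    stat <- sum((obs[use] - expd[use])^2 / expd[use])
    df <- length(cats) - 1L
    sum_rows[[node]] <- data.frame(
      source_node = node, n = length(sub), chisq = stat, df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    long_rows[[node]] <- data.frame(
      source_node = node, foreign_node = cats, observed = obs,
      expected = expd, fold = ifelse(expd > 0, obs / expd, NA_real_),
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(sum_rows,
                                            make.row.names = FALSE)),
                 obs_exp = do.call(rbind, c(long_rows,
                                            make.row.names = FALSE)),
                 genes = genes),
            class = "atlas_intersection")
}

#' @export
print.atlas_intersection <- function(x, ...) {
  cat("atlas_intersection:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
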