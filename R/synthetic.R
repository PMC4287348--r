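#' Canonical accumulation prototype profiles
#'
#' Six hand-authored multiplicative profiles over the six pseudo-organs,
#' mirroring the accumulation patterns an apical-basal atlas exhibits:
#' apex-high; pinnule+rachis-high; rachis+frond-base-high;
#' frond-base+stolon-high; stolon+holdfast-high; holdfast-high.  For fewer
#' nodes an evenly spaced subset along the axis is used.  The high organs
#' carry `fold` times the baseline intensity.
#'
#' @param n_nodes Number of prototypes (2-6).
#' @param organs Organ labels (length 6 in the default design).
#' @param fold Fold elevation of the high organs.
#' @return Matrix, nodes x organs, of relative intensities.
#' @export
prototype_profiles <- function(n_nodes = 6, organs = atlas_organs,
                               fold = 4) {
  if (length(organs) != 6L)
    stop("the canonical prototypes are defined over 6 pseudo-organs")
  if (n_nodes < 2L || n_nodes > 6L) stop("n_nodes must be in 2..6")
  high <- list(1L, c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L), 6L)
  pick <- round(seq(1L, 6L, length.out = n_nodes))
  tmpl <- t(vapply(high[pick], function(h) {
    v <- rep(1, 6); v[h] <- fold; v
  }, numeric(6)))
  dimnames(tmpl) <- list(paste0("planted", seq_len(n_nodes)), organs)
  tmpl
}

#' Generate a synthetic pseudo-organ count atlas with planted structure
#'
#' Counts are negative binomial with variance `mu + phi mu^2`; a planted
#' fraction of transcripts follows one of the prototype accumulation
#' profiles (drawn uniformly over nodes) while the rest are flat (null).
#' Per-transcript baselines are log-normal and each sample's expected
#' column sum equals `depth`.  The default design matches the sampling of
#' a six-pseudo-organ atlas with replicates (5, 5, 5, 5, 5, 4).
#'
#' @param n_transcripts Number of transcripts.
#' @param organs Organ labels.
#' @param replicates Replicate count per organ (same order as `organs`).
#' @param templates Prototype matrix (nodes x organs); default
#'   [prototype_profiles()] with 6 nodes.
#' @param fraction_null Fraction of transcripts with a flat profile.
#' @param dispersion NB dispersion phi (0 gives Poisson counts).
#' @param depth Expected library size per sample.
#' @param baseline_sdlog Log-normal sd of per-transcript baselines.
#' @param profile_noise_sd Log-scale sd of gene-level multiplicative
#'   noise on each structured gene's per-organ intensity, emulating
#'   gene-to-gene variation in accumulation patterns around the node
#'   prototype (null genes remain exactly flat).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments and this seed.
#' @return List with `counts` (an `atlas_counts`) and `truth` (class
#'   `atlas_truth`): planted `node` per transcript (NA = null), the
#'   `templates`, and all generating parameters.
#' @export
generate_atlas <- function(n_transcripts = 2000, organs = atlas_organs,
                           replicates = c(5, 5, 5, 5, 5, 4),
                           templates = NULL, fraction_null = 0.5,
                           dispersion = 0.1, depth = 5e5,
                           baseline_sdlog = 1, profile_noise_sd = 0.45,
                           seed = 1) {
  if (length(replicates) != length(organs) || any(replicates < 1))
    stop("replicates must give a positive count per organ")
  if (is.null(templates)) templates <- prototype_profiles(6, organs)
  if (ncol(templates) != length(organs))
    stop("templates must have one column per organ")
  set.seed(seed)
  n_nodes <- nrow(templates)
  n_null <- round(fraction_null * n_transcripts)
  node <- c(rep(NA_integer_, n_null),
            sample.int(n_nodes, n_transcripts - n_null, replace = TRUE))
  node <- sample(node)  # interleave null and structured transcripts
  ids <- sprintf("contig_%05d", seq_len(n_transcripts))
  names(node) <- ids
  baseline <- rlnorm(n_transcripts, meanlog = 0, sdlog = baseline_sdlog)
  profile <- matrix(1, n_transcripts, length(organs))
  structured <- !is.na(node)
  profile[structured, ] <- templates[node[structured], , drop = FALSE] *
    exp(matrix(rnorm(sum(structured) * length(organs), 0, profile_noise_sd),
               sum(structured), length(organs)))
  intensity <- baseline * profile                   # transcripts x organs
  organ_of_sample <- rep(organs, times = replicates)
  sample_ids <- unlist(lapply(seq_along(organs), function(i)
    sprintf("%s_r%d", organs[i], seq_len(replicates[i]))))
  mu <- intensity[, match(organ_of_sample, organs), drop = FALSE]
  mu <- sweep(mu, 2L, colSums(mu), "/") * depth
  counts <- if (dispersion == 0) {
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  } else {
    matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
           nrow(mu), ncol(mu))
  }
  dimnames(counts) <- list(ids, sample_ids)
  sheet <- data.frame(sample_id = sample_ids, organ = organ_of_sample,
                      stringsAsFactors = FALSE)
  truth <- structure(list(node = node, templates = templates,
                          dispersion = dispersion, depth = depth,
                          organs = organs, replicates = replicates,
                          fraction_null = fraction_null, seed = seed),
                     class = "atlas_truth")
  list(counts = count_matrix(counts, sheet, organ_levels = NULL),
       truth = truth)
}

#' Generate a foreign expression atlas and a synthetic homolog map
#'
#' Emulates the inputs of a cross-species atlas intersection: a foreign
#' ("tomato-like") atlas assigning each foreign transcript to one of
#' `n_foreign_nodes` nodes, and a best-hit homolog table in which each
#' source transcript's homolog is drawn from the foreign node given by its
#' source node's row of the association matrix (uniform rows mean no
#' association).  Hit scores are synthesized with e-values log-uniform
#' below 1e-5 so none are filtered by the default ceiling.
#'
#' @param truth An `atlas_truth` from [generate_atlas()].
#' @param n_foreign_nodes Number of foreign atlas nodes.
#' @param n_foreign Number of foreign transcripts.
#' @param association Matrix (source nodes x foreign nodes) of
#'   probabilities; each row must sum to 1.  Default: uniform (null).
#' @param hit_fraction Fraction of source transcripts receiving a hit.
#' @param seed Integer seed.
#' @return List with `foreign_membership` (data frame `transcript_id`,
#'   `node`), `hits` (best-hit data frame), `association`, `seed`.
#' @export
generate_foreign_atlas_and_homologs <- function(truth, n_foreign_nodes = 9,
                                                n_foreign = 4500,
                                                association = NULL,
                                                hit_fraction = 0.9,
                                                seed = 1) {
  stopifnot(inherits(truth, "atlas_truth"))
  n_source_nodes <- nrow(truth$templates)
  if (is.null(association))
    association <- matrix(1 / n_foreign_nodes, n_source_nodes,
                          n_foreign_nodes)
  if (ncol(association) != n_foreign_nodes ||
      nrow(association) != n_source_nodes ||
      any(abs(rowSums(association) - 1) > 1e-8))
    stop("association must be source-nodes x foreign-nodes with rows summing to 1")
  set.seed(seed)
  foreign_ids <- sprintf("foreign_%05d", seq_len(n_foreign))
  foreign_node <- sample.int(n_foreign_nodes, n_foreign, replace = TRUE)
  by_node <- split(foreign_ids, foreign_node)
  queries <- names(truth$node)
  queries <- sort(sample(queries, round(hit_fraction * length(queries))))
  uniform <- rep(1 / n_foreign_nodes, n_foreign_nodes)
  target_node <- vapply(queries, function(q) {
    src <- truth$node[[q]]
    pr <- if (is.na(src)) uniform else association[src, ]
    sample.int(n_foreign_nodes, 1L, prob = pr)
  }, integer(1))
  subject <- vapply(as.character(target_node), function(f) {
    pool <- by_node[[f]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  hits <- data.frame(query_id = queries, subject_id = unname(subject),
                     percent_identity = round(runif(length(queries), 30, 95), 1),
                     e_value = 10^runif(length(queries), -50, -5),
                     bit_score = round(runif(length(queries), 60, 500), 1),
                     stringsAsFactors = FALSE)
  list(foreign_membership = data.frame(transcript_id = foreign_ids,
                                       node = as.character(foreign_node),
                                       stringsAsFactors = FALSE),
       hits = hits, association = association, seed = seed)
}

#' Generate GO annotation, contig lengths, and an optional FASTA
#'
#' Plants one over-represented GO term per node (members annotated with
#' probability `p_planted`, non-members with the probability implied by
#' the enrichment `odds`), adds random background terms, and draws
#' log-normal contig lengths, optionally coupled to node membership
#' (structured transcripts longer by `length_coupling` on the log scale).
#'
#' @param truth An `atlas_truth` from [generate_atlas()].
#' @param odds Planted enrichment odds ratio.
#' @param p_planted Annotation probability for node members.
#' @param n_background Number of background GO terms.
#' @param p_background Annotation probability per background term.
#' @param length_meanlog,length_sdlog Log-normal length parameters (bp).
#' @param length_coupling Added to `length_meanlog` for structured
#'   transcripts (0 = no length bias).
#' @param fasta_path If non-NULL, a FASTA of random sequences with these
#'   lengths is written there.
#' @param seed Integer seed.
#' @return List with `annotation` (an `atlas_go`), `lengths` (named
#'   vector), `planted_terms` (GO ID per node), `seed`.
#' @export
generate_go_and_lengths <- function(truth, odds = 8, p_planted = 0.4,
                                    n_background = 30, p_background = 0.05,
                                    length_meanlog = log(450),
                                    length_sdlog = 0.7,
                                    length_coupling = 0,
                                    fasta_path = NULL, seed = 1) {
  stopifnot(inherits(truth, "atlas_truth"))
  set.seed(seed)
  ids <- names(truth$node)
  n_nodes <- nrow(truth$templates)
  o0 <- (p_planted / (1 - p_planted)) / odds
  p0 <- o0 / (1 + o0)
  pairs <- list()
  planted_terms <- sprintf("GO:%07d", seq_len(n_nodes))
  for (u in seq_len(n_nodes)) {
    inside <- !is.na(truth$node) & truth$node == u
    pr <- ifelse(inside, p_planted, p0)
    hit <- runif(length(ids)) < pr
    if (any(hit))
      pairs[[length(pairs) + 1L]] <-
        data.frame(transcript_id = ids[hit], go_id = planted_terms[u])
  }
  bg_terms <- sprintf("GO:%07d", 1000L + seq_len(n_background))
  for (tm in bg_terms) {
    hit <- runif(length(ids)) < p_background
    if (any(hit))
      pairs[[length(pairs) + 1L]] <-
        data.frame(transcript_id = ids[hit], go_id = tm)
  }
  annotation <- go_annotation(do.call(rbind, pairs))
  meanlog <- length_meanlog + length_coupling * as.numeric(!is.na(truth$node))
  lengths <- pmax(100L, as.integer(round(rlnorm(length(ids), meanlog,
                                                length_sdlog))))
  names(lengths) <- ids
  if (!is.null(fasta_path)) {
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seqs, ids)),
                                fasta_path)
  }
  list(annotation = annotation, lengths = lengths,
       planted_terms = setNames(planted_terms,
                                rownames(truth$templates)), seed = seed)
}

#' Write a complete set of synthetic pipeline inputs to disk
#'
#' Generates the default synthetic atlas plus foreign atlas, homolog map,
#' GO annotation and contig FASTA, and writes `counts.tsv`, `sheet.tsv`,
#' `go.tsv`, `contigs.fasta`, `foreign_nodes.tsv`, `blast.tsv` and
#' `truth.json` under `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param ... Arguments forwarded to [generate_atlas()].
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_atlas_files <- function(out_dir, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_atlas(seed = seed, ...)
  foreign <- generate_foreign_atlas_and_homologs(sim$truth, seed = seed + 1)
  go <- generate_go_and_lengths(sim$truth, seed = seed + 2,
                                fasta_path = file.path(out_dir,
                                                       "contigs.fasta"))
  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                sheet = file.path(out_dir, "sheet.tsv"),
                go = file.path(out_dir, "go.tsv"),
                fasta = file.path(out_dir, "contigs.fasta"),
                foreign_nodes = file.path(out_dir, "foreign_nodes.tsv"),
                hits = file.path(out_dir, "blast.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_count_matrix(sim$counts, paths$counts, paths$sheet)
  write_go_annotation(go$annotation, paths$go)
  write.table(foreign$foreign_membership, paths$foreign_nodes,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_best_hits(foreign$hits, paths$hits)
  jsonlite::write_json(
    list(seed = seed,
         node = as.list(sim$truth$node),
         planted_terms = as.list(go$planted_terms)),
    paths$truth, auto_unbox = TRUE, null = "null")
  invisible(list(sim = sim, foreign = foreign, go = go, paths = paths))
}
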