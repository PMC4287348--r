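#' Run the full atlas pipeline from a configuration
#'
#' Composes the stages in order: count filter, TMM factors, CPM, common
#' dispersion, pairwise differential abundance, replicate averaging, row
#' scaling, PCA, SOM clustering, node summaries, and — when the inputs are
#' configured — per-node GO enrichment and the cross-species atlas
#' intersection.  All stage outputs are written as TSV under `out_dir`
#' together with a JSON run summary (parameters, seed, input checksums,
#' and the size of the data at each stage).
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure.  Recognized fields: `counts`, `sheet` (required paths);
#'   `go`, `fasta`, `hits`, `foreign_nodes` (optional paths); `out_dir`
#'   (required); `min_total` (default 30), `fdr` (0.05), `grid`
#'   (c(3, 2)), `topology` ("hexagonal"), `n_iter` (100), `alpha`
#'   (c(0.05, 0.01)), `seed` (1), `organ_levels` (NULL accepts any
#'   label).
#' @return The run summary list, invisibly (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_total = 30, fdr = 0.05, grid = c(3, 2),
                   topology = "hexagonal", n_iter = 100,
                   alpha = c(0.05, 0.01), seed = 1, organ_levels = NULL)
  cfg <- modifyList(defaults, config)
  for (field in c("counts", "sheet", "out_dir"))
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
  inputs <- cfg[intersect(c("counts", "sheet", "go", "fasta", "hits",
                            "foreign_nodes"), names(cfg))]
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  missing <- names(inputs)[!vapply(unlist(inputs), file.exists, logical(1))]
  if (length(missing) > 0L)
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing, unlist(inputs[missing])),
               collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cm <- stage("read", read_count_matrix(cfg$counts, cfg$sheet,
                                        organ_levels = cfg$organ_levels))
  n_input <- nrow(cm$counts)
  cm <- stage("filter", filter_low_counts(cm, cfg$min_total))
  factors <- stage("tmm", tmm_factors(cm))
  write.table(data.frame(sample_id = names(factors), factor = factors),
              out("tmm_factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nm <- stage("cpm", cpm(cm, factors))
  disp <- stage("dispersion",
                estimate_common_dispersion(cm, factors = factors))
  de <- stage("de", pairwise_de(cm, factors = factors,
                                dispersion = disp$common_dispersion,
                                threshold = cfg$fdr))
  for (pair in names(de)) {
    write.table(de[[pair]], out(sprintf("de_%s.tsv", gsub("\\|", "_vs_",
                                                          pair))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  union_ids <- stage("de_union", de_union(de, threshold = cfg$fdr))
  writeLines(union_ids, out("de_union.txt"))

  avg <- stage("average", average_replicates(nm))
  spm <- stage("scale",
               suppressWarnings(scale_rows(avg[union_ids, , drop = FALSE])))
  pca <- stage("pca", atlas_pca(spm, observations = "transcripts"))
  som <- stage("som", train_som(spm, grid = cfg$grid,
                                topology = cfg$topology,
                                n_iter = cfg$n_iter, alpha = cfg$alpha,
                                seed = cfg$seed))
  nodes <- stage("node_summary", node_summary(som, spm))
  write.table(nodes, out("node_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ids <- rownames(spm)
  n_pcs <- min(6L, ncol(pca$scores))
  atlas_tab <- data.frame(
    transcript_id = ids,
    setNames(as.data.frame(avg[ids, , drop = FALSE]),
             paste0("mean_", colnames(avg))),
    setNames(as.data.frame(unclass(spm)), paste0("sc_", colnames(spm))),
    setNames(as.data.frame(pca$scores[, seq_len(n_pcs), drop = FALSE]),
             paste0("PC", seq_len(n_pcs))),
    node = som$assignment[ids],
    distance = som$distance[ids],
    stringsAsFactors = FALSE, check.names = FALSE)
  write.table(atlas_tab, out("atlas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("siphonatlas")),
    seed = cfg$seed,
    parameters = cfg[c("min_total", "fdr", "grid", "topology", "n_iter",
                       "alpha")],
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    n_transcripts_input = n_input,
    n_transcripts_filtered = nrow(cm$counts),
    common_dispersion = disp$common_dispersion,
    de_union_size = length(union_ids),
    node_sizes = as.list(table(som$assignment)))

  if (!is.null(cfg$fasta)) {
    stats <- stage("assembly_stats", assembly_summary(cfg$fasta))
    jsonlite::write_json(stats, out("assembly_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$assembly <- stats
  }
  if (!is.null(cfg$go)) {
    ann <- stage("read_go", read_go_annotation(cfg$go))
    lengths <- if (!is.null(cfg$fasta)) read_contig_lengths(cfg$fasta)
    enr <- stage("enrich", enrich_nodes(som, ann, lengths = lengths,
                                        fdr = cfg$fdr))
    for (node in names(enr))
      write.table(enr[[node]], out(sprintf("enrichment_%s.tsv", node)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_enriched_terms <- vapply(enr, function(tab)
      sum(tab$significant), integer(1))
  }
  if (!is.null(cfg$hits) && !is.null(cfg$foreign_nodes)) {
    hits <- stage("read_hits", read_best_hits(cfg$hits))
    fm <- stage("read_foreign", .read_tsv(cfg$foreign_nodes))
    names(fm)[1:2] <- c("transcript_id", "node")
    genes <- stage("assign", assign_foreign_nodes(hits, fm,
                                                  queries = ids))
    inter <- stage("intersect",
                   intersection_chisq(genes, som$assignment,
                                      null_distribution(fm)))
    write.table(inter$summary, out("intersection_chisq.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(inter$obs_exp, out("intersection_obs_exp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(inter$genes, out("intersection_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$intersection_p <- setNames(inter$summary$p_value,
                                       inter$summary$source_node)
  }
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(summary)
}
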