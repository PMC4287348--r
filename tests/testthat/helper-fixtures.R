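# Small programmatic fixtures shared across test files.

tiny_counts <- function(counts = NULL, organs = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 20, 30,
                       5, 10, 15), nrow = 2, byrow = TRUE,
                     dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  if (is.null(organs)) organs <- rep("apex", ncol(counts))
  sheet <- data.frame(sample_id = colnames(counts), organ = organs,
                      stringsAsFactors = FALSE)
  count_matrix(counts, sheet, organ_levels = NULL)
}

write_blast_lines <- function(rows, path) {
  # rows: data.frame query, subject, pident, evalue, bitscore
  lines <- sprintf("%s\t%s\t%s\t100\t0\t0\t1\t100\t1\t100\t%s\t%s",
                   rows$query, rows$subject, rows$pident, rows$evalue,
                   rows$bitscore)
  writeLines(lines, path)
  path
}

# Straight-from-definition TMM oracle: unoptimized loop following the
# trimmed-mean-of-M-values definition (written before the package
# implementation; kept independent of it).
tmm_oracle_pair <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  m <- c(); a <- c(); v <- c()
  for (g in seq_along(obs)) {
    if (obs[g] > 0 && ref[g] > 0) {
      m <- c(m, log2((obs[g] / n_obs) / (ref[g] / n_ref)))
      a <- c(a, 0.5 * (log2(obs[g] / n_obs) + log2(ref[g] / n_ref)))
      v <- c(v, (n_obs - obs[g]) / (n_obs * obs[g]) +
               (n_ref - ref[g]) / (n_ref * ref[g]))
    }
  }
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rep(FALSE, n)
  rm <- rank(m); ra <- rank(a)
  for (g in seq_len(n))
    keep[g] <- rm[g] >= lo_m && rm[g] <= hi_m && ra[g] >= lo_a && ra[g] <= hi_a
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

# Shared default synthetic pipeline run (computed once per test session).
default_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- generate_atlas(seed = 1)
    cm <- filter_low_counts(sim$counts)
    factors <- tmm_factors(cm)
    nm <- cpm(cm, factors)
    disp <- estimate_common_dispersion(cm, factors = factors)
    de <- pairwise_de(cm, factors = factors,
                      dispersion = disp$common_dispersion)
    union_ids <- de_union(de)
    spm <- scale_rows(average_replicates(nm)[union_ids, , drop = FALSE])
    som <- train_som(spm, seed = 1)
    cache <<- list(sim = sim, cm = cm, factors = factors, nm = nm,
                   disp = disp, de = de, union_ids = union_ids,
                   spm = spm, som = som)
    cache
  }
})
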