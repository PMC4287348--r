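make_group_cm <- function(counts, groups) {
  cm <- tiny_counts(counts, organs = groups)
  cm
}

test_that("common dispersion is near zero for Poisson data", {
  set.seed(31)
  mu <- exp(runif(200, 3, 6))
  counts <- matrix(rpois(200 * 10, rep(mu, 10)), 200, 10,
                   dimnames = list(paste0("t", 1:200), paste0("s", 1:10)))
  cm <- make_group_cm(counts, rep(c("apex", "stolon"), each = 5))
  d <- estimate_common_dispersion(cm)
  expect_lt(d$common_dispersion, 0.05)
})

test_that("common dispersion recovers a planted value", {
  set.seed(37)
  mu <- exp(runif(1000, 3, 6))
  counts <- matrix(rnbinom(1000 * 10, mu = rep(mu, 10), size = 1 / 0.4),
                   1000, 10,
                   dimnames = list(paste0("t", 1:1000), paste0("s", 1:10)))
  cm <- make_group_cm(counts, rep(c("apex", "stolon"), each = 5))
  d <- estimate_common_dispersion(cm)
  expect_gt(d$common_dispersion, 0.25)
  expect_lt(d$common_dispersion, 0.6)
})

test_that("constant data gives dispersion 0 and single replicates error", {
  counts <- matrix(5, 50, 4, dimnames = list(paste0("t", 1:50),
                                             paste0("s", 1:4)))
  cm <- make_group_cm(counts, rep(c("apex", "stolon"), each = 2))
  expect_identical(estimate_common_dispersion(cm)$common_dispersion, 0)
  cm1 <- make_group_cm(counts[, 1:2], c("apex", "stolon"))
  expect_error(estimate_common_dispersion(cm1), "fixed dispersion")
})

test_that("exact test is symmetric and matches the binomial oracle", {
  a <- matrix(c(10, 20), 1, 2); b <- matrix(c(15, 15), 1, 2)
  rownames(a) <- rownames(b) <- "t1"
  expect_equal(nb_exact_test(a, b, 0.1)$p_value, 1)  # equal group sums

  # Poisson limit, equal sizes: conditional binomial oracle from raw tails
  set.seed(41)
  for (i in 1:100) {
    z <- sample(5:400, 1)
    za <- sample(0:z, 1)
    a <- matrix(c(za, 0), 1, 2); b <- matrix(c(z - za, 0), 1, 2)
    p <- nb_exact_test(a, b, 0)$p_value
    lo <- sum(dbinom(0:za, z, 0.5))
    hi <- sum(dbinom(za:z, z, 0.5))
    expect_equal(p, min(1, 2 * min(lo, hi)), tolerance = 1e-9)
  }

  # extreme split
  a <- matrix(c(50, 50), 1, 2); b <- matrix(c(0, 0), 1, 2)
  expect_equal(nb_exact_test(a, b, 0)$p_value, 2 * 0.5^100,
               tolerance = 1e-12)
  expect_error(nb_exact_test(a, b, -0.1), ">= 0")
})

test_that("exact test controls type-I error on null NB data", {
  set.seed(43)
  n <- 2000
  mu <- exp(runif(n, 3.5, 6))
  counts <- matrix(rnbinom(n * 10, mu = rep(mu, 10), size = 1 / 0.1),
                   n, 10, dimnames = list(paste0("t", 1:n),
                                          paste0("s", 1:10)))
  cm <- make_group_cm(counts, rep(c("apex", "stolon"), each = 5))
  d <- estimate_common_dispersion(cm)
  res <- nb_exact_test(cm$counts[, 1:5], cm$counts[, 6:10],
                       d$common_dispersion)
  rate <- mean(res$p_value < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("planted four-fold changes are detected with high power", {
  set.seed(47)
  n <- 400
  mu <- exp(runif(n, 4, 6))
  a <- matrix(rnbinom(n * 5, mu = rep(mu, 5), size = 10), n, 5)
  b <- matrix(rnbinom(n * 5, mu = rep(4 * mu, 5), size = 10), n, 5)
  rownames(a) <- rownames(b) <- paste0("t", 1:n)
  res <- nb_exact_test(a, b, 0.1)
  res$fdr <- bh_fdr(res$p_value)
  expect_gt(mean(res$fdr < 0.05), 0.8)
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.007), 0.007)
  # monotone non-decreasing in p-value rank
  set.seed(53)
  p <- runif(200)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("pairwise DE enumerates all organ pairs and unions hits", {
  set.seed(59)
  sim <- generate_atlas(n_transcripts = 300, seed = 59)
  cm <- filter_low_counts(sim$counts)
  de <- pairwise_de(cm, dispersion = 0.1)
  expect_length(de, 15L)  # 6 choose 2
  expect_true(all(c("apex|holdfast", "pinnule|rachis") %in% names(de)))
  u <- de_union(de)
  one_pair_only <- de[["apex|holdfast"]]
  sig <- one_pair_only$transcript_id[one_pair_only$significant]
  expect_true(all(sig %in% u))
  expect_error(de_union(de[-1], organs = attr(de, "organs")),
               "apex|frond_base")
})

test_that("de_union warns when nothing is significant", {
  tabs <- lapply(1:1, function(i)
    data.frame(transcript_id = "t1", log_fc = 0, p_value = 1, fdr = 1,
               significant = FALSE))
  names(tabs) <- "apex|stolon"
  expect_warning(u <- de_union(tabs, organs = c("apex", "stolon")),
                 "no transcript")
  expect_length(u, 0L)
})
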