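test_that("foreign node assignment maps subjects and logs exclusions", {
  hits <- data.frame(query_id = c("q1", "q2", "q3"),
                     subject_id = c("f1", "f2", "f9"),
                     percent_identity = c(90, 80, 70),
                     e_value = c(1e-30, 1e-20, 1e-10),
                     bit_score = c(300, 200, 100))
  fm <- data.frame(transcript_id = c("f1", "f2"), node = c("3", "1"))
  out <- assign_foreign_nodes(hits, fm, queries = c("q1", "q2", "q3", "q4"))
  expect_identical(out$foreign_node[out$query_id == "q1"], "3")
  expect_identical(nrow(out), 2L)  # q3's subject has no node
  excl <- attr(out, "excluded")
  expect_identical(excl[["no_hit"]], 1L)              # q4
  expect_identical(excl[["subject_without_node"]], 1L)  # q3
})

test_that("null distribution is the foreign node proportions", {
  fm <- c(a = "1", b = "1", c = "2", d = "2")
  expect_equal(null_distribution(fm), c("1" = 0.5, "2" = 0.5))
  set.seed(139)
  fm2 <- setNames(as.character(sample(1:5, 500, replace = TRUE)),
                  paste0("f", 1:500))
  expect_equal(sum(null_distribution(fm2)), 1, tolerance = 1e-12)
  expect_error(null_distribution(character(0)), "empty")
})

test_that("chi-squared statistic matches hand computation and the oracle", {
  genes <- data.frame(query_id = paste0("q", 1:40),
                      subject_id = paste0("f", 1:40),
                      foreign_node = rep(c("1", "2"), c(10, 30)),
                      percent_identity = 80, e_value = 1e-20,
                      bit_score = 100)
  sn <- setNames(rep("A", 40), paste0("q", 1:40))
  res <- intersection_chisq(genes, sn, c("1" = 0.5, "2" = 0.5))
  expect_equal(res$summary$chisq, 10)
  expect_identical(res$summary$df, 1L)
  expect_equal(res$summary$p_value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$summary$p_value, 0.001565, tolerance = 1e-3)
  # cross-check against the reference goodness-of-fit test
  ref <- chisq.test(c(10, 30), p = c(0.5, 0.5))
  expect_equal(res$summary$chisq, unname(ref$statistic))
  expect_equal(res$summary$p_value, unname(ref$p.value))
  # observed/expected bookkeeping
  expect_equal(sum(res$obs_exp$expected), sum(res$obs_exp$observed))
  expect_equal(res$obs_exp$fold,
               res$obs_exp$observed / res$obs_exp$expected)
})

test_that("proportional observed counts give chisq 0 and p 1", {
  genes <- data.frame(query_id = paste0("q", 1:30),
                      subject_id = paste0("f", 1:30),
                      foreign_node = rep(c("1", "2", "3"), each = 10),
                      percent_identity = 80, e_value = 1e-20,
                      bit_score = 100)
  sn <- setNames(rep("A", 30), paste0("q", 1:30))
  res <- intersection_chisq(genes, sn,
                            c("1" = 1/3, "2" = 1/3, "3" = 1/3))
  expect_equal(res$summary$chisq, 0)
  expect_equal(res$summary$p_value, 1)
  # invariance under category permutation
  res2 <- intersection_chisq(genes, sn,
                             c("3" = 1/3, "1" = 1/3, "2" = 1/3))
  expect_equal(res2$summary$chisq, res$summary$chisq)
})

test_that("degenerate chi-squared inputs error clearly", {
  genes <- data.frame(query_id = "q1", subject_id = "f1",
                      foreign_node = "1", percent_identity = 80,
                      e_value = 1e-20, bit_score = 100)
  sn <- c(q1 = "A")
  expect_error(intersection_chisq(genes, sn, c("1" = 1)), "df")
  expect_error(
    suppressWarnings(intersection_chisq(genes, sn, c("1" = 0, "2" = 1))),
    "merge")
})

test_that("chi-squared p-values are calibrated under the null", {
  set.seed(149)
  props <- c("1" = 0.2, "2" = 0.3, "3" = 0.5)
  stats <- replicate(2000, {
    obs <- as.numeric(rmultinom(1, 60, props))
    sum((obs - 60 * props)^2 / (60 * props))
  })
  p <- pchisq(stats, 2, lower.tail = FALSE)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("planted association is detected while null nodes stay flat", {
  sim <- generate_atlas(n_transcripts = 2200, fraction_null = 0, seed = 151)
  assoc <- matrix(1 / 9, 6, 9)
  assoc[1, ] <- c(0.6, rep(0.4 / 8, 8))  # node 1 prefers foreign node 1
  fh <- generate_foreign_atlas_and_homologs(sim$truth, association = assoc,
                                            hit_fraction = 1, seed = 151)
  genes <- assign_foreign_nodes(fh$hits, fh$foreign_membership)
  sn <- setNames(as.character(sim$truth$node), names(sim$truth$node))
  res <- intersection_chisq(genes, sn,
                            null_distribution(fh$foreign_membership))
  p1 <- res$summary$p_value[res$summary$source_node == "1"]
  expect_gte(res$summary$n[res$summary$source_node == "1"], 300)
  expect_lt(p1, 0.01)
  others <- res$summary$p_value[res$summary$source_node != "1"]
  expect_gt(min(others), 0.001)  # no spurious strong association
})
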