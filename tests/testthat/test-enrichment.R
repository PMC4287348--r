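make_ann <- function(pairs) {
  go_annotation(data.frame(transcript_id = pairs[[1]], go_id = pairs[[2]]))
}

test_that("hypergeometric p matches exhaustive enumeration on the toy", {
  # N=10, n=5, K=4, k=4: enumerate all C(10,4) draws
  universe <- paste0("t", 1:10)
  term <- paste0("t", 1:5)
  node <- paste0("t", 1:4)       # 4 of the 5 term members
  draws <- combn(universe, 4, simplify = FALSE)
  exhaustive <- mean(vapply(draws, function(d)
    sum(d %in% term) >= 4, logical(1)))
  expect_equal(exhaustive, 5 / 210, tolerance = 1e-12)
  ann <- make_ann(list(term, rep("GO:0000001", 5)))
  res <- hypergeom_enrich(node, universe, ann)
  expect_equal(res$p_value[res$go_id == "GO:0000001"], 5 / 210,
               tolerance = 1e-12)
  expect_identical(res$k[res$go_id == "GO:0000001"], 4L)
})

test_that("degenerate enrichment cases give p = 1", {
  universe <- paste0("t", 1:10)
  ann <- make_ann(list(c("t1", "t2", "t9"),
                       c("GO:0000001", "GO:0000001", "GO:0000002")))
  # node = universe: every term fully contained
  res <- hypergeom_enrich(universe, universe, ann)
  expect_true(all(res$p_value == 1))
  # term absent from node (k = 0)
  res2 <- hypergeom_enrich(c("t3", "t4"), universe, ann)
  expect_true(all(res2$p_value == 1))
  expect_error(hypergeom_enrich(c("t1", "zzz"), universe, ann), "zzz")
})

test_that("enrichment p is monotone decreasing in overlap k", {
  universe <- paste0("t", 1:40)
  term <- paste0("t", 1:10)
  ps <- vapply(1:8, function(k) {
    node <- c(term[seq_len(k)], setdiff(universe, term)[seq_len(8 - k)])
    ann <- make_ann(list(term, rep("GO:0000007", 10)))
    hypergeom_enrich(node, universe, ann)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(113)
  N <- 2000; K <- 500
  universe <- paste0("t", 1:N)
  node <- sample(universe, K)
  n_terms <- 2000
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  pairs <- do.call(rbind, lapply(seq_len(n_terms), function(i)
    data.frame(transcript_id = sample(universe, 100), go_id = ids[i])))
  res <- hypergeom_enrich(node, universe, go_annotation(pairs))
  # discrete upper-tail p-values are super-uniform; KS distance stays small
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("Wallenius at odds 1 equals the classical hypergeometric tail", {
  for (case in list(c(k = 3, n = 8, N = 30, K = 10),
                    c(k = 5, n = 5, N = 12, K = 6),
                    c(k = 1, n = 4, N = 50, K = 7))) {
    w <- siphonatlas:::.wallenius_upper(case["k"], case["n"],
                                        case["N"] - case["n"], case["K"],
                                        w = 1)
    h <- phyper(case["k"] - 1, case["n"], case["N"] - case["n"],
                case["K"], lower.tail = FALSE)
    expect_equal(unname(w), unname(h), tolerance = 1e-9)
  }
})

test_that("wallenius_enrich reduces to hypergeometric for uniform lengths", {
  set.seed(127)
  universe <- paste0("t", 1:60)
  node <- sample(universe, 15)
  ann <- make_ann(list(sample(universe, 20), rep("GO:0000003", 20)))
  lengths <- setNames(rep(500, 60), universe)
  wal <- wallenius_enrich(node, universe, ann, lengths)
  hyp <- hypergeom_enrich(node, universe, ann)
  expect_equal(wal$p_value, hyp$p_value, tolerance = 1e-6)
  expect_identical(unique(wal$method), "wallenius")
})

test_that("length bias is discounted by the Wallenius test", {
  set.seed(131)
  N <- 800
  universe <- paste0("t", 1:N)
  lengths <- setNames(round(exp(rnorm(N, log(600), 0.8))), universe)
  # selection probability proportional to length
  node <- sample(universe, 200, prob = lengths)
  # a GO category made of long transcripts
  long_term <- universe[order(-lengths)[1:60]]
  ann <- make_ann(list(long_term, rep("GO:0000009", 60)))
  wal <- wallenius_enrich(node, universe, ann, lengths)
  hyp <- hypergeom_enrich(node, universe, ann)
  expect_gt(wal$p_value[wal$go_id == "GO:0000009"],
            hyp$p_value[hyp$go_id == "GO:0000009"])
})

test_that("missing lengths trigger the hypergeometric fallback", {
  universe <- paste0("t", 1:20)
  ann <- make_ann(list(universe[1:6], rep("GO:0000004", 6)))
  lengths <- setNames(rep(300, 5), universe[1:5])
  expect_warning(res <- wallenius_enrich(universe[1:4], universe, ann,
                                         lengths),
                 "hypergeometric")
  expect_identical(unique(res$method), "hypergeometric")
})

test_that("a planted GO term is recovered at FDR < 0.05", {
  sim <- generate_atlas(n_transcripts = 1500, seed = 137)
  go <- generate_go_and_lengths(sim$truth, odds = 8, seed = 137)
  universe <- names(sim$truth$node)
  node1 <- universe[!is.na(sim$truth$node) & sim$truth$node == 1]
  res <- hypergeom_enrich(node1, universe, go$annotation)
  planted <- go$planted_terms[["planted1"]]
  expect_true(res$significant[res$go_id == planted])
  # the planted term ranks at (or near) the top
  expect_lte(which(res$go_id == planted), 2L)
})

test_that("odds-1 planting is usually not significant", {
  hits <- vapply(1:10, function(s) {
    sim <- generate_atlas(n_transcripts = 600, seed = 200 + s)
    go <- generate_go_and_lengths(sim$truth, odds = 1, seed = 200 + s)
    universe <- names(sim$truth$node)
    node1 <- universe[!is.na(sim$truth$node) & sim$truth$node == 1]
    res <- hypergeom_enrich(node1, universe, go$annotation)
    res$significant[res$go_id == go$planted_terms[["planted1"]]]
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})
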