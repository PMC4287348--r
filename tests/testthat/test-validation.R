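test_that("LDA matches a brute-force Bayes-rule oracle on a 2-class toy", {
  set.seed(89)
  x <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(80, 2.5, 1), 40, 2))
  labs <- rep(c("a", "b"), c(30, 40))
  fit <- lda_fit(x, labs)
  # oracle: evaluate the Gaussian discriminant formula point by point
  mu_a <- colMeans(x[labs == "a", ]); mu_b <- colMeans(x[labs == "b", ])
  ca <- sweep(x[labs == "a", ], 2, mu_a); cb <- sweep(x[labs == "b", ], 2, mu_b)
  s <- (crossprod(ca) + crossprod(cb)) / (nrow(x) - 2)
  si <- solve(s)
  pr <- c(a = 30, b = 40) / 70
  oracle <- apply(x, 1, function(p) {
    da <- p %*% si %*% mu_a - 0.5 * mu_a %*% si %*% mu_a + log(pr["a"])
    db <- p %*% si %*% mu_b - 0.5 * mu_b %*% si %*% mu_b + log(pr["b"])
    if (da >= db) "a" else "b"
  })
  expect_identical(predict(fit, x), unname(oracle))
})

test_that("LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(97)
  x <- matrix(rnorm(300 * 4), 300, 4)
  labs <- sample(letters[1:3], 300, replace = TRUE)
  x[labs == "b", 1] <- x[labs == "b", 1] + 2
  x[labs == "c", 2] <- x[labs == "c", 2] - 2
  fit <- lda_fit(x, labs)
  ref <- MASS::lda(x, grouping = labs)
  expect_identical(predict(fit, x),
                   as.character(predict(ref, x)$class))
})

test_that("perfectly separated classes reassign completely", {
  x <- rbind(matrix(rnorm(100, -5, 0.5), 50, 2),
             matrix(rnorm(100, 5, 0.5), 50, 2))
  labs <- rep(c("lo", "hi"), each = 50)
  fit <- lda_fit(x, labs)
  fr <- reassignment_fractions(x, labs, fit)
  expect_equal(unname(fr), c(1, 1))
  # permutation-invariance of the fractions under relabelling
  relab <- ifelse(labs == "lo", "B", "A")
  fr2 <- reassignment_fractions(x, relab, lda_fit(x, relab))
  expect_equal(sort(unname(fr2)), sort(unname(fr)))
})

test_that("duplicated clusters confuse the classifier down to the prior", {
  set.seed(101)
  blob <- matrix(rnorm(400 * 3), 400, 3)
  labs <- rep(c("c1", "c2"), 200)  # interleaved identical clusters
  fit <- lda_fit(blob, labs)
  fr <- reassignment_fractions(blob, labs, fit)
  expect_true(all(fr < 0.75))  # far below 1, near the 0.5 prior
})

test_that("priors shift the boundary toward the smaller class", {
  set.seed(103)
  a <- matrix(rnorm(200, -1, 1), 100, 2)
  b <- matrix(rnorm(200, 1, 1), 100, 2)
  x <- rbind(a, b)
  labs <- rep(c("a", "b"), each = 100)
  base <- predict(lda_fit(x, labs), x)
  # triple class a: more points now predicted "a"
  x2 <- rbind(a, a, a, b)
  labs2 <- rep(c("a", "b"), c(300, 100))
  heavy <- predict(lda_fit(x2, labs2), x)
  expect_gt(sum(heavy == "a"), sum(base == "a"))
})

test_that("singleton classes are excluded with a warning", {
  x <- rbind(matrix(rnorm(40), 20, 2), c(50, 50),
             matrix(rnorm(40, 5), 20, 2))
  labs <- c(rep("a", 20), "lone", rep("b", 20))
  expect_warning(fit <- lda_fit(x, labs), "lone")
  expect_setequal(fit$classes, c("a", "b"))
  expect_error(suppressWarnings(lda_fit(x[c(1, 21), ], c("a", "lone"))),
               "class")
})

test_that("a single validation run composes train_som and lda_fit", {
  set.seed(107)
  x <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(paste0("t", 1:200), NULL))
  v <- validate_cluster_numbers(x, grids = list(c(1, 2)), n_runs = 1,
                                master_seed = 5)
  # derived seed is master_seed + 1
  som <- train_som(x, grid = c(1, 2), seed = 6)
  pca <- atlas_pca(x)
  fit <- lda_fit(pca$scores[, 1:5], as.character(som$assignment))
  fr <- reassignment_fractions(pca$scores[, 1:5],
                               as.character(som$assignment), fit)
  got <- setNames(v$fractions$fraction, v$fractions$cluster)
  expect_equal(got[names(fr)], fr)
})

test_that("validation results are bit-reproducible under a fixed seed", {
  set.seed(109)
  x <- matrix(rnorm(150 * 6), 150, 6,
              dimnames = list(paste0("t", 1:150), NULL))
  v1 <- validate_cluster_numbers(x, grids = list(c(1, 2), c(2, 2)),
                                 n_runs = 3, master_seed = 11)
  v2 <- validate_cluster_numbers(x, grids = list(c(1, 2), c(2, 2)),
                                 n_runs = 3, master_seed = 11)
  expect_identical(v1$fractions, v2$fractions)
  expect_identical(v1$recommended_k, v2$recommended_k)
  expect_error(validate_cluster_numbers(x, grids = list()), "empty")
})

test_that("six-node synthetic data scores higher at k=6 than k=8 or k=12", {
  sim <- generate_atlas(n_transcripts = 1200, fraction_null = 0, seed = 13)
  nm <- cpm(filter_low_counts(sim$counts))
  spm <- scale_rows(average_replicates(nm))
  v <- validate_cluster_numbers(spm, grids = list(c(3, 2), c(2, 4),
                                                  c(3, 4)),
                                n_runs = 10, master_seed = 13)
  expect_gt(v$medians[["6"]], v$medians[["8"]])
  expect_gt(v$medians[["6"]], v$medians[["12"]])
})
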