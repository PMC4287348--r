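#' Fit a Gaussian linear discriminant model
#'
#' Class means, pooled within-class covariance and log-priors; observations
#' are classified to the class maximizing the linear discriminant score
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`.  Classes with a single
#' member are excluded with a warning (their covariance contribution is
#' undefined).  If the pooled covariance is numerically singular a ridge of
#' `1e-8 * trace/d` is added to its diagonal.
#'
#' @param scores Numeric matrix of observations x features (e.g. PC
#'   scores).
#' @param labels Class label per observation.
#' @param prior `"proportional"` (class sizes) or `"equal"`.
#' @return Object of class `atlas_lda` with `means`, `cov_inv`, `log_prior`,
#'   `classes`.
#' @export
lda_fit <- function(scores, labels, prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  cnt <- table(labels)
  single <- names(cnt)[cnt < 2L]
  if (length(single) > 0L) {
    if (length(single) == length(cnt))
      stop("all classes have a single member")
    warning("excluding singleton class(es): ",
            paste(single, collapse = ", "))
    keep <- !(labels %in% single)
    scores <- scores[keep, , drop = FALSE]
    labels <- labels[keep]
    cnt <- table(labels)
  }
  classes <- names(cnt)
  if (length(classes) < 2L) stop("need >= 2 classes with >= 2 members")
  d <- ncol(scores)
  means <- t(vapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]), numeric(d)))
  pooled <- matrix(0, d, d)
  for (cl in classes) {
    xc <- sweep(scores[labels == cl, , drop = FALSE], 2L, means[cl, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (nrow(scores) - length(classes))
  cov_inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(cov_inv)) {
    pooled <- pooled + diag(1e-8 * sum(diag(pooled)) / d, d)
    cov_inv <- solve(pooled)
  }
  pr <- if (prior == "proportional") as.numeric(cnt) / sum(cnt)
        else rep(1 / length(classes), length(classes))
  structure(list(means = means, cov_inv = cov_inv,
                 log_prior = setNames(log(pr), classes), classes = classes),
            class = "atlas_lda")
}

#' Predict classes from a fitted discriminant model
#'
#' @param object An `atlas_lda` model.
#' @param newdata Matrix of observations x features.
#' @param ... Ignored.
#' @return Character vector of predicted class labels.
#' @export
predict.atlas_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  a <- object$means %*% object$cov_inv              # classes x d
  const <- -0.5 * rowSums(a * object$means) + object$log_prior
  scores <- x %*% t(a)                              # n x classes
  scores <- sweep(scores, 2L, const, "+")
  object$classes[max.col(scores, ties.method = "first")]
}

#' Fraction of each cluster re-predicted into itself
#'
#' For each class, the fraction of its members whose LDA-predicted class
#' equals the original label (self-prediction on the fitting data).  Near 1
#' means the cluster occupies its own region of the score space; clusters
#' that duplicate each other confuse the classifier and score far below 1.
#'
#' @param scores Matrix used to fit (or evaluate) the model.
#' @param labels Original cluster labels.
#' @param model An `atlas_lda` model fitted on the same label set.
#' @return Named numeric vector of per-class fractions in \[0, 1\].
#' @export
reassignment_fractions <- function(scores, labels, model) {
  labels <- as.character(labels)
  keep <- labels %in% model$classes
  pred <- predict(model, as.matrix(scores)[keep, , drop = FALSE])
  labs <- labels[keep]
  vapply(split(pred == labs, labs), mean, numeric(1))
}

#' Validate candidate SOM cluster numbers by LDA reassignment
#'
#' For each candidate grid, trains `n_runs` SOMs with seeds derived from
#' `master_seed` by a counter, fits an LDA on principal components 1-5
#' against each run's cluster labels, and records per-cluster reassignment
#' fractions.  The recommended cluster number is the largest cluster count
#' whose median fraction is at least `threshold` and within `tolerance` of
#' the median at the smallest grid (a codified form of "reassignment has
#' not yet dropped"); the raw per-run fractions are always returned so any
#' other rule can be applied.
#'
#' @param spm Scaled profile matrix (rows clustered by the SOM).
#' @param grids List of `c(rows, cols)` grids to evaluate.
#' @param n_runs SOM trainings per grid.
#' @param master_seed Integer master seed.
#' @param pca Optional `atlas_pca` of `spm` (computed when `NULL`).
#' @param n_pcs Number of leading PCs for the LDA (default 5; with six
#'   organ variables and row-scaled profiles the sixth PC carries
#'   negligible variance).
#' @param topology Grid topology passed to [train_som()].
#' @param threshold,tolerance Parameters of the recommendation rule.
#' @param ... Further arguments to [train_som()] (e.g. `n_iter`, `alpha`).
#' @return Object of class `atlas_validation`: `fractions` (long data
#'   frame: grid, k, run, seed, cluster, fraction), `medians` (per grid),
#'   `recommended_k`, `n_runs`, `master_seed`.
#' @export
validate_cluster_numbers <- function(spm, grids, n_runs = 100,
                                     master_seed = 1, pca = NULL,
                                     n_pcs = 5, topology = "hexagonal",
                                     threshold = 0.8, tolerance = 0.05,
                                     ...) {
  if (length(grids) == 0L) stop("empty grid list")
  x <- as.matrix(spm)
  if (is.null(pca)) pca <- atlas_pca(x, observations = "transcripts")
  pcs <- pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE]
  counter <- 0L
  rows <- list()
  for (g in grids) {
    k <- g[1L] * g[2L]
    glab <- sprintf("%dx%d", g[1L], g[2L])
    for (r in seq_len(n_runs)) {
      counter <- counter + 1L
      seed <- (master_seed + counter) %% .Machine$integer.max
      som <- train_som(x, grid = g, topology = topology, seed = seed, ...)
      labs <- as.character(som$assignment)
      present <- names(table(labs))[table(labs) >= 2L]
      if (length(present) < 2L) next  # degenerate run, logged by omission
      fit <- suppressWarnings(lda_fit(pcs, labs))
      fr <- reassignment_fractions(pcs, labs, fit)
      rows[[length(rows) + 1L]] <-
        data.frame(grid = glab, k = k, run = r, seed = seed,
                   cluster = names(fr), fraction = as.numeric(fr),
                   stringsAsFactors = FALSE)
    }
  }
  fractions <- do.call(rbind, rows)
  med <- vapply(split(fractions$fraction, fractions$k), median, numeric(1))
  ks <- as.integer(names(med))
  ord <- order(ks)
  med <- med[ord]; ks <- ks[ord]
  base <- med[1L]
  ok <- med >= threshold & med >= base - tolerance
  recommended_k <- if (any(ok)) max(ks[ok]) else ks[1L]
  structure(list(fractions = fractions,
                 medians = setNames(med, ks),
                 recommended_k = recommended_k,
                 n_runs = n_runs, master_seed = master_seed,
                 threshold = threshold, tolerance = tolerance),
            class = "atlas_validation")
}

#' @export
print.atlas_validation <- function(x, ...) {
  cat("atlas_validation: median reassignment by cluster number\n")
  print(round(x$medians, 3))
  cat("recommended k:", x$recommended_k, "\n")
  invisible(x)
}
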