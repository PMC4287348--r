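#' Average normalized abundance across replicates per pseudo-organ
#'
#' @param nm An `atlas_norm` object (or a values matrix plus `sheet`).
#' @param sheet Optional sample sheet (`sample_id`, `organ`); taken from
#'   `nm` when omitted.
#' @param organ_order Column order of the result; defaults to the order of
#'   [atlas_organs] restricted to organs present, then any others.
#' @return Matrix, transcripts x organs, of mean CPM.
#' @export
average_replicates <- function(nm, sheet = NULL, organ_order = NULL) {
  if (inherits(nm, "atlas_norm")) {
    values <- nm$values
    if (is.null(sheet)) sheet <- nm$sample_sheet
  } else {
    values <- as.matrix(nm)
  }
  if (is.null(sheet)) stop("a sample sheet is required")
  organ <- sheet$organ[match(colnames(values), sheet$sample_id)]
  if (any(is.na(organ))) stop("sample missing from sheet: ",
                              colnames(values)[which(is.na(organ))[1L]])
  organs <- unique(organ)
  if (is.null(organ_order))
    organ_order <- c(intersect(atlas_organs, organs),
                     setdiff(organs, atlas_organs))
  if (!setequal(organ_order, organs))
    stop("organ_order must match the organs present")
  out <- vapply(organ_order, function(o) {
    j <- which(organ == o)
    if (length(j) == 0L) stop("pseudo-organ with no samples: ", o)
    rowMeans(values[, j, drop = FALSE])
  }, numeric(nrow(values)))
  rownames(out) <- rownames(values)
  out
}

#' Scale each transcript's profile to mean 0, variance 1
#'
#' Rows are centred and scaled with the n-1 standard deviation so that
#' every transcript's accumulation profile across pseudo-organs has mean 0
#' and variance 1.  Constant rows (zero variance) cannot be scaled and are
#' dropped with a warning naming them.
#'
#' @param m Matrix, transcripts x organs.
#' @return Matrix of class `atlas_profiles` with row-scaled values.
#' @export
scale_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- s == 0 | !is.finite(s)
  if (all(const)) stop("all rows are constant; nothing to scale")
  if (any(const)) {
    warning(sprintf("dropping %d constant row(s): %s", sum(const),
                    paste(head(rownames(m)[const], 5L), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
    mu <- mu[!const]; s <- s[!const]
  }
  out <- (m - mu) / s
  class(out) <- c("atlas_profiles", class(out))
  out
}

#' Principal component analysis of an expression matrix
#'
#' Column-centred, SVD-based PCA (via [stats::prcomp()]).  With
#' `observations = "transcripts"` the rows (transcript profiles) are the
#' observations and the organs the variables; `observations = "samples"`
#' transposes first, so samples/organs are the observations.
#'
#' @param m Matrix (transcripts x organs or transcripts x samples).
#' @param observations Which margin forms the observations.
#' @param scale. Scale variables to unit variance before PCA.
#' @return List of class `atlas_pca`: `scores`, `loadings`,
#'   `var_explained` (fractions, non-increasing), `sdev`, `center`.
#' @export
atlas_pca <- function(m, observations = c("transcripts", "samples"),
                      scale. = FALSE) {
  observations <- match.arg(observations)
  x <- as.matrix(m)
  if (observations == "samples") x <- t(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs at least 2 observations and 2 variables")
  fit <- prcomp(x, center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, loadings = fit$rotation,
                 var_explained = ve, sdev = fit$sdev, center = fit$center),
            class = "atlas_pca")
}

#' @export
print.atlas_pca <- function(x, ...) {
  cat("atlas_pca:", nrow(x$scores), "observations;",
      "variance explained:",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 6L)),
            collapse = " "), "\n")
  invisible(x)
}
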