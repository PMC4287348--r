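#' Grid-space coordinates of SOM units
#'
#' Units are numbered row-major over a `rows` x `cols` grid.  Hexagonal
#' topology uses odd-row offset coordinates: even-numbered rows are shifted
#' half a unit right and rows are sqrt(3)/2 apart, so neighbouring hexagon
#' centres are distance 1 apart.
#'
#' @param rows,cols Grid dimensions.
#' @param topology `"hexagonal"` or `"rectangular"`.
#' @return List with `coords` (k x 2 matrix), `dist` (k x k distances),
#'   `rows`, `cols`, `topology`.
#' @export
som_grid <- function(rows, cols, topology = c("hexagonal", "rectangular")) {
  topology <- match.arg(topology)
  stopifnot(rows >= 1, cols >= 1)
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  if (topology == "hexagonal") {
    x <- ij$col + 0.5 * ((ij$row - 1) %% 2)
    y <- (ij$row - 1) * sqrt(3) / 2
  } else {
    x <- ij$col
    y <- ij$row
  }
  coords <- cbind(x = x, y = y)
  list(coords = coords, dist = as.matrix(dist(coords)),
       rows = rows, cols = cols, topology = topology)
}

#' Train a self-organizing map on scaled accumulation profiles
#'
#' Online (sequential) SOM: the codebook is initialized from a seeded
#' random sample of data rows; each training iteration presents every row
#' once in a seeded random order; the winning unit is the one at minimal
#' Euclidean distance (ties to the lowest unit index); all units within the
#' current neighbourhood radius of the winner move toward the presented row
#' by `alpha(t) * (x - w)` (bubble neighbourhood).  The learning rate
#' decreases linearly between `alpha[1]` and `alpha[2]` over the
#' iterations, and the radius linearly from 2/3 of the maximum inter-unit
#' grid distance to 0.
#'
#' @param spm Numeric matrix of row profiles (e.g. from [scale_rows()]);
#'   at least as many rows as grid units.
#' @param grid Integer vector `c(rows, cols)`.
#' @param topology Grid topology, hexagonal by default.
#' @param n_iter Number of training iterations (full passes).
#' @param alpha Length-2 learning-rate schedule `c(start, end)`.
#' @param radius Optional starting radius; default 2/3 of the largest
#'   inter-unit distance.
#' @param seed Integer seed controlling initialization and presentation
#'   order.
#' @return Object of class `atlas_som`: `codebook` (units x organs),
#'   `grid`, `assignment` (named unit index per row), `distance` (named
#'   Euclidean distance to the assigned codebook), `mean_dist_per_iter`,
#'   plus the training parameters.
#' @export
train_som <- function(spm, grid = c(3, 2), topology = "hexagonal",
                      n_iter = 100, alpha = c(0.05, 0.01), radius = NULL,
                      seed = 1) {
  x <- unclass(as.matrix(spm))
  if (any(!is.finite(x))) stop("profiles must be finite")
  g <- som_grid(grid[1L], grid[2L], topology)
  k <- nrow(g$coords)
  if (nrow(x) < k) stop("fewer data rows than grid units")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  set.seed(seed)
  init_idx <- sample.int(nrow(x), k)
  codebook0 <- x[init_idx, , drop = FALSE]
  orders <- vapply(seq_len(n_iter), function(t) sample.int(nrow(x)),
                   integer(nrow(x)))
  sched <- if (n_iter == 1L) 0 else (seq_len(n_iter) - 1) / (n_iter - 1)
  alphas <- alpha[1L] + (alpha[2L] - alpha[1L]) * sched
  r0 <- if (is.null(radius)) (2 / 3) * max(g$dist) else radius
  radii <- r0 * (1 - sched)
  fit <- som_train_cpp(x, codebook0, orders, alphas, radii, g$dist)
  asg <- som_assign_cpp(x, fit$codebook)
  codebook <- fit$codebook
  dimnames(codebook) <- list(paste0("node", seq_len(k)), colnames(x))
  structure(list(codebook = codebook, grid = g,
                 assignment = setNames(asg$unit, rownames(x)),
                 distance = setNames(asg$distance, rownames(x)),
                 mean_dist_per_iter = fit$mean_dist,
                 n_iter = n_iter, alpha = alpha, radius_start = r0,
                 seed = seed),
            class = "atlas_som")
}

#' @export
print.atlas_som <- function(x, ...) {
  cat(sprintf("atlas_som: %dx%d %s grid, %d profiles, %d iterations\n",
              x$grid$rows, x$grid$cols, x$grid$topology,
              length(x$assignment), x$n_iter))
  print(table(node = x$assignment))
  invisible(x)
}

#' Per-node summary of a trained SOM
#'
#' For each grid unit: member count, the median scaled abundance per
#' pseudo-organ over its members, and the organs whose median scaled
#' abundance exceeds 0 (the organs a node's transcripts preferentially
#' accumulate in).
#'
#' @param model An `atlas_som` model.
#' @param spm The profile matrix the model was trained on.
#' @return Data frame with one row per node: `node`, `n_members`,
#'   `high_organs` (comma-separated), and one `med_<organ>` column per
#'   organ (NA for empty nodes).
#' @export
node_summary <- function(model, spm) {
  stopifnot(inherits(model, "atlas_som"))
  x <- as.matrix(spm)
  k <- nrow(model$codebook)
  organs <- colnames(x)
  if (is.null(organs)) organs <- paste0("V", seq_len(ncol(x)))
  colnames(x) <- organs
  med <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, organs))
  n_members <- integer(k)
  high <- character(k)
  for (u in seq_len(k)) {
    members <- names(model$assignment)[model$assignment == u]
    n_members[u] <- length(members)
    if (length(members) > 0L) {
      med[u, ] <- apply(x[members, , drop = FALSE], 2L, median)
      high[u] <- paste(organs[med[u, ] > 0], collapse = ",")
    }
  }
  out <- data.frame(node = seq_len(k), n_members = n_members,
                    high_organs = high, stringsAsFactors = FALSE)
  colnames(med) <- paste0("med_", organs)
  cbind(out, med)
}
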