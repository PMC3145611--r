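# Clustering of density matrices: a built-in self-organizing map plus
# k-means (Lloyd, via stats::kmeans) and average-linkage hierarchical
# clustering, all returning the same assignment structure so cluster
# region lists can be exported uniformly.

#' Self-organizing map clustering
#'
#' Classic online SOM on a rectangular node grid: weights are initialized
#' from the seeded RNG (uniform within each column's data range), rows are
#' presented in random order each epoch, the nearest node (Euclidean) wins,
#' and the winner's grid neighborhood is pulled toward the sample with a
#' Gaussian kernel whose radius and learning rate decay linearly over the
#' epochs. The final assignment maps each row to its nearest node.
#'
#' @param mat numeric matrix (rows = items to cluster).
#' @param grid `c(rows, cols)` of the node grid (default `c(3, 3)`).
#' @param epochs training epochs (default 100).
#' @param alpha `c(start, end)` learning rate (default `c(0.5, 0.01)`).
#' @param radius initial neighborhood radius; default `max(grid) / 2`.
#' @param seed RNG seed.
#' @return A list of class `cluster_assignment`: `method`, `cluster`
#'   (integer node id per row, row-major over the grid), `centers` (node
#'   weight matrix), `grid`, `seed`.
#' @export
som_cluster <- function(mat, grid = c(3L, 3L), epochs = 100L,
                        alpha = c(0.5, 0.01), radius = NULL, seed = 1L) {
  stopifnot(nrow(mat) >= 1, all(grid >= 1))
  nn <- prod(grid)
  if (is.null(radius)) radius <- max(grid) / 2
  force(seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rng <- apply(mat, 2, range)
  W <- matrix(stats::runif(nn * ncol(mat), rng[1, ], rng[2, ]),
              nn, ncol(mat), byrow = TRUE)
  # node grid coordinates, row-major
  gx <- rep(seq_len(grid[1]), each = grid[2])
  gy <- rep(seq_len(grid[2]), times = grid[1])
  total_steps <- epochs
  for (ep in seq_len(epochs)) {
    frac <- (ep - 1) / max(1, total_steps - 1)
    a <- alpha[1] + (alpha[2] - alpha[1]) * frac
    r <- max(radius * (1 - frac), 0.5)
    for (i in sample.int(nrow(mat))) {
      x <- mat[i, ]
      d2 <- rowSums(sweep(W, 2, x)^2)
      win <- which.min(d2)
      gd2 <- (gx - gx[win])^2 + (gy - gy[win])^2
      h <- a * exp(-gd2 / (2 * r^2))
      upd <- h > 1e-4
      W[upd, ] <- W[upd, , drop = FALSE] +
        h[upd] * (matrix(x, sum(upd), ncol(mat), byrow = TRUE) -
                    W[upd, , drop = FALSE])
    }
  }
  assign_node <- apply(mat, 1, function(x) which.min(colSums((t(W) - x)^2)))
  structure(list(method = "som", cluster = as.integer(assign_node),
                 centers = W, grid = grid, seed = seed),
            class = "cluster_assignment")
}

#' k-means clustering of a matrix
#'
#' Seeded Lloyd iterations via [stats::kmeans()].
#'
#' @param mat numeric matrix.
#' @param k number of clusters (1 <= k <= rows).
#' @param seed RNG seed.
#' @param nstart random restarts (default 5).
#' @return A `cluster_assignment` (`method = "kmeans"`).
#' @export
kmeans_cluster <- function(mat, k, seed = 1L, nstart = 5L) {
  if (k <= 0) stop("k must be positive")
  stopifnot(k <= nrow(mat))
  force(seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  if (k == nrow(mat)) {
    # singleton clusters; kmeans() rejects duplicate centers
    return(structure(list(method = "kmeans",
                          cluster = seq_len(nrow(mat)),
                          centers = mat, k = k, seed = seed),
                     class = "cluster_assignment"))
  }
  km <- stats::kmeans(mat, centers = k, nstart = nstart,
                      algorithm = "Lloyd", iter.max = 100L)
  structure(list(method = "kmeans", cluster = as.integer(km$cluster),
                 centers = km$centers, k = k, seed = seed,
                 tot_withinss = km$tot.withinss),
            class = "cluster_assignment")
}

#' Hierarchical clustering of a matrix
#'
#' Average-linkage agglomeration on Euclidean distances, cut at `k`.
#'
#' @param mat numeric matrix.
#' @param k number of clusters.
#' @param linkage linkage method (default `"average"`).
#' @return A `cluster_assignment` (`method = "hierarchical"`).
#' @export
hierarchical_cluster <- function(mat, k, linkage = "average") {
  if (k <= 0) stop("k must be positive")
  hc <- stats::hclust(stats::dist(mat), method = linkage)
  structure(list(method = "hierarchical",
                 cluster = as.integer(stats::cutree(hc, k = k)),
                 k = k, linkage = linkage),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d item(s) in %d cluster(s)\n",
              x$method, length(x$cluster), length(unique(x$cluster))))
  invisible(x)
}

#' Export per-cluster region lists
#'
#' @param assignment a `cluster_assignment`.
#' @param regions the [peak_set()] (or [gene_table()]) whose rows were
#'   clustered, in matrix row order.
#' @param outdir output directory; one BED (peaks) or symbol list (genes)
#'   per cluster.
#' @return Character vector of written paths.
#' @export
write_cluster_regions <- function(assignment, regions, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cl in sort(unique(assignment$cluster))) {
    sel <- assignment$cluster == cl
    p <- file.path(outdir, sprintf("cluster_%d%s", cl,
                                   if (inherits(regions, "peak_set")) ".bed" else ".txt"))
    if (inherits(regions, "peak_set"))
      write_peaks(regions[sel, , drop = FALSE], p)
    else
      writeLines(regions$symbol[sel], p)
    paths <- c(paths, p)
  }
  paths
}
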