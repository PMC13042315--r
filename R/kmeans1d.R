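#' Exact one-dimensional k-means clustering
#'
#' Globally optimal 1-D k-means by dynamic programming over the sorted
#' values (optimal 1-D clusters are contiguous in sorted order). The result
#' is deterministic; `seed` is accepted for interface symmetry with the
#' other simulation operations but is not used.
#'
#' @param values Numeric vector.
#' @param K Number of clusters (at most the number of distinct values).
#' @param seed Ignored (the algorithm is deterministic).
#' @return List with `cluster` (integer assignment in input order, clusters
#'   numbered by increasing center), `centers` (cluster means, increasing)
#'   and `loss` (within-cluster sum of squares, the global minimum).
#' @export
kmeans_1d <- function(values, K, seed = NULL) {
  n <- length(values)
  if (K > length(unique(values))) {
    stop("K = ", K, " exceeds the number of distinct values (",
         length(unique(values)), ")")
  }
  stopifnot(K >= 1)
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # ss(i, j): within-cluster sum of squares of x[i..j]
  ss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, K, n)
  B <- matrix(0L, K, n)
  for (j in 1:n) {
    D[1, j] <- ss(1, j)
    B[1, j] <- 1L
  }
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:n) {
        best <- Inf; bi <- k
        for (i in k:j) {
          v <- D[k - 1, i - 1] + ss(i, j)
          if (v < best - 1e-12) { best <- v; bi <- i }
        }
        D[k, j] <- best
        B[k, j] <- as.integer(bi)
      }
    }
  }
  cl_sorted <- integer(n)
  j <- n
  for (k in K:1) {
    i <- B[k, j]
    cl_sorted[i:j] <- k
    j <- i - 1
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centers <- vapply(1:K, function(k) mean(x[cl_sorted == k]), numeric(1))
  list(cluster = cluster, centers = centers, loss = D[K, n])
}

#' Select a reference panel by clustering distances to an anchor strain
#'
#' Clusters strains into K groups by their genetic distance from a single
#' anchor strain (exact 1-D k-means) and picks one strain uniformly at
#' random from each cluster, reproducing the panel-thinning procedure used
#' to reduce a large strain collection to a fixed-size reference panel.
#'
#' @param distance_to_anchor Named numeric vector: distance of each strain
#'   from the anchor.
#' @param K Number of clusters / panel size.
#' @param seed Integer seed for the per-cluster random choice.
#' @return Character vector of K selected strain ids (one per cluster, in
#'   increasing cluster-center order).
#' @export
select_panel <- function(distance_to_anchor, K, seed = 1) {
  if (is.null(names(distance_to_anchor))) {
    stop("distance_to_anchor must be a named vector")
  }
  km <- kmeans_1d(distance_to_anchor, K)
  set.seed(seed)
  vapply(1:K, function(k) {
    ids <- names(distance_to_anchor)[km$cluster == k]
    if (length(ids) == 1) ids else sample(ids, 1)
  }, character(1))
}
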