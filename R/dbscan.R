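#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN with Euclidean distances. A point is a core point when at
#' least `min_samples` points (itself included) lie within `eps`; clusters
#' are the density-reachability closures of the core points; points within
#' `eps` of a core point but not core themselves are border points; the rest
#' is noise. Border points reachable from several clusters are assigned to
#' the cluster of their nearest core neighbour (ties to the lowest point
#' index), which makes the labelling independent of input order; cluster
#' numbers follow first appearance in input order.
#'
#' @param points Numeric matrix (n x d) or data frame of coordinates.
#' @param eps Neighbourhood radius, > 0. Neighbourhood is closed
#'   (distance <= eps).
#' @param min_samples Core-point threshold >= 1, self included.
#' @return Integer vector of cluster labels, one per point; `0` marks noise.
#' @examples
#' pts <- rbind(matrix(rnorm(20, sd = 0.05), ncol = 2), c(5, 5))
#' dbscan(pts, eps = 0.5, min_samples = 3)
#' @export
dbscan <- function(points, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(n) || n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- integer(n) # 0 = noise
  # union-find over core points
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  core_idx <- which(core)
  for (i in core_idx) {
    for (j in core_idx[core_idx > i]) {
      if (nb[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  # number clusters by first core appearance in input order
  next_label <- 0L
  root_label <- integer(n)
  for (i in core_idx) {
    r <- find(i)
    if (root_label[r] == 0L) { next_label <- next_label + 1L; root_label[r] <- next_label }
    labels[i] <- root_label[r]
  }
  # border points: nearest core neighbour within eps, tie -> lowest index
  for (i in which(!core)) {
    cand <- core_idx[nb[i, core_idx]]
    if (length(cand) > 0) {
      best <- cand[order(d[i, cand], cand)][1]
      labels[i] <- labels[best]
    }
  }
  labels
}
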