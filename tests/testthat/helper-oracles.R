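# Independent oracles and fixture builders used across the suite.

# vectorized point-in-convex-polygon (poly CCW, nx2 points)
points_in_convex <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    cross <- ex * (pts[, 2] - poly[i, 2]) - ey * (pts[, 1] - poly[i, 1])
    inside <- inside & cross >= -1e-12
  }
  inside
}

orient_ccw <- function(p) {
  n <- nrow(p); i2 <- c(2:n, 1)
  s <- sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
  if (s < 0) p[rev(seq_len(n)), , drop = FALSE] else p
}

# Monte-Carlo IoU by area sampling over the joint bounding box
mc_iou <- function(a, b, n = 1e5) {
  pa <- orient_ccw(box_corners(a)); pb <- orient_ccw(box_corners(b))
  allc <- rbind(pa, pb)
  xs <- runif(n, min(allc[, 1]), max(allc[, 1]))
  ys <- runif(n, min(allc[, 2]), max(allc[, 2]))
  pts <- cbind(xs, ys)
  in_a <- points_in_convex(pts, pa)
  in_b <- points_in_convex(pts, pb)
  union <- sum(in_a | in_b)
  if (union == 0) return(0)
  sum(in_a & in_b) / union
}

# Brute-force DBSCAN by boolean reachability-matrix closure; border points
# attach to the cluster of their nearest core neighbour (tie: lowest index),
# the same documented rule as the implementation, derived independently.
dbscan_oracle <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(points))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  reach <- nb & outer(core, core, `&`)
  diag(reach) <- core
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  nxt_lab <- 0L
  for (i in which(core)) {
    if (labels[i] == 0L) {
      nxt_lab <- nxt_lab + 1L
      labels[reach[i, ] & core] <- nxt_lab
    }
  }
  for (i in which(!core)) {
    cand <- which(core & nb[i, ])
    if (length(cand) > 0) {
      labels[i] <- labels[cand[order(d[i, cand], cand)][1]]
    }
  }
  labels
}

# canonicalise a labelling: clusters renumbered by first appearance,
# noise (0) kept as-is, so partitions compare up to label permutation
canon_labels <- function(lab) {
  pos <- lab > 0
  lab[pos] <- as.integer(factor(lab[pos], levels = unique(lab[pos])))
  lab
}

# AUC by explicit pair counting over all positive/negative pairs
auc_pair_oracle <- function(scores, truth) {
  sp <- scores[truth == 1]; sn <- scores[truth == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Exact signed-rank distribution by generating-function convolution over the
# (possibly mid-ranked) ranks; an independent route to full enumeration.
signrank_p_oracle <- function(diffs, tail = "greater") {
  d <- diffs[diffs != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  w2 <- round(2 * r) # half-integer ranks doubled onto an integer grid
  probs <- 1
  offset <- 0
  for (w in w2) {
    shifted <- c(rep(0, w), probs)
    probs <- c(probs, rep(0, w)) / 2 + shifted / 2
  }
  support <- (seq_along(probs) - 1) / 2
  p_ge <- sum(probs[support >= W - 1e-9])
  p_le <- sum(probs[support <= W + 1e-9])
  switch(tail, greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# fixture builders -----------------------------------------------------------

dummy_box <- function(cx = 100, cy = 100) rotated_box(cx, cy, 40, 30, 10)

make_frame <- function(idx, structures = character(0), confs = numeric(0)) {
  dets <- mapply(function(s, cf) detection(s, cf, dummy_box()),
                 structures, confs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  frame_detections(idx, dets)
}

# two-structure toy scoring config used by unit tests
toy_config <- function(...) {
  scoring_config(
    base_scores = c(A = 2, B = 1, C = 1.5),
    criteria = list(AHV = list(required = "A", min_confidence = 0.5),
                    TVV = list(required = "B", min_confidence = 0.5),
                    BV = list(required = "C", min_confidence = 0.5)),
    ...)
}

make_image <- function(...) {
  probs <- setNames(rep(0.05, 6), condition_labels())
  over <- list(...)
  probs[names(over)] <- unlist(over)
  image_prediction(probs)
}

normal_image <- function() make_image(normal = 0.9)

random_rotated_box <- function() {
  rotated_box(runif(1, -50, 50), runif(1, -50, 50),
              runif(1, 1, 40), runif(1, 1, 40), runif(1, -90, 90))
}
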